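#' Model configuration
#'
#' Architecture and training-relevant hyperparameters of the natural-growth
#' network. Node hidden dimension after the embedding stage is
#' `d_inherent_embed + d_env_embed`; the quasi-dissolved branch widens it by
#' `d_solvent_embed`.
#'
#' Defaults (all overridable): three intramolecular and two intermolecular
#' passing rounds, LeakyReLU(0.01) activation, 64-dimensional embeddings,
#' a set2set readout with 3 processing steps, and a (128, 64, 1) prediction
#' head.
#'
#' @param d_inherent_embed Embedding width of the inherent-feature map W1.
#' @param d_env_embed Embedding width of the environmental-feature map W2.
#' @param d_solvent_embed Embedding width of the solvent-descriptor map W3.
#' @param d_edge_embed Embedding width of the bond (W4) and polarity (W5) maps.
#' @param k_intra Number of intramolecular message-passing rounds.
#' @param k_inter Number of intermolecular rounds (both dissolved branches).
#' @param activation One of `"leaky_relu"`, `"relu"`, `"tanh"`, `"identity"`.
#' @param readout `"set2set"` (default, 3 processing steps) or `"sum"`.
#' @param processing_steps set2set processing steps.
#' @param head_layers Widths of the prediction head MLP, final width must be 1.
#' @param share_theta Share one Theta per passing stage across rounds instead
#'   of one per round.
#' @param solvent_blind Freeze W3 and W5 at zero (ablation: the architecture
#'   sees no solvent information).
#' @param seed Integer seed governing parameter initialization.
#' @return An object of class `ngnn_config`.
#' @export
ngnn_config <- function(d_inherent_embed = 64L,
                        d_env_embed = 64L,
                        d_solvent_embed = 64L,
                        d_edge_embed = 64L,
                        k_intra = 3L,
                        k_inter = 2L,
                        activation = "leaky_relu",
                        readout = "set2set",
                        processing_steps = 3L,
                        head_layers = c(128L, 64L, 1L),
                        share_theta = FALSE,
                        solvent_blind = FALSE,
                        seed = 1L) {
  dims <- c(d_inherent_embed, d_env_embed, d_solvent_embed, d_edge_embed)
  if (any(dims < 1)) ngnn_abort("all embedding dims must be >= 1")
  if (k_intra < 1 || k_inter < 1) {
    ngnn_abort("k_intra and k_inter must be >= 1")
  }
  if (!readout %in% c("set2set", "sum")) {
    ngnn_abort("readout must be 'set2set' or 'sum'")
  }
  if (utils::tail(head_layers, 1) != 1) {
    ngnn_abort("final head layer width must be 1")
  }
  activation_fun(activation)  # validates the name
  structure(
    list(
      d_inherent_embed = as.integer(d_inherent_embed),
      d_env_embed = as.integer(d_env_embed),
      d_solvent_embed = as.integer(d_solvent_embed),
      d_edge_embed = as.integer(d_edge_embed),
      k_intra = as.integer(k_intra),
      k_inter = as.integer(k_inter),
      activation = activation,
      readout = readout,
      processing_steps = as.integer(processing_steps),
      head_layers = as.integer(head_layers),
      share_theta = isTRUE(share_theta),
      solvent_blind = isTRUE(solvent_blind),
      seed = as.integer(seed)
    ),
    class = "ngnn_config"
  )
}

# derived dimensions
config_dims <- function(config, n_custom_flags = 0L) {
  nd <- config$d_inherent_embed + config$d_env_embed
  ndq <- nd + config$d_solvent_embed
  readout_mult <- if (config$readout == "set2set") 2L else 1L
  list(
    n_env = 23L + as.integer(n_custom_flags),
    nd = nd, ndq = ndq, de = config$d_edge_embed,
    d_graph = readout_mult * (nd + ndq)
  )
}

#' @export
print.ngnn_config <- function(x, ...) {
  dims <- config_dims(x)
  cat(sprintf(
    "<ngnn_config> dims (inherent/env/solvent/edge) = %d/%d/%d/%d, node dim %d (+%d dissolved), k_intra = %d, k_inter = %d, %s readout, head (%s), activation %s\n",
    x$d_inherent_embed, x$d_env_embed, x$d_solvent_embed, x$d_edge_embed,
    dims$nd, x$d_solvent_embed, x$k_intra, x$k_inter, x$readout,
    paste(x$head_layers, collapse = ", "), x$activation
  ))
  invisible(x)
}
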