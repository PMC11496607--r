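# Learnable parameter banks: W1..W5 raw-feature maps, per-round Theta square
# maps for the three passing stages, the three edge-gate MLPs, set2set
# readouts and the prediction head. Initialization is Glorot-uniform, drawn
# in a fixed order from the configured seed, so a (config, n_custom_flags,
# seed) triple fully determines every tensor.

glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Initialize all model parameters
#'
#' @param config An [ngnn_config()].
#' @param n_custom_flags Number of marking-rule flags appended to the
#'   environmental block (changes only W2's input dimension).
#' @return An object of class `ngnn_parameters`.
#' @export
ngnn_init <- function(config, n_custom_flags = 0L) {
  stopifnot(inherits(config, "ngnn_config"))
  dims <- config_dims(config, n_custom_flags)
  nd <- dims$nd; ndq <- dims$ndq; de <- dims$de
  n_theta <- function(k) if (config$share_theta) 1L else k

  params <- with_seed(sub_seed(config$seed, 2L), {
    p <- list(
      W1 = glorot(6L, config$d_inherent_embed),
      W2 = glorot(dims$n_env, config$d_env_embed),
      W3 = glorot(66L, config$d_solvent_embed),
      W4 = glorot(7L, de),
      W5 = glorot(5L, de),
      theta_intra = lapply(seq_len(n_theta(config$k_intra)),
                           function(k) glorot(nd, nd)),
      theta_q = lapply(seq_len(n_theta(config$k_inter)),
                       function(k) glorot(ndq, ndq)),
      theta_e = lapply(seq_len(n_theta(config$k_inter)),
                       function(k) glorot(nd, nd)),
      mlp_intra = list(W1 = glorot(de, nd), b1 = numeric(nd),
                       W2 = glorot(nd, nd), b2 = numeric(nd)),
      mlp_q = list(W1 = glorot(de, ndq), b1 = numeric(ndq),
                   W2 = glorot(ndq, ndq), b2 = numeric(ndq)),
      mlp_e = list(W1 = glorot(2L * de, nd), b1 = numeric(nd),
                   W2 = glorot(nd, nd), b2 = numeric(nd))
    )
    if (config$readout == "set2set") {
      s2s <- function(d) {
        b <- numeric(4L * d)
        b[(d + 1L):(2L * d)] <- 1  # forget-gate bias
        list(Wx = glorot(2L * d, 4L * d), Wh = glorot(d, 4L * d), b = b)
      }
      p$readout_q <- s2s(ndq)
      p$readout_e <- s2s(nd)
    }
    widths <- c(dims$d_graph, config$head_layers)
    p$head <- lapply(seq_len(length(widths) - 1L), function(l) {
      list(W = glorot(widths[l], widths[l + 1L]), b = numeric(widths[l + 1L]))
    })
    p
  })
  if (config$solvent_blind) {
    params$W3[] <- 0
    params$W5[] <- 0
  }
  structure(params,
            config = config,
            n_custom_flags = as.integer(n_custom_flags),
            frozen = if (config$solvent_blind) c("W3", "W5") else character(0),
            class = "ngnn_parameters")
}

#' Total number of learnable scalars
#' @param params An `ngnn_parameters` object.
#' @return Integer count.
#' @export
ngnn_param_count <- function(params) {
  length(flatten_params(params))
}

#' @export
print.ngnn_parameters <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<ngnn_parameters> %d parameters, seed %d, %d marking flag(s)%s\n",
              ngnn_param_count(x), cfg$seed, attr(x, "n_custom_flags"),
              if (length(attr(x, "frozen")))
                paste0(", frozen: ", paste(attr(x, "frozen"), collapse = ", "))
              else ""))
  invisible(x)
}

# flatten to a named numeric vector / restore (used by the finite-difference
# gradient checker and the optimizer bookkeeping)
flatten_params <- function(params) {
  unlist(unclass(params))
}

unflatten_params <- function(params, flat) {
  skel <- unclass(params)
  out <- utils::relist(flat, skel)
  structure(out,
            config = attr(params, "config"),
            n_custom_flags = attr(params, "n_custom_flags"),
            frozen = attr(params, "frozen"),
            class = "ngnn_parameters")
}

# zero-valued gradient container with the same shape
zero_like <- function(params) {
  rapply(unclass(params), function(x) x * 0, how = "replace")
}

# elementwise in-place-style combination of two same-shape nested lists
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- map2_params(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

# ---- checkpointing (text JSON, bit-exact tensors via base64 doubles) --------

encode_tensor <- function(x) {
  list(dim = dim(x) %||% length(x),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8, endian = "little")))
}

decode_tensor <- function(obj) {
  v <- readBin(jsonlite::base64_dec(obj$data), numeric(),
               n = prod(unlist(obj$dim)), size = 8, endian = "little")
  d <- unlist(obj$dim)
  if (length(d) > 1) dim(v) <- d
  v
}

encode_bank <- function(x) {
  if (is.list(x)) lapply(x, encode_bank) else encode_tensor(x)
}

decode_bank <- function(x) {
  if (!is.null(x$data) && !is.null(x$dim)) decode_tensor(x)
  else lapply(x, decode_bank)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON text file holding the configuration, every
#' parameter tensor (base64-encoded IEEE doubles, so the round-trip is
#' bit-exact), the descriptor registry version, the marking-flag count and
#' optionally the target standardization of a fitted model.
#'
#' @param params An `ngnn_parameters` object (or an `ngnn_fit`, whose
#'   parameters and standardization are saved).
#' @param path Output path.
#' @export
ngnn_save <- function(params, path) {
  standardize <- NULL
  if (inherits(params, "ngnn_fit")) {
    standardize <- params$standardize
    params <- params$params
  }
  obj <- list(
    config = unclass(attr(params, "config")),
    n_custom_flags = attr(params, "n_custom_flags"),
    frozen = attr(params, "frozen"),
    registry_version = descriptor_registry_version(),
    standardize = standardize,
    params = encode_bank(unclass(params))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname ngnn_save
#' @return `ngnn_load()` returns an `ngnn_parameters` object; if the
#'   checkpoint came from a fit, the standardization is attached as attribute
#'   `standardize`.
#' @export
ngnn_load <- function(path) {
  obj <- jsonlite::read_json(path)
  cfg <- do.call(ngnn_config, obj$config)
  p <- decode_bank(obj$params)
  out <- structure(p,
                   config = cfg,
                   n_custom_flags = as.integer(obj$n_custom_flags),
                   frozen = unlist(obj$frozen) %||% character(0),
                   class = "ngnn_parameters")
  if (!is.null(obj$standardize)) {
    attr(out, "standardize") <- list(mean = obj$standardize$mean,
                                     sd = obj$standardize$sd)
  }
  out
}
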