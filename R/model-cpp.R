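# Bridge to the compiled training kernels. The flat parameter layout is the
# collect_leaves() order; cpp_config() hands the C++ side everything it needs
# to reconstruct the banks from one numeric vector.

cpp_config <- function(params) {
  config <- attr(params, "config")
  dims <- config_dims(config, attr(params, "n_custom_flags"))
  act_id <- match(config$activation,
                  c("leaky_relu", "relu", "tanh", "identity")) - 1L
  list(
    d1 = config$d_inherent_embed, d2 = config$d_env_embed,
    d3 = config$d_solvent_embed, de = config$d_edge_embed,
    n_env = dims$n_env,
    k_intra = config$k_intra, k_inter = config$k_inter,
    share_theta = config$share_theta,
    set2set = config$readout == "set2set",
    processing_steps = config$processing_steps,
    act = act_id,
    head_widths = c(dims$d_graph, config$head_layers)
  )
}

cpp_batch <- function(batch) {
  list(
    Xa = batch$Xa, Xb = batch$Xb, Ea = batch$Ea,
    Hc = batch$Hc, Eb = batch$Eb,
    src = as.integer(batch$src), dst = as.integer(batch$dst),
    graph_node = as.integer(batch$graph_node),
    graph_edge = as.integer(batch$graph_edge),
    deg = as.numeric(batch$deg)
  )
}

# logical mask of flat coordinates belonging to frozen banks
frozen_mask <- function(params) {
  frozen <- attr(params, "frozen")
  nm <- names(flatten_params(params))
  if (!length(frozen)) return(logical(0))
  Reduce(`|`, lapply(frozen, function(bk) startsWith(nm, bk)))
}

# compiled-path prediction in original units
cpp_predict_samples <- function(flat, ccfg, samples, standardize = NULL,
                                batch_size = 256L) {
  out <- numeric(length(samples))
  idx <- split(seq_along(samples), ceiling(seq_along(samples) / batch_size))
  for (ii in idx) {
    cb <- cpp_batch(build_batch(samples[ii]))
    out[ii] <- cpp_loss_grads(flat, ccfg, cb, numeric(length(ii)),
                              FALSE)$y_hat
  }
  if (!is.null(standardize)) out <- out * standardize$sd + standardize$mean
  out
}
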