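# Reverse-mode gradients for the batched forward pass. Every stage's backward
# mirrors its forward exactly (same caches, same segment orderings); the
# finite-difference check in ngnn_gradient_check() validates all banks.

gate_mlp_backward <- function(X, g, mlp, act, dG) {
  dW2 <- crossprod(g$A1, dG)
  db2 <- colSums(dG)
  dA1 <- tcrossprod(dG, mlp$W2)
  dZ1 <- dA1 * act$df(g$Z1)
  dW1 <- crossprod(X, dZ1)
  db1 <- colSums(dZ1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dX = tcrossprod(dZ1, mlp$W1))
}

pass_backward <- function(Hs, src, dst, deg, gate, thetas, share_theta,
                          dH_final) {
  k_rounds <- length(Hs) - 1L
  n <- nrow(Hs[[1]])
  inv_deg <- numeric(n)
  inv_deg[deg > 0] <- 1 / deg[deg > 0]
  dThetas <- lapply(thetas, function(th) th * 0)
  dGate <- gate * 0
  dH <- dH_final
  for (k in rev(seq_len(k_rounds))) {
    idx <- if (share_theta) 1L else k
    Hk1 <- Hs[[k]]
    dThetas[[idx]] <- dThetas[[idx]] + crossprod(Hk1, dH)
    dH_prev <- tcrossprod(dH, thetas[[idx]])
    if (length(src)) {
      dAgg <- dH * inv_deg
      dMsg <- dAgg[dst, , drop = FALSE]
      dH_prev <- dH_prev + segment_sum(dMsg * gate, src, n)
      dGate <- dGate + dMsg * Hk1[src, , drop = FALSE]
    }
    dH <- dH_prev
  }
  list(dH0 = dH, dGate = dGate, dThetas = dThetas)
}

set2set_backward <- function(M, graph_node, n_graphs, rp, cache, dOut) {
  d <- ncol(M)
  steps <- length(cache)
  dM <- M * 0
  dWx <- rp$Wx * 0; dWh <- rp$Wh * 0; db <- rp$b * 0
  dqstar <- dOut
  dh_carry <- matrix(0, n_graphs, d)
  dc_carry <- matrix(0, n_graphs, d)
  for (t in rev(seq_len(steps))) {
    cc <- cache[[t]]
    dq <- dqstar[, 1:d, drop = FALSE]
    dr <- dqstar[, (d + 1):(2 * d), drop = FALSE]
    dM <- dM + cc$a * dr[graph_node, , drop = FALSE]
    da <- rowSums(M * dr[graph_node, , drop = FALSE])
    sg <- segment_sum(matrix(cc$a * da, ncol = 1), graph_node, n_graphs)[, 1]
    dlogits <- cc$a * (da - sg[graph_node])
    dM <- dM + dlogits * cc$q[graph_node, , drop = FALSE]
    dq <- dq + segment_sum(dlogits * M, graph_node, n_graphs)
    dh_total <- dq + dh_carry
    do_ <- dh_total * cc$tc
    dc_total <- dc_carry + dh_total * cc$oo * (1 - cc$tc^2)
    di <- dc_total * cc$gg
    df_ <- dc_total * cc$c_in
    dg <- dc_total * cc$ii
    dZ <- cbind(di * cc$ii * (1 - cc$ii),
                df_ * cc$ff * (1 - cc$ff),
                do_ * cc$oo * (1 - cc$oo),
                dg * (1 - cc$gg^2))
    dWx <- dWx + crossprod(cc$x, dZ)
    dWh <- dWh + crossprod(cc$h_in, dZ)
    db <- db + colSums(dZ)
    dqstar <- tcrossprod(dZ, rp$Wx)
    dh_carry <- tcrossprod(dZ, rp$Wh)
    dc_carry <- dc_total * cc$ff
  }
  list(dM = dM, grads = list(Wx = dWx, Wh = dWh, b = db))
}

readout_backward <- function(M, graph_node, n_graphs, rp, ro, config, dOut) {
  if (config$readout == "sum") {
    list(dM = dOut[graph_node, , drop = FALSE], grads = NULL)
  } else {
    set2set_backward(M, graph_node, n_graphs, rp, ro$cache, dOut)
  }
}

head_backward <- function(head, hd, act, dY) {
  L <- length(head)
  grads <- vector("list", L)
  dZ <- matrix(dY, ncol = 1)
  for (l in rev(seq_len(L))) {
    if (l < L) dZ <- dZ * act$df(hd$Zs[[l]])
    grads[[l]] <- list(W = crossprod(hd$As[[l]], dZ), b = colSums(dZ))
    dZ <- tcrossprod(dZ, head[[l]]$W)
  }
  list(grads = grads, dX = dZ)
}

# gradient of a scalar loss with dLoss/dy = dY, for all parameter banks
backward_batch <- function(params, batch, cache, dY) {
  config <- cache$config
  act <- cache$act
  N <- batch$n_nodes; G <- batch$n_graphs
  nd <- ncol(cache$H0)
  d1 <- attr(params, "config")$d_inherent_embed

  hb <- head_backward(params$head, cache$head, act, dY)
  wq <- ncol(cache$ro_q$out)
  d_roq <- hb$dX[, 1:wq, drop = FALSE]
  d_roe <- hb$dX[, (wq + 1):ncol(hb$dX), drop = FALSE]

  rb_q <- readout_backward(cache$Hs_q[[length(cache$Hs_q)]], batch$graph_node,
                           G, params$readout_q, cache$ro_q, config, d_roq)
  rb_e <- readout_backward(cache$Hs_e[[length(cache$Hs_e)]], batch$graph_node,
                           G, params$readout_e, cache$ro_e, config, d_roe)

  pb_q <- pass_backward(cache$Hs_q, batch$src, batch$dst, batch$deg,
                        cache$g_q$G, params$theta_q, config$share_theta,
                        rb_q$dM)
  pb_e <- pass_backward(cache$Hs_e, batch$src, batch$dst, batch$deg,
                        cache$g_e$G, params$theta_e, config$share_theta,
                        rb_e$dM)

  # dissolve_nodes: split the widened gradient
  dHq0 <- pb_q$dH0
  dHprime <- dHq0[, 1:nd, drop = FALSE] + pb_e$dH0
  dHcg_pernode <- dHq0[, (nd + 1):ncol(dHq0), drop = FALSE]
  dHcg <- segment_sum(dHcg_pernode, batch$graph_node, G)
  dZc <- dHcg * act$df(cache$Zc)
  dW3 <- crossprod(batch$Hc, dZc)

  pb_i <- pass_backward(cache$Hs_intra, batch$src, batch$dst, batch$deg,
                        cache$g_intra$G, params$theta_intra,
                        config$share_theta, dHprime)

  # gate MLPs
  gb_i <- gate_mlp_backward(cache$Pa, cache$g_intra, params$mlp_intra, act,
                            pb_i$dGate)
  gb_q <- gate_mlp_backward(cache$Pa, cache$g_q, params$mlp_q, act,
                            pb_q$dGate)
  gb_e <- gate_mlp_backward(cache$Ec, cache$g_e, params$mlp_e, act,
                            pb_e$dGate)

  # dissolved edges: split into the W4 and W5 halves
  de <- ncol(cache$Pa)
  dPa <- gb_i$dX + gb_q$dX
  if (length(batch$src)) {
    dEc <- gb_e$dX
    dPa <- dPa + dEc[, 1:de, drop = FALSE]
    dP5 <- segment_sum(dEc[, (de + 1):(2 * de), drop = FALSE],
                       batch$graph_edge, G)
  } else {
    dP5 <- matrix(0, G, de)
  }
  dZw5 <- dP5 * act$df(cache$Zw5)
  dW5 <- crossprod(batch$Eb, dZw5)
  dZpa <- dPa * act$df(cache$Zpa)
  dW4 <- crossprod(batch$Ea, dZpa)

  # node embedding
  dH0 <- pb_i$dH0
  dZa <- dH0[, 1:d1, drop = FALSE] * act$df(cache$Za)
  dZb <- dH0[, (d1 + 1):nd, drop = FALSE] * act$df(cache$Zb)

  grads <- list(
    W1 = crossprod(batch$Xa, dZa),
    W2 = crossprod(batch$Xb, dZb),
    W3 = dW3,
    W4 = dW4,
    W5 = dW5,
    theta_intra = pb_i$dThetas,
    theta_q = pb_q$dThetas,
    theta_e = pb_e$dThetas,
    mlp_intra = gb_i$grads,
    mlp_q = gb_q$grads,
    mlp_e = gb_e$grads
  )
  if (config$readout == "set2set") {
    grads$readout_q <- rb_q$grads
    grads$readout_e <- rb_e$grads
  }
  grads$head <- hb$grads
  grads
}

# mean-squared-error loss (on whatever scale y is given) and its gradients
loss_and_grads <- function(params, batch, y = batch$y) {
  fw <- forward_batch(params, batch, keep_cache = TRUE)
  resid <- fw$y - y
  loss <- mean(resid^2)
  dY <- 2 * resid / length(y)
  grads <- backward_batch(params, batch, fw$cache, dY)
  list(loss = loss, grads = grads, y_hat = fw$y)
}

#' Finite-difference gradient verification
#'
#' Compares backpropagated gradients of the mean-squared-error loss on a small
#' batch with central finite differences, parameter bank by parameter bank.
#'
#' @param params `ngnn_parameters`.
#' @param samples List of `dissolved_sample`s (a small molecule suffices).
#' @param eps Finite-difference step.
#' @param max_coords_per_bank At most this many coordinates are probed per
#'   bank (all of them if the bank is smaller), deterministically spread.
#' @return A tibble with one row per parameter bank: the largest relative
#'   discrepancy and the number of coordinates checked.
#' @export
ngnn_gradient_check <- function(params, samples, eps = 1e-5,
                                max_coords_per_bank = 25L) {
  batch <- build_batch(samples)
  an <- loss_and_grads(params, batch)
  flat_g <- flatten_params(structure(an$grads, class = "list"))
  flat_p <- flatten_params(params)
  stopifnot(length(flat_g) == length(flat_p))

  bank_of <- sub("([0-9]+)?$", "", names(flat_p))
  bank_of <- sub("^(W[1-5]|theta_intra|theta_q|theta_e|mlp_intra|mlp_q|mlp_e|readout_q|readout_e|head).*",
                 "\\1", names(flat_p))
  banks <- unique(bank_of)
  res <- lapply(banks, function(bk) {
    idx <- which(bank_of == bk)
    if (length(idx) > max_coords_per_bank) {
      idx <- idx[round(seq(1, length(idx), length.out = max_coords_per_bank))]
    }
    err <- 0
    for (i in idx) {
      pp <- flat_p; pp[i] <- pp[i] + eps
      lp <- forward_loss_flat(params, batch, pp)
      pm <- flat_p; pm[i] <- pm[i] - eps
      lm <- forward_loss_flat(params, batch, pm)
      num <- (lp - lm) / (2 * eps)
      # relative error with a unit floor: coordinates whose gradient is
      # negligible on the loss scale are judged absolutely
      err <- max(err, abs(num - flat_g[i]) /
                   max(abs(num) + abs(flat_g[i]), 1))
    }
    tibble::tibble(bank = bk, max_rel_err = err, n_checked = length(idx))
  })
  dplyr::bind_rows(res)
}

forward_loss_flat <- function(params, batch, flat) {
  p <- unflatten_params(params, flat)
  fw <- forward_batch(p, batch)
  mean((fw$y - batch$y)^2)
}
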