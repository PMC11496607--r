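# Forward pass. The canonical implementation is batched: a list of dissolved
# samples becomes one disjoint graph union, and every stage is a dense matrix
# operation plus segment sums over edge/node groupings. Batching is exact —
# predictions are identical (to float associativity) to one-by-one evaluation
# because message aggregation is a per-receiver mean and the readout is
# per-graph. Single-sample stage functions (embed_nodes, intra_pass, ...)
# wrap the same kernels.

# segment sum of rows of X by integer group, result has n rows (missing
# groups give zero rows)
segment_sum <- function(X, group, n) {
  out <- matrix(0, n, ncol(X))
  if (length(group) == 0) return(out)
  rs <- rowsum(X, group = group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Assemble a disjoint graph union from dissolved samples
#'
#' @param samples List of `dissolved_sample` objects with identical marking
#'   rules.
#' @return A list batch structure (node/edge feature matrices, index maps,
#'   degrees, per-graph solvent blocks, targets).
#' @export
build_batch <- function(samples) {
  stopifnot(length(samples) >= 1)
  ks <- vapply(samples, function(s) ncol(s$solute$custom_flags), integer(1))
  if (length(unique(ks)) != 1) {
    ngnn_abort("all samples in a batch must carry the same marking rules")
  }
  n_nodes <- vapply(samples, function(s) s$solute$n_atoms, integer(1))
  offsets <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  Xa <- do.call(rbind, lapply(samples, function(s) s$solute$inherent))
  Xb <- do.call(rbind, lapply(samples, function(s) env_features(s$solute)))
  graph_node <- rep(seq_along(samples), n_nodes)
  edge_list <- lapply(seq_along(samples), function(g) {
    e <- samples[[g]]$solute$edges
    if (nrow(e) == 0) return(NULL)
    cbind(e[, 1] + offsets[g], e[, 2] + offsets[g], g)
  })
  edge_list <- do.call(rbind, edge_list)
  if (is.null(edge_list)) {
    src <- dst <- graph_edge <- integer(0)
    Ea <- matrix(numeric(0), 0, 7)
  } else {
    src <- edge_list[, 1]; dst <- edge_list[, 2]; graph_edge <- edge_list[, 3]
    Ea <- do.call(rbind, lapply(samples, function(s) s$solute$bond_features))
  }
  N <- sum(n_nodes)
  deg <- tabulate(dst, nbins = N)
  Hc <- do.call(rbind, lapply(samples, function(s)
    matrix(s$solvent_descriptors, 1)))
  Eb <- do.call(rbind, lapply(samples, function(s)
    matrix(s$solvent_polarity, 1)))
  list(
    n_graphs = length(samples), n_nodes = N,
    Xa = Xa, Xb = Xb, graph_node = graph_node,
    src = src, dst = dst, graph_edge = graph_edge, Ea = Ea, deg = deg,
    Hc = Hc, Eb = Eb,
    y = vapply(samples, function(s) s$target, numeric(1)),
    sample_id = vapply(samples, function(s) as.character(s$sample_id),
                       character(1))
  )
}

# two-layer MLP with linear output (the edge gates)
add_bias <- function(M, b) {
  if (nrow(M) == 0) return(M)
  M + matrix(b, nrow(M), length(b), byrow = TRUE)
}

gate_mlp <- function(X, mlp, act) {
  Z1 <- add_bias(X %*% mlp$W1, mlp$b1)
  A1 <- act$f(Z1)
  G <- add_bias(A1 %*% mlp$W2, mlp$b2)
  list(Z1 = Z1, A1 = A1, G = G)
}

# k rounds of gated-mean message passing:
#   h_i^k = Theta_k h_i^{k-1} + (1/N_i) sum_{j in N(i)} h_j^{k-1} * gate_ij
pass_rounds <- function(H, src, dst, deg, gate, thetas, k_rounds, share_theta) {
  Hs <- vector("list", k_rounds + 1L)
  Hs[[1]] <- H
  n <- nrow(H)
  inv_deg <- numeric(n)
  inv_deg[deg > 0] <- 1 / deg[deg > 0]
  for (k in seq_len(k_rounds)) {
    th <- thetas[[if (share_theta) 1L else k]]
    Hk <- Hs[[k]]
    if (length(src)) {
      Msg <- Hk[src, , drop = FALSE] * gate
      Agg <- segment_sum(Msg, dst, n) * inv_deg
    } else {
      Agg <- matrix(0, n, ncol(H))
    }
    Hs[[k + 1L]] <- Hk %*% th + Agg
    if (!all(is.finite(Hs[[k + 1L]]))) {
      ngnn_abort(sprintf("non-finite node states after passing round %d", k))
    }
  }
  Hs
}

# batched set2set readout (Vinyals-style: LSTM controller + content attention)
set2set_forward <- function(M, graph_node, n_graphs, rp, steps) {
  d <- ncol(M)
  qstar <- matrix(0, n_graphs, 2L * d)
  h <- matrix(0, n_graphs, d)
  c <- matrix(0, n_graphs, d)
  cache <- vector("list", steps)
  seg_idx <- split(seq_len(nrow(M)), graph_node)
  for (t in seq_len(steps)) {
    x <- qstar
    Z <- add_bias(x %*% rp$Wx + h %*% rp$Wh, rp$b)
    ii <- sigmoid(Z[, 1:d, drop = FALSE])
    ff <- sigmoid(Z[, (d + 1):(2 * d), drop = FALSE])
    oo <- sigmoid(Z[, (2 * d + 1):(3 * d), drop = FALSE])
    gg <- tanh(Z[, (3 * d + 1):(4 * d), drop = FALSE])
    c_new <- ff * c + ii * gg
    tc <- tanh(c_new)
    h_new <- oo * tc
    q <- h_new
    logits <- rowSums(M * q[graph_node, , drop = FALSE])
    # per-graph softmax (max-shifted)
    mx <- vapply(seg_idx, function(ii) max(logits[ii]), numeric(1))
    shift <- numeric(length(logits))
    shift[unlist(seg_idx, use.names = FALSE)] <- rep(mx, lengths(seg_idx))
    ex <- exp(logits - shift)
    ssum <- segment_sum(matrix(ex, ncol = 1), graph_node, n_graphs)[, 1]
    a <- ex / ssum[graph_node]
    r <- segment_sum(M * a, graph_node, n_graphs)
    cache[[t]] <- list(x = x, h_in = h, c_in = c, ii = ii, ff = ff, oo = oo,
                       gg = gg, c_new = c_new, tc = tc, q = q, a = a)
    qstar <- cbind(q, r)
    h <- h_new
    c <- c_new
  }
  list(out = qstar, cache = cache)
}

readout_pool <- function(M, graph_node, n_graphs, rp, config) {
  if (config$readout == "sum") {
    list(out = segment_sum(M, graph_node, n_graphs), cache = NULL)
  } else {
    set2set_forward(M, graph_node, n_graphs, rp, config$processing_steps)
  }
}

head_forward <- function(X, head, act) {
  L <- length(head)
  Zs <- vector("list", L)
  As <- vector("list", L + 1L)
  As[[1]] <- X
  for (l in seq_len(L)) {
    Zs[[l]] <- add_bias(As[[l]] %*% head[[l]]$W, head[[l]]$b)
    As[[l + 1L]] <- if (l < L) act$f(Zs[[l]]) else Zs[[l]]
  }
  list(y = Zs[[L]][, 1], Zs = Zs, As = As)
}

# full batched forward; keep_cache = TRUE retains every intermediate needed
# by the backward pass
forward_batch <- function(params, batch, keep_cache = FALSE) {
  config <- attr(params, "config")
  act <- activation_fun(config$activation)
  N <- batch$n_nodes; G <- batch$n_graphs

  if (ncol(batch$Xb) != nrow(params$W2)) {
    ngnn_abort(sprintf(
      "environmental feature width %d does not match W2 input dimension %d (marking rules of data and parameters disagree)",
      ncol(batch$Xb), nrow(params$W2)
    ), class = "ngnn_dim_mismatch")
  }

  # Stage 1: node embedding
  Za <- batch$Xa %*% params$W1
  Zb <- batch$Xb %*% params$W2
  H0 <- cbind(act$f(Za), act$f(Zb))

  # bond embedding + intra gate
  Zpa <- batch$Ea %*% params$W4
  Pa <- act$f(Zpa)
  g_intra <- gate_mlp(Pa, params$mlp_intra, act)

  # Stage 2: intramolecular rounds
  Hs_intra <- pass_rounds(H0, batch$src, batch$dst, batch$deg, g_intra$G,
                          params$theta_intra, config$k_intra,
                          config$share_theta)
  Hprime <- Hs_intra[[length(Hs_intra)]]

  # Stage 3: dissolve nodes (solvent tail broadcast to every atom)
  Zc <- batch$Hc %*% params$W3
  Hcg <- act$f(Zc)
  Hq0 <- cbind(Hprime, Hcg[batch$graph_node, , drop = FALSE])

  # Stage 4: dissolve edges
  Zw5 <- batch$Eb %*% params$W5
  P5 <- act$f(Zw5)
  Ec <- if (length(batch$src)) {
    cbind(Pa, P5[batch$graph_edge, , drop = FALSE])
  } else {
    matrix(numeric(0), 0, 2L * ncol(P5))
  }

  # Stages 5/6: the two intermolecular branches
  g_q <- gate_mlp(Pa, params$mlp_q, act)
  Hs_q <- pass_rounds(Hq0, batch$src, batch$dst, batch$deg, g_q$G,
                      params$theta_q, config$k_inter, config$share_theta)
  g_e <- gate_mlp(Ec, params$mlp_e, act)
  Hs_e <- pass_rounds(Hprime, batch$src, batch$dst, batch$deg, g_e$G,
                      params$theta_e, config$k_inter, config$share_theta)

  # Stage 7: readout
  ro_q <- readout_pool(Hs_q[[length(Hs_q)]], batch$graph_node, G,
                       params$readout_q, config)
  ro_e <- readout_pool(Hs_e[[length(Hs_e)]], batch$graph_node, G,
                       params$readout_e, config)
  hG <- cbind(ro_q$out, ro_e$out)

  # Stage 8: prediction head
  hd <- head_forward(hG, params$head, act)
  assert_finite(hd$y, "predictions")

  res <- list(y = hd$y)
  if (keep_cache) {
    res$cache <- list(
      act = act, config = config,
      Za = Za, Zb = Zb, H0 = H0,
      Zpa = Zpa, Pa = Pa, g_intra = g_intra, Hs_intra = Hs_intra,
      Zc = Zc, Hcg = Hcg, Hq0 = Hq0,
      Zw5 = Zw5, P5 = P5, Ec = Ec,
      g_q = g_q, Hs_q = Hs_q, g_e = g_e, Hs_e = Hs_e,
      ro_q = ro_q, ro_e = ro_e, hG = hG, head = hd
    )
  }
  res
}

# ---- per-sample stage operations (the architecture, stage by stage) --------

sample_batch <- function(sample) build_batch(list(sample))

node_states <- function(H, track) {
  structure(H, track = track, class = c("node_states", "matrix", "array"))
}

#' Stage 1: embed raw atom features into the hidden node space
#'
#' Per atom: `h_i = concat(act(W1 h_ia), act(W2 h_ib))` — inherent constants
#' and environmental one-hots are mapped by separate scales because their
#' codings are incompatible (natural vs one-hot).
#'
#' @param sample A `dissolved_sample`.
#' @param params `ngnn_parameters`.
#' @return Node-state matrix `n_atoms x (d_inherent_embed + d_env_embed)`.
#' @export
embed_nodes <- function(sample, params) {
  config <- attr(params, "config")
  act <- activation_fun(config$activation)
  b <- sample_batch(sample)
  if (ncol(b$Xb) != nrow(params$W2)) {
    ngnn_abort(sprintf(
      "environmental feature width %d does not match W2 input dimension %d",
      ncol(b$Xb), nrow(params$W2)
    ), class = "ngnn_dim_mismatch")
  }
  node_states(cbind(act$f(b$Xa %*% params$W1), act$f(b$Xb %*% params$W2)),
              track = "intact")
}

#' Edge-gate vectors of one passing stage
#'
#' Computes the per-directed-edge gate `MLP(act(W4 e_ij_a))` (stages
#' `"intra"` and `"q"`) or `MLP(e_ij_c)` (stage `"e"`, which consumes the
#' dissolved edge features directly).
#'
#' @param graph A `molecular_graph`.
#' @param params `ngnn_parameters`.
#' @param which One of `"intra"`, `"q"`, `"e"`.
#' @param edge_states Dissolved edge matrix (required for `which = "e"`).
#' @return Matrix `n_directed_edges x node_dim`.
#' @export
edge_gate <- function(graph, params, which, edge_states = NULL) {
  config <- attr(params, "config")
  act <- activation_fun(config$activation)
  if (which == "e") {
    gate_mlp(edge_states, params$mlp_e, act)$G
  } else {
    Pa <- act$f(graph$bond_features %*% params$W4)
    gate_mlp(Pa, params[[paste0("mlp_", which)]], act)$G
  }
}

#' Stage 2: intramolecular message passing
#'
#' `k_rounds` applications of
#' `h_i^k = Theta_k h_i^{k-1} + (1/N_i) sum_j h_j^{k-1} * MLP(act(W4 e_ij))`,
#' with elementwise gating by the bond-feature embedding and mean aggregation
#' over the receiving atom's neighbourhood (isolated atoms get a zero
#' message).
#'
#' @param states Node states from [embed_nodes()].
#' @param graph The solute `molecular_graph`.
#' @param params `ngnn_parameters`.
#' @param k_rounds Number of rounds (default from the configuration).
#' @return Updated node states.
#' @export
intra_pass <- function(states, graph, params,
                       k_rounds = attr(params, "config")$k_intra) {
  config <- attr(params, "config")
  deg <- tabulate(graph$edges[, 2], nbins = graph$n_atoms)
  G <- edge_gate(graph, params, "intra")
  Hs <- pass_rounds(unclass(states), graph$edges[, 1], graph$edges[, 2], deg,
                    G, params$theta_intra, k_rounds, config$share_theta)
  node_states(Hs[[length(Hs)]], track = "intact")
}

#' Stage 3: dissolve atoms in the solvent descriptor field
#'
#' Widens every node state with the same solvent tail
#' `act(W3 h_c)` — one vector per solvent molecule, broadcast to all solute
#' atoms.
#'
#' @inheritParams intra_pass
#' @param sample The `dissolved_sample` providing the solvent descriptors.
#' @return Node states of width `node_dim + d_solvent_embed`.
#' @export
dissolve_nodes <- function(states, sample, params) {
  config <- attr(params, "config")
  act <- activation_fun(config$activation)
  tail <- act$f(matrix(sample$solvent_descriptors, 1) %*% params$W3)
  H <- unclass(states)
  node_states(cbind(H, matrix(tail, nrow(H), length(tail), byrow = TRUE)),
              track = "dissolved_q")
}

#' Stage 4: dissolved edge features
#'
#' Per directed edge: `e_ij_c = concat(act(W4 e_ij_a), act(W5 e_ij_b))`; the
#' polarity term is one vector per sample, shared by all edges.
#'
#' @param sample A `dissolved_sample` whose solute has at least one bond.
#' @param params `ngnn_parameters`.
#' @return Matrix `n_directed_edges x (2 * d_edge_embed)`.
#' @export
dissolve_edges <- function(sample, params) {
  config <- attr(params, "config")
  act <- activation_fun(config$activation)
  graph <- sample$solute
  if (nrow(graph$edges) == 0) {
    ngnn_abort("dissolve_edges requires a solute with at least one bond")
  }
  Pa <- act$f(graph$bond_features %*% params$W4)
  P5 <- act$f(matrix(sample$solvent_polarity, 1) %*% params$W5)
  cbind(Pa, matrix(P5, nrow(Pa), length(P5), byrow = TRUE))
}

#' Stage 5: intermolecular passing on the quasi-dissolved atom graph
#'
#' Same recurrence as [intra_pass()] on the widened states, gated by the
#' original bond embedding `MLP(act(W4 e_ij_a))`, with its own Theta and MLP
#' parameter bank.
#'
#' @param states_q Widened states from [dissolve_nodes()].
#' @inheritParams intra_pass
#' @export
inter_pass_q <- function(states_q, graph, params,
                         k_rounds = attr(params, "config")$k_inter) {
  config <- attr(params, "config")
  deg <- tabulate(graph$edges[, 2], nbins = graph$n_atoms)
  G <- edge_gate(graph, params, "q")
  Hs <- pass_rounds(unclass(states_q), graph$edges[, 1], graph$edges[, 2],
                    deg, G, params$theta_q, k_rounds, config$share_theta)
  node_states(Hs[[length(Hs)]], track = "dissolved_q")
}

#' Stage 6: intermolecular passing on the solvated-edge graph
#'
#' Operates on the unwidened intramolecular output; the gate MLP consumes the
#' dissolved edge features `e_ij_c` directly (no inner re-embedding).
#'
#' @param states Node states from [intra_pass()] (not widened).
#' @param edge_states Dissolved edge matrix from [dissolve_edges()].
#' @inheritParams intra_pass
#' @export
inter_pass_e <- function(states, graph, edge_states, params,
                         k_rounds = attr(params, "config")$k_inter) {
  config <- attr(params, "config")
  deg <- tabulate(graph$edges[, 2], nbins = graph$n_atoms)
  G <- edge_gate(graph, params, "e", edge_states = edge_states)
  Hs <- pass_rounds(unclass(states), graph$edges[, 1], graph$edges[, 2],
                    deg, G, params$theta_e, k_rounds, config$share_theta)
  node_states(Hs[[length(Hs)]], track = "dissolved_e")
}

#' Stage 7: permutation-invariant graph readout
#'
#' Aggregates each branch's final node states with the configured Set
#' operator (set2set or sum) and concatenates the two graph vectors.
#'
#' @param states_q_final Final states of the quasi-dissolved branch.
#' @param states_e_final Final states of the solvated-edge branch.
#' @param params `ngnn_parameters`.
#' @return Named list with `h_G1`, `h_G2` and their concatenation `h_G`.
#' @export
readout_graph <- function(states_q_final, states_e_final, params) {
  config <- attr(params, "config")
  if (nrow(states_q_final) != nrow(states_e_final)) {
    ngnn_abort("the two state sets must come from the same solute (atom counts differ)")
  }
  n <- nrow(states_q_final)
  g1 <- readout_pool(unclass(states_q_final), rep(1L, n), 1L,
                     params$readout_q, config)$out[1, ]
  g2 <- readout_pool(unclass(states_e_final), rep(1L, n), 1L,
                     params$readout_e, config)$out[1, ]
  list(h_G1 = g1, h_G2 = g2, h_G = c(g1, g2))
}

#' Stage 8: decode the graph embedding to the property value
#'
#' @param embedding Result of [readout_graph()] (or a bare numeric vector).
#' @param params `ngnn_parameters`.
#' @return A single numeric prediction.
#' @export
predict_property <- function(embedding, params) {
  config <- attr(params, "config")
  act <- activation_fun(config$activation)
  v <- if (is.list(embedding)) embedding$h_G else embedding
  assert_finite(v, "graph embedding")
  head_forward(matrix(v, 1), params$head, act)$y
}

#' Full forward pass on one dissolved sample
#'
#' Composition of the eight stages: embed, intramolecular passing, the two
#' dissolution branches with intermolecular passing, readout, and the
#' prediction head. Deterministic given parameters; invariant to atom
#' relabeling of the solute.
#'
#' @param sample A `dissolved_sample`.
#' @param params `ngnn_parameters`.
#' @return A single numeric prediction (standardized scale; training fits
#'   attach the inverse transform).
#' @export
ngnn_forward <- function(sample, params) {
  forward_batch(params, sample_batch(sample))$y
}
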