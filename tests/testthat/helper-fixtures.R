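# Shared fixtures: small configurations, cached samples, and an independent
# dense reference implementation of the gated-mean message-passing update.

suppress_ob <- function(expr) suppressWarnings(suppressMessages(expr))

small_config <- function(seed = 42L, ...) {
  ngnn_config(d_inherent_embed = 5L, d_env_embed = 4L, d_solvent_embed = 3L,
              d_edge_embed = 4L, k_intra = 2L, k_inter = 2L,
              head_layers = c(6L, 1L), seed = seed, ...)
}

tiny_sample <- function(smiles = "CCO", solvent = "H2O", target = -0.77,
                        rules = character(0)) {
  build_sample(smiles, solvent, target, marking_rules = rules)
}

# Dense O(n^2) reference for one passing stage: explicit loops over ordered
# atom pairs with an adjacency mask, computed straight from the update
# rule's definition. Independent of the package's segment-sum kernels.
dense_reference_pass <- function(H, graph, gate, thetas, k_rounds,
                                 share_theta = FALSE) {
  n <- graph$n_atoms
  adj <- matrix(FALSE, n, n)
  gate_of <- vector("list", n)
  for (i in seq_len(n)) gate_of[[i]] <- vector("list", n)
  if (nrow(graph$edges) > 0) {
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges[r, 2]  # receiver
      j <- graph$edges[r, 1]  # sender
      adj[i, j] <- TRUE
      gate_of[[i]][[j]] <- gate[r, ]
    }
  }
  for (k in seq_len(k_rounds)) {
    th <- thetas[[if (share_theta) 1L else k]]
    Hnew <- matrix(0, n, ncol(H))
    for (i in seq_len(n)) {
      self <- as.numeric(H[i, ] %*% th)
      msg <- numeric(ncol(H))
      deg <- 0
      for (j in seq_len(n)) {
        if (adj[i, j]) {
          msg <- msg + H[j, ] * gate_of[[i]][[j]]
          deg <- deg + 1
        }
      }
      Hnew[i, ] <- self + if (deg > 0) msg / deg else 0
    }
    H <- Hnew
  }
  H
}

# random molecules with <= `max_atoms` heavy atoms, drawn from the grammars
small_molecules <- function(max_atoms = 6) {
  pool <- unique(unlist(solute_grammars()))
  keep <- character(0)
  for (s in pool) {
    g <- suppress_ob(parse_smiles(s))
    if (g$n_atoms <= max_atoms) keep <- c(keep, s)
  }
  keep
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))
}

# relabel the atoms of a sample's solute by a random permutation (features,
# edges and atom states move consistently)
permute_sample <- function(sample, perm = NULL) {
  g <- sample$solute
  if (is.null(perm)) perm <- sample(g$n_atoms)
  inv <- order(perm)  # old index -> new index
  g2 <- g
  g2$elements <- g$elements[perm]
  g2$atom_state <- g$atom_state[perm, ]
  g2$inherent <- g$inherent[perm, , drop = FALSE]
  g2$env <- g$env[perm, , drop = FALSE]
  g2$custom_flags <- g$custom_flags[perm, , drop = FALSE]
  if (nrow(g$edges) > 0) {
    g2$edges <- cbind(src = inv[g$edges[, 1]], dst = inv[g$edges[, 2]])
  }
  s2 <- sample
  s2$solute <- g2
  s2
}
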