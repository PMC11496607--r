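# Stage-by-stage architecture checks: hand-computable micro-cases, dense
# oracle equivalence, permutation invariance, dimensional bookkeeping.

zeroed_params <- function(config = small_config(), n_flags = 0L) {
  p <- ngnn_init(config, n_flags)
  unflatten_params(p, flatten_params(p) * 0)
}

test_that("embedding with zero maps gives zero states of the right width", {
  s <- suppress_ob(tiny_sample())
  p <- zeroed_params()
  st <- embed_nodes(s, p)
  expect_equal(dim(st), c(3, 5 + 4))
  expect_true(all(st == 0))
})

test_that("embedding is row-wise: permuting atoms permutes states", {
  p <- ngnn_init(small_config())
  s <- suppress_ob(tiny_sample("CCO"))
  st <- embed_nodes(s, p)
  s2 <- s
  perm <- c(2, 3, 1)
  s2$solute$inherent <- s$solute$inherent[perm, ]
  s2$solute$env <- s$solute$env[perm, , drop = FALSE]
  st2 <- embed_nodes(s2, p)
  expect_equal(unclass(st2), unclass(st)[perm, ], ignore_attr = TRUE)
})

test_that("a single-atom embedding with identity-padded W1 reproduces the raw constants", {
  cfg <- ngnn_config(d_inherent_embed = 8L, d_env_embed = 4L,
                     d_solvent_embed = 3L, d_edge_embed = 4L,
                     activation = "identity", head_layers = c(4L, 1L),
                     seed = 1L)
  p <- zeroed_params(cfg)
  p$W1[1:6, 1:6] <- diag(6)
  s <- suppress_ob(tiny_sample("C"))
  st <- embed_nodes(s, p)
  expect_equal(unname(st[1, 1:6]), unname(encode_inherent("C")))
  expect_true(all(st[1, 7:12] == 0))
})

test_that("intramolecular passing reduces to mutual addition on a 2-atom path", {
  # Theta = I and gate == 1 turn one round into mutual addition
  cfg <- small_config()
  p <- zeroed_params(cfg)
  nd <- cfg$d_inherent_embed + cfg$d_env_embed
  for (k in seq_along(p$theta_intra)) p$theta_intra[[k]] <- diag(nd)
  p$mlp_intra$b2[] <- 1  # gate MLP outputs exactly 1 everywhere
  s <- suppress_ob(tiny_sample("CC", "H2O", 0))
  H0 <- matrix(rnorm(2 * nd), 2)
  out <- intra_pass(node_states(H0, "intact"), s$solute, p, k_rounds = 1)
  expect_equal(unclass(out), rbind(H0[1, ] + H0[2, ], H0[2, ] + H0[1, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an isolated atom only sees its Theta chain", {
  cfg <- small_config()
  p <- ngnn_init(cfg)
  s <- suppress_ob(tiny_sample("C", "H2O", 0))
  st <- embed_nodes(s, p)
  out <- intra_pass(st, s$solute, p, k_rounds = 2)
  expected <- unclass(st) %*% p$theta_intra[[1]] %*% p$theta_intra[[2]]
  expect_equal(unclass(out), expected, tolerance = 1e-12, ignore_attr = TRUE)
  # and in the widened branch
  stq <- dissolve_nodes(out, s, p)
  outq <- inter_pass_q(stq, s$solute, p, k_rounds = 2)
  expect_equal(unclass(outq),
               unclass(stq) %*% p$theta_q[[1]] %*% p$theta_q[[2]],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero passing rounds is the identity", {
  p <- ngnn_init(small_config())
  s <- suppress_ob(tiny_sample("CCO"))
  st <- embed_nodes(s, p)
  expect_equal(unclass(intra_pass(st, s$solute, p, k_rounds = 0)),
               unclass(st), ignore_attr = TRUE)
  stq <- dissolve_nodes(st, s, p)
  expect_equal(unclass(inter_pass_q(stq, s$solute, p, k_rounds = 0)),
               unclass(stq), ignore_attr = TRUE)
})

test_that("every passing stage matches the dense O(n^2) oracle", {
  set.seed(99)
  mols <- small_molecules(6)
  pick <- sample(mols, 6)
  for (draw in 1:4) {
    cfg <- small_config(seed = 100L + draw)
    p <- ngnn_init(cfg)
    for (smi in pick) {
      s <- suppress_ob(build_sample(smi, "DMSO", 1))
      g <- s$solute
      st <- embed_nodes(s, p)

      gate_i <- edge_gate(g, p, "intra")
      ref <- dense_reference_pass(unclass(st), g, gate_i, p$theta_intra,
                                  cfg$k_intra)
      out <- intra_pass(st, g, p)
      expect_lt(max_rel_err(unclass(out), ref), 1e-6)

      stq <- dissolve_nodes(out, s, p)
      gate_q <- edge_gate(g, p, "q")
      ref_q <- dense_reference_pass(unclass(stq), g, gate_q, p$theta_q,
                                    cfg$k_inter)
      out_q <- inter_pass_q(stq, g, p)
      expect_lt(max_rel_err(unclass(out_q), ref_q), 1e-6)

      if (nrow(g$edges) > 0) {
        ec <- dissolve_edges(s, p)
        gate_e <- edge_gate(g, p, "e", edge_states = ec)
        ref_e <- dense_reference_pass(unclass(out), g, gate_e, p$theta_e,
                                      cfg$k_inter)
        out_e <- inter_pass_e(out, g, ec, p)
        expect_lt(max_rel_err(unclass(out_e), ref_e), 1e-6)
      }
    }
  }
})

test_that("node dissolution appends one identical solvent tail per atom", {
  cfg <- small_config()
  p <- ngnn_init(cfg)
  s <- suppress_ob(build_sample("c1ccccc1", "H2O", 0))
  st <- intra_pass(embed_nodes(s, p), s$solute, p)
  stq <- dissolve_nodes(st, s, p)
  nd <- ncol(st)
  expect_equal(ncol(stq), nd + cfg$d_solvent_embed)
  act <- activation_fun(cfg$activation)
  tail_ref <- as.numeric(act$f(matrix(s$solvent_descriptors, 1) %*% p$W3))
  for (i in 1:6) {
    expect_equal(unname(unclass(stq)[i, (nd + 1):ncol(stq)]), tail_ref,
                 tolerance = 1e-12)
  }
  # zero W3 gives a zero tail
  p0 <- p; p0$W3[] <- 0
  stq0 <- dissolve_nodes(st, s, p0)
  expect_true(all(unclass(stq0)[, (nd + 1):ncol(stq0)] == 0))
})

test_that("edge dissolution concatenates bond and polarity embeddings", {
  cfg <- small_config()
  p <- ngnn_init(cfg)
  s <- suppress_ob(build_sample("CCO", "DMSO", 0))
  ec <- dissolve_edges(s, p)
  expect_equal(dim(ec), c(4, 2 * cfg$d_edge_embed))
  act <- activation_fun(cfg$activation)
  pa <- act$f(s$solute$bond_features %*% p$W4)
  p5 <- as.numeric(act$f(matrix(s$solvent_polarity, 1) %*% p$W5))
  for (e in seq_len(nrow(ec))) {
    expect_equal(unname(ec[e, ]), unname(c(pa[e, ], p5)), tolerance = 1e-12)
  }
  # polarity half identical across edges; zero W5 zeroes it
  p0 <- p; p0$W5[] <- 0
  ec0 <- dissolve_edges(s, p0)
  expect_true(all(ec0[, (cfg$d_edge_embed + 1):ncol(ec0)] == 0))
  expect_error(dissolve_edges(suppress_ob(build_sample("C", "DMSO", 0)), p))
})

test_that("sum readout pools exactly and concatenates branch embeddings", {
  cfg <- small_config(readout = "sum")
  p <- ngnn_init(cfg)
  sq <- node_states(matrix(1, 3, 4), "dissolved_q")
  se <- node_states(matrix(1, 3, 4), "dissolved_e")
  ro <- readout_graph(sq, se, p)
  expect_equal(unname(ro$h_G), rep(3, 8))
  expect_equal(length(ro$h_G), length(ro$h_G1) + length(ro$h_G2))
  expect_error(readout_graph(sq, node_states(matrix(1, 2, 4), "x"), p))
})

test_that("readout is invariant to atom permutation for both Set operators", {
  for (ro_type in c("set2set", "sum")) {
    cfg <- small_config(readout = ro_type)
    p <- ngnn_init(cfg)
    nd <- cfg$d_inherent_embed + cfg$d_env_embed
    ndq <- nd + cfg$d_solvent_embed
    set.seed(7)
    Mq <- matrix(rnorm(5 * ndq), 5)
    Me <- matrix(rnorm(5 * nd), 5)
    perm <- sample(5)
    a <- readout_graph(node_states(Mq, "q"), node_states(Me, "e"), p)
    b <- readout_graph(node_states(Mq[perm, ], "q"),
                       node_states(Me[perm, ], "e"), p)
    expect_lt(max(abs(a$h_G - b$h_G)), 1e-6)
  }
})

test_that("the prediction head is an exact affine map in the linear case", {
  cfg <- ngnn_config(d_inherent_embed = 4L, d_env_embed = 4L,
                     d_solvent_embed = 2L, d_edge_embed = 2L,
                     readout = "sum", head_layers = 1L, seed = 5L)
  p <- ngnn_init(cfg)
  hg <- rnorm(nrow(p$head[[1]]$W))
  y <- predict_property(hg, p)
  expect_equal(y, sum(hg * p$head[[1]]$W[, 1]) + p$head[[1]]$b,
               tolerance = 1e-12)
  # zero final layer leaves only the bias
  p$head[[1]]$W[] <- 0
  p$head[[1]]$b <- 0.42
  expect_equal(predict_property(hg, p), 0.42)
})

test_that("all-zero weights with a head bias predict the bias for every sample", {
  p <- zeroed_params()
  L <- length(p$head)
  p$head[[L]]$b <- -1.25
  for (smi in c("C", "CCO", "c1ccccc1")) {
    s <- suppress_ob(build_sample(smi, "hexane", 0))
    expect_equal(ngnn_forward(s, p), -1.25, tolerance = 1e-12)
  }
})

test_that("forward is deterministic and invariant to atom reordering", {
  p <- ngnn_init(small_config())
  pairs <- list(c("CCO", "OCC"), c("Cc1ccccc1", "c1ccccc1C"),
                c("CC(C)O", "OC(C)C"), c("ClCCBr", "BrCCCl"))
  for (pr in pairs) {
    s1 <- suppress_ob(build_sample(pr[1], "MeOH", 0))
    s2 <- suppress_ob(build_sample(pr[2], "MeOH", 0))
    y1 <- ngnn_forward(s1, p)
    y2 <- ngnn_forward(s2, p)
    expect_lt(abs(y1 - y2) / max(abs(y1), 1e-8), 1e-5)
    expect_identical(ngnn_forward(s1, p), y1)  # bit-stable repeat
  }
})

test_that("the architecture is not solvent-blind", {
  p <- ngnn_init(small_config(seed = 8L))
  y_w <- ngnn_forward(suppress_ob(build_sample("CCO", "H2O", 0)), p)
  y_d <- ngnn_forward(suppress_ob(build_sample("CCO", "DMSO", 0)), p)
  expect_true(y_w != y_d)
  # but the frozen ablation is
  cfgb <- small_config(solvent_blind = TRUE)
  pb <- ngnn_init(cfgb)
  yb_w <- ngnn_forward(suppress_ob(build_sample("CCO", "H2O", 0)), pb)
  yb_d <- ngnn_forward(suppress_ob(build_sample("CCO", "DMSO", 0)), pb)
  expect_equal(yb_w, yb_d, tolerance = 1e-12)
})

test_that("graph embedding dims follow the two-branch bookkeeping for random configs", {
  set.seed(21)
  for (i in 1:10) {
    ro <- sample(c("set2set", "sum"), 1)
    cfg <- ngnn_config(
      d_inherent_embed = sample(2:6, 1), d_env_embed = sample(2:6, 1),
      d_solvent_embed = sample(2:5, 1), d_edge_embed = sample(2:5, 1),
      k_intra = sample(1:3, 1), k_inter = sample(1:2, 1),
      readout = ro, head_layers = c(4L, 1L), seed = i
    )
    p <- ngnn_init(cfg)
    s <- suppress_ob(build_sample("CCO", "H2O", 0))
    st <- intra_pass(embed_nodes(s, p), s$solute, p)
    stq <- inter_pass_q(dissolve_nodes(st, s, p), s$solute, p)
    ste <- inter_pass_e(st, s$solute, dissolve_edges(s, p), p)
    emb <- readout_graph(stq, ste, p)
    nd <- cfg$d_inherent_embed + cfg$d_env_embed
    mult <- if (ro == "set2set") 2L else 1L
    expect_length(emb$h_G1, mult * (nd + cfg$d_solvent_embed))
    expect_length(emb$h_G2, mult * nd)
    expect_length(emb$h_G, length(emb$h_G1) + length(emb$h_G2))
    # parameter count is a pure function of the configuration
    expect_identical(ngnn_param_count(p), ngnn_param_count(ngnn_init(cfg)))
  }
})

test_that("staged composition equals the one-shot forward pass", {
  p <- ngnn_init(small_config())
  s <- suppress_ob(build_sample("CC(C)O", "THF", 0))
  st <- embed_nodes(s, p)
  st1 <- intra_pass(st, s$solute, p)
  stq <- inter_pass_q(dissolve_nodes(st1, s, p), s$solute, p)
  ste <- inter_pass_e(st1, s$solute, dissolve_edges(s, p), p)
  emb <- readout_graph(stq, ste, p)
  y_staged <- predict_property(emb, p)
  expect_equal(y_staged, ngnn_forward(s, p), tolerance = 1e-12)
})

test_that("batched evaluation equals one-by-one evaluation", {
  p <- ngnn_init(small_config())
  smis <- c("C", "CCO", "c1ccccc1", "CC(C)Cl", "CCCC")
  samples <- lapply(smis, function(x)
    suppress_ob(build_sample(x, "MeCN", 1)))
  yb <- forward_batch(p, build_batch(samples))$y
  y1 <- vapply(samples, function(s) ngnn_forward(s, p), numeric(1))
  expect_lt(max(abs(yb - y1)), 1e-5)
})

test_that("the compiled kernels agree with the reference implementation", {
  smis <- c("CCO", "c1ccncc1", "CC(C)Br", "C")
  samples <- lapply(smis, function(x)
    suppress_ob(build_sample(x, "toluene", 0.5)))
  batch <- build_batch(samples)
  y <- c(0.1, -0.4, 2.2, 0)
  for (variant in list(list(), list(readout = "sum"),
                       list(share_theta = TRUE))) {
    cfg <- do.call(small_config, variant)
    p <- ngnn_init(cfg)
    ref <- loss_and_grads(p, batch, y)
    got <- cpp_loss_grads(as.numeric(flatten_params(p)), cpp_config(p),
                          cpp_batch(batch), y, TRUE)
    expect_equal(got$loss, ref$loss, tolerance = 1e-10)
    expect_equal(got$y_hat, ref$y_hat, tolerance = 1e-10)
    ref_flat <- as.numeric(flatten_params(structure(ref$grads,
                                                    class = "list")))
    expect_lt(max(abs(got$grads - ref_flat)), 1e-8)
  }
})

test_that("checkpoints round-trip bit-exactly", {
  p <- ngnn_init(small_config(seed = 77L))
  tf <- withr::local_tempfile(fileext = ".json")
  ngnn_save(p, tf)
  p2 <- ngnn_load(tf)
  expect_identical(flatten_params(p), flatten_params(p2))
  expect_equal(attr(p2, "config")$d_inherent_embed, 5L)
  s <- suppress_ob(build_sample("CCO", "H2O", 0))
  expect_identical(ngnn_forward(s, p), ngnn_forward(s, p2))
})

test_that("marking-rule mismatch between data and parameters is rejected", {
  p <- ngnn_init(small_config())  # zero marking flags
  s <- suppress_ob(tiny_sample("CCl", rules = "hydrophobic_halogen"))
  expect_error(ngnn_forward(s, p), class = "ngnn_dim_mismatch")
})
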