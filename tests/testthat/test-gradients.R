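# Analytic gradients against central finite differences, for every parameter
# bank of the default-shaped architecture (small dims keep this fast; the
# bank structure is identical to the default configuration).

test_that("backpropagated gradients match finite differences in every bank", {
  p <- ngnn_init(small_config(seed = 42L))
  s <- suppress_ob(tiny_sample("CCO", "H2O", -0.77))  # 3-atom sample
  res <- ngnn_gradient_check(p, list(s), eps = 1e-5,
                             max_coords_per_bank = 20L)
  expect_equal(nrow(res), 14)  # W1..W5, 3 theta banks, 3 MLPs, 2 readouts, head
  for (i in seq_len(nrow(res))) {
    expect_lt(res$max_rel_err[i], 1e-4)
  }
})

test_that("gradients are exact for the sum-readout and shared-theta variants", {
  for (variant in list(list(readout = "sum"), list(share_theta = TRUE))) {
    cfg <- do.call(small_config, c(list(seed = 13L), variant))
    p <- ngnn_init(cfg)
    s <- suppress_ob(tiny_sample("CC(C)Br", "DMSO", 1.5))
    res <- ngnn_gradient_check(p, list(s), max_coords_per_bank = 10L)
    expect_lt(max(res$max_rel_err), 1e-4)
  }
})

test_that("compiled-kernel gradients pass the same finite-difference check", {
  p <- ngnn_init(small_config(seed = 7L))
  s <- suppress_ob(tiny_sample("CCO", "MeOH", 0.3))
  batch <- build_batch(list(s))
  flat <- as.numeric(flatten_params(p))
  ccfg <- cpp_config(p)
  cb <- cpp_batch(batch)
  got <- cpp_loss_grads(flat, ccfg, cb, batch$y, TRUE)
  eps <- 1e-5
  idx <- round(seq(1, length(flat), length.out = 60))
  for (i in idx) {
    fp <- flat; fp[i] <- fp[i] + eps
    fm <- flat; fm[i] <- fm[i] - eps
    num <- (cpp_loss_grads(fp, ccfg, cb, batch$y, FALSE)$loss -
              cpp_loss_grads(fm, ccfg, cb, batch$y, FALSE)$loss) / (2 * eps)
    expect_lt(abs(num - got$grads[i]) /
                max(abs(num) + abs(got$grads[i]), 1), 1e-4)
  }
})
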