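# The toy-data generator: grammars, closed-form target rules, reproducibility
# and the generator's own sanity oracles.

test_that("solute grammars emit unique parseable molecules deterministically", {
  for (fam in c("alkanes", "alcohols", "halides", "aromatics",
                "heteroaromatics")) {
    smis <- enumerate_solutes(fam, 5, seed = 3)
    expect_length(unique(smis), 5)
    for (s in smis) expect_s3_class(suppress_ob(parse_smiles(s)),
                                    "molecular_graph")
  }
  expect_identical(enumerate_solutes("alkanes", 4, seed = 9),
                   enumerate_solutes("alkanes", 4, seed = 9))
  expect_error(enumerate_solutes("alkanes", 10000, seed = 1), "unique")
  expect_error(enumerate_solutes("polymers", 1, seed = 1), "unknown")
  for (s in enumerate_solutes("halides", 10, seed = 2)) {
    g <- suppress_ob(parse_smiles(s))
    expect_gte(sum(g$elements %in% c("F", "Cl", "Br", "I")), 1)
  }
})

test_that("target rules are the documented closed forms", {
  reg <- suppress_ob(default_solvent_registry())
  benzene_w <- suppress_ob(build_sample("c1ccccc1", "H2O", 0))
  benzene_d <- suppress_ob(build_sample("c1ccccc1", "DMSO", 0))
  # solute_only ignores the solvent
  expect_equal(synth_target(benzene_w, "solute_only"),
               synth_target(benzene_d, "solute_only"))
  expect_equal(synth_target(benzene_w, "solute_only"), 5 * 6)
  # solvent_linear differences equal alpha * SdP differences
  sdp_w <- suppress_ob(lookup_solvent("H2O", reg))$polarity[["sdp"]]
  sdp_d <- suppress_ob(lookup_solvent("DMSO", reg))$polarity[["sdp"]]
  expect_equal(
    synth_target(benzene_d, "solvent_linear") -
      synth_target(benzene_w, "solvent_linear"),
    10 * (sdp_d - sdp_w)
  )
  # marked_sensitive is dominated by halogen count: CCl4 vs CH4 gap = 4 gamma
  ccl4 <- suppress_ob(build_sample("ClC(Cl)(Cl)Cl", "H2O", 0))
  ch4 <- suppress_ob(build_sample("C", "H2O", 0))
  expect_equal(synth_target(ccl4, "marked_sensitive") -
                 synth_target(ch4, "marked_sensitive"), 4 * 3)
  expect_error(synth_target(ch4, "no_such_rule"), "unknown")
})

test_that("generation is byte-reproducible and balanced over solvents", {
  spec <- toy_dataset_spec(n_samples = 100, noise_sd = 0, seed = 17)
  tf1 <- withr::local_tempfile(fileext = ".csv")
  tf2 <- withr::local_tempfile(fileext = ".csv")
  d1 <- suppress_ob(generate_toy_dataset(spec, tf1))
  d2 <- suppress_ob(generate_toy_dataset(spec, tf2))
  expect_identical(readLines(tf1), readLines(tf2))
  expect_equal(unname(table(d1$solvent)), rep(25L, 4), ignore_attr = TRUE)
  # noiseless targets recompute exactly from the rule
  samples <- suppress_ob(featurize_dataset(d1))
  recomputed <- vapply(samples, synth_target, numeric(1),
                       rule = "solvent_linear")
  expect_equal(d1$target, recomputed)
})

test_that("noise is additive on top of the exact rule values", {
  spec <- toy_dataset_spec(n_samples = 50, noise_sd = 0.5, seed = 23)
  d <- suppress_ob(generate_toy_dataset(spec))
  exact <- attr(d, "target_exact")
  resid <- d$target - exact
  expect_false(all(resid == 0))
  expect_lt(max(abs(resid)), 0.5 * 5)  # bounded Gaussian draws
})

test_that("OLS on the rule's own features explains noiseless targets exactly", {
  reg <- suppress_ob(default_solvent_registry())
  d <- suppress_ob(generate_toy_dataset(
    toy_dataset_spec(n_samples = 80, noise_sd = 0, seed = 29)))
  samples <- suppress_ob(featurize_dataset(d))
  X <- t(vapply(samples, function(s) {
    c(sdp = s$solvent_polarity[["sdp"]],
      arom = sum(s$solute$atom_state$aromatic),
      hal = sum(s$solute$elements %in% c("F", "Cl", "Br", "I")))
  }, numeric(3)))
  fit <- stats::lm(d$target ~ X)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # warns on an essentially perfect fit
  expect_gt(r2, 1 - 1e-12)
  expect_equal(unname(stats::coef(fit)[-1]), c(10, 5, 3), tolerance = 1e-8)
})

test_that("the solute-only ceiling is strictly below one and correctly ordered", {
  d <- suppress_ob(generate_toy_dataset(
    toy_dataset_spec(n_samples = 200, noise_sd = 0, seed = 31)))
  ceil0 <- solute_only_ceiling(d, noise_sd = 0)
  expect_lt(ceil0, 1)
  expect_gt(ceil0, 0)
  # more noise lowers the ceiling
  expect_lt(solute_only_ceiling(d, noise_sd = 2), ceil0)
  # a per-solute conditional-mean predictor attains (nearly) the ceiling
  exact <- attr(d, "target_exact")
  mu <- tapply(exact, d$solute_smiles, mean)
  pred <- as.numeric(mu[d$solute_smiles])
  r2 <- compute_metrics(pred, exact)$r2
  expect_equal(r2, ceil0, tolerance = 1e-10)
})
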