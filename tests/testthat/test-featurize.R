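# SMILES parsing, feature encodings, marking rules and the solvent registry.

test_that("parse_smiles builds correct heavy-atom graphs", {
  g <- suppress_ob(parse_smiles("C"))
  expect_equal(g$n_atoms, 1)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$atom_state$h_count, 4L)

  g <- suppress_ob(parse_smiles("CC"))
  expect_equal(g$n_atoms, 2)
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$bond_features[, 1] == 1))  # single both directions

  g <- suppress_ob(parse_smiles("c1ccccc1"))
  expect_equal(g$n_atoms, 6)
  expect_equal(nrow(g$edges), 12)
  expect_true(all(g$bond_features[, 6] == 1))  # aromatic
  expect_true(all(g$bond_features[, 7] == 1))  # ring
  expect_true(all(g$atom_state$aromatic == 1))
  expect_true(all(g$atom_state$valence == 4))
})

test_that("parse_smiles rejects bad inputs with informative errors", {
  expect_error(suppress_ob(parse_smiles("not a smiles !!")),
               class = "ngnn_bad_smiles")
  expect_error(suppress_ob(parse_smiles("CC.O")), class = "ngnn_bad_smiles")
  expect_error(suppress_ob(parse_smiles("[U]")),
               class = "ngnn_unknown_element")
})

test_that("directed edges come in symmetric pairs with equal features", {
  for (smi in c("CCO", "c1ccncc1", "CC(=O)OCC", "FC(F)(F)F")) {
    g <- suppress_ob(parse_smiles(smi))
    key <- paste(g$edges[, 1], g$edges[, 2])
    rev_key <- paste(g$edges[, 2], g$edges[, 1])
    idx <- match(rev_key, key)
    expect_false(anyNA(idx))
    expect_equal(g$bond_features, g$bond_features[idx, , drop = FALSE])
    expect_true(all(g$edges[, 1] != g$edges[, 2]))  # no self-loops
  }
})

test_that("two SMILES of one molecule give identical graphs after canonicalisation", {
  a <- suppress_ob(parse_smiles("OCC"))
  b <- suppress_ob(parse_smiles("CCO"))
  expect_identical(a$smiles, b$smiles)
  expect_identical(a$inherent, b$inherent)
  expect_identical(a$env, b$env)
  expect_identical(a$edges, b$edges)
})

test_that("encode_inherent returns the tabulated six constants in order", {
  v <- encode_inherent("C")
  expect_length(v, 6)
  expect_equal(unname(v["atomic_number"]), 6)
  row <- dplyr::filter(atomic_constants(), symbol == "C")
  expect_equal(unname(v), c(row$covalent_radius, row$electronegativity,
                            row$atomic_number, row$atomic_mass,
                            row$first_ionization_energy,
                            row$electron_affinity))
  expect_error(encode_inherent("Xx"), class = "ngnn_unknown_element")
})

test_that("environmental one-hot layout matches the documented block order", {
  v <- encode_environment(list(valence = 4, h_count = 4, formal_charge = 0,
                               hybridization = "sp3", in_ring = 0,
                               aromatic = 0))
  expect_length(v, 23)
  # valence 4 -> slot 5; h 4 -> slot 12; charge 0 is 5th listed -> slot 17;
  # sp3 is 4th -> slot 21
  expect_equal(which(v == 1), c(5L, 12L, 17L, 21L))
  expect_error(
    encode_environment(list(valence = 4, h_count = 0, formal_charge = -3,
                            hybridization = "sp3", in_ring = 0,
                            aromatic = 0)),
    class = "ngnn_bad_category"
  )
  expect_error(
    encode_environment(list(valence = 7, h_count = 0, formal_charge = 0,
                            hybridization = "sp3", in_ring = 0,
                            aromatic = 0)),
    class = "ngnn_bad_category"
  )
})

test_that("one-hot blocks each sum to one for parsed molecules", {
  for (smi in c("CCO", "c1ccsc1", "CC(=O)[O-]", "C#N")) {
    g <- suppress_ob(parse_smiles(smi))
    for (i in seq_len(g$n_atoms)) {
      v <- g$env[i, ]
      expect_equal(sum(v[1:7]), 1)     # valence
      expect_equal(sum(v[8:12]), 1)    # h count
      expect_equal(sum(v[13:17]), 1)   # charge
      expect_equal(sum(v[18:21]), 1)   # hybridization
      expect_true(all(v %in% c(0, 1)))
    }
  }
})

test_that("marking rules append exactly one flag and refuse reapplication", {
  g <- suppress_ob(parse_smiles("CCl"))
  m <- mark_atoms(g, "hydrophobic_halogen")
  expect_equal(as.numeric(m$custom_flags),
               as.numeric(m$elements %in% c("F", "Cl", "Br", "I")))
  expect_equal(sum(m$custom_flags), 1)  # exactly the chlorine
  expect_equal(ncol(env_features(m)), 24)
  expect_error(mark_atoms(m, "hydrophobic_halogen"),
               class = "ngnn_rule_reapplied")
  expect_error(mark_atoms(g, "no_such_rule"), class = "ngnn_unknown_rule")

  m2 <- mark_atoms(suppress_ob(parse_smiles("CCO")), "hydrophobic_halogen")
  expect_true(all(m2$custom_flags == 0))

  m3 <- mark_atoms(suppress_ob(parse_smiles("FC(F)(F)F")),
                   "hydrophobic_halogen")
  expect_equal(sum(m3$custom_flags), 4)  # the four fluorines
  expect_equal(as.numeric(m3$custom_flags),
               as.numeric(m3$elements == "F"))
})

test_that("solvent descriptors are length-66, finite and canonical-invariant", {
  w1 <- suppress_ob(compute_solvent_descriptors("O"))
  w2 <- suppress_ob(compute_solvent_descriptors("[OH2]"))
  expect_length(w1, 66)
  expect_true(all(is.finite(w1)))
  expect_equal(as.numeric(w1), as.numeric(w2))
  meoh <- suppress_ob(compute_solvent_descriptors("CO"))
  expect_true(any(as.numeric(w1) != as.numeric(meoh)))
  reg <- descriptor_registry()
  expect_equal(nrow(reg), 66)
  expect_setequal(unique(reg$family),
                  c("estate", "vsa", "topological", "connectivity"))
  expect_identical(names(w1), reg$name)
})

test_that("classical indices match literature values on reference molecules", {
  hexane <- suppress_ob(compute_solvent_descriptors("CCCCCC"))
  expect_equal(unname(hexane["chi1"]), 2.914214, tolerance = 1e-6)
  expect_equal(unname(hexane["wiener_index"]), 35)
  toluene <- suppress_ob(compute_solvent_descriptors("Cc1ccccc1"))
  expect_equal(unname(toluene["wiener_index"]), 42)
  benzene <- suppress_ob(compute_solvent_descriptors("c1ccccc1"))
  expect_equal(unname(benzene["chi1"]), 3)  # 6 bonds of (2*2)^-1/2
})

test_that("every bundled solvent resolves by name, alias and SMILES", {
  reg <- suppress_ob(default_solvent_registry())
  expect_equal(nrow(reg), 12)
  for (nm in c("toluene", "THF", "MeOH", "MeCN", "hexane", "H2O", "EtOH",
               "ethyl acetate", "DMSO", "DMF", "CHCl3", "CH2Cl2")) {
    hit <- suppress_ob(lookup_solvent(nm, reg))
    expect_length(hit$descriptors, 66)
    expect_length(hit$polarity, 5)
    expect_true(all(is.finite(hit$polarity)))
    expect_true(nzchar(hit$citation))
  }
  by_name <- suppress_ob(lookup_solvent("H2O", reg))
  by_alias <- suppress_ob(lookup_solvent("water", reg))
  by_smiles <- suppress_ob(lookup_solvent("O", reg))
  expect_identical(by_name$name, by_alias$name)
  expect_identical(by_name$name, by_smiles$name)
  expect_identical(by_name$descriptors, by_smiles$descriptors)
  expect_error(suppress_ob(lookup_solvent("unobtainium", reg)),
               class = "ngnn_unknown_solvent")
  # SMILES outside the registry: descriptors computable, polarity missing
  expect_error(suppress_ob(lookup_solvent("CCCCO", reg)),
               class = "ngnn_unknown_solvent")
  zf <- suppress_ob(lookup_solvent("CCCCO", reg,
                                   allow_missing_polarity = TRUE))
  expect_true(all(zf$polarity == 0))
  expect_length(zf$descriptors, 66)
})

test_that("build_sample composes solute, solvent and target with validation", {
  s <- suppress_ob(tiny_sample("CCO", "H2O", -0.77))
  expect_equal(s$solute$n_atoms, 3)
  expect_equal(s$target, -0.77)
  expect_equal(s$solvent_name, "H2O")
  expect_error(suppress_ob(tiny_sample("CCO", "H2O", NaN)),
               class = "ngnn_bad_target")
  s2 <- suppress_ob(tiny_sample("CCl", "H2O", 1.0,
                                rules = "hydrophobic_halogen"))
  expect_equal(sum(s2$solute$custom_flags), 1)
  expect_equal(s2$solute$custom_flags[s2$solute$elements == "Cl", 1], 1)
})

test_that("feature block widths follow the 6 + 23 + k contract", {
  for (rules in list(character(0), "hydrophobic_halogen")) {
    s <- suppress_ob(tiny_sample("CCl", "DMSO", 1, rules = rules))
    k <- length(rules)
    expect_equal(ncol(s$solute$inherent), 6)
    expect_equal(ncol(env_features(s$solute)), 23 + k)
    expect_equal(ncol(s$solute$bond_features), 7)
    expect_length(s$solvent_descriptors, 66)
    expect_length(s$solvent_polarity, 5)
  }
})

test_that("featurization is deterministic across repeated calls", {
  a <- suppress_ob(tiny_sample("Clc1ccccc1", "DMSO", 2.5))
  b <- suppress_ob(tiny_sample("Clc1ccccc1", "DMSO", 2.5))
  expect_identical(a$solute$inherent, b$solute$inherent)
  expect_identical(a$solute$env, b$solute$env)
  expect_identical(a$solute$bond_features, b$solute$bond_features)
  expect_identical(a$solvent_descriptors, b$solvent_descriptors)
})

test_that("dataset CSV reader enforces the exact header", {
  tf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(sample_id = "a", solute_smiles = "C",
                                  solvent = "H2O", target = 1), tf)
  expect_equal(nrow(read_dataset_csv(tf)), 1)
  readr::write_csv(tibble::tibble(id = "a", smiles = "C"), tf)
  expect_error(read_dataset_csv(tf), class = "ngnn_bad_dataset")
})
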