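# Deterministic toy datasets with closed-form targets. These emulate the
# tabular shape of solubility/spectroscopy datasets (solute SMILES, solvent,
# numeric property) with targets that are exact, documented functions of the
# features, so the whole train/evaluate loop is testable without any external
# download. They do not attempt to mimic real photophysics.

# target-rule constants: chosen once so the solvent and solute terms have
# comparable variance over the default pools; see the methods vignette
RULE_ALPHA <- 10  # weight of the solvent SdP (dipolarity) coordinate
RULE_BETA <- 5    # weight of the solute aromatic-atom count
RULE_GAMMA <- 3   # weight of the solute halogen-atom count

#' Built-in toy solute families
#'
#' Named enumerations of template SMILES (alkanes, alcohols, halides,
#' aromatics, heteroaromatics) that the toy-data generator draws from.
#'
#' @return Named list of character vectors of SMILES.
#' @export
solute_grammars <- function() {
  list(
    alkanes = c(
      "C", "CC", "CCC", "CCCC", "CC(C)C", "CCCCC", "CC(C)CC", "CC(C)(C)C",
      "CCCCCC", "CC(C)CCC", "CCC(C)CC", "CC(C)(C)CC", "CCCCCCC",
      "CC(C)CCCC", "CCCCCCCC", "CC(C)CCCCC", "CCC(CC)CCC", "CC(C)(C)CCC"
    ),
    alcohols = c(
      "CO", "CCO", "CCCO", "CC(C)O", "CCCCO", "CC(O)CC", "CC(C)(C)O",
      "CCCCCO", "OCCO", "CC(O)CO", "CCC(O)CC", "OCCCCO"
    ),
    halides = c(
      "CF", "CCl", "CBr", "CI", "CCF", "CCCl", "CCBr", "CCI",
      "FC(F)F", "ClC(Cl)Cl", "FC(F)(F)F", "ClC(Cl)(Cl)Cl",
      "CC(Cl)C", "CC(Br)C", "FCCF", "ClCCCl", "BrCCBr", "CCC(F)(F)F"
    ),
    aromatics = c(
      "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Cc1ccccc1C", "Cc1cccc(C)c1",
      "Cc1ccc(C)cc1", "Oc1ccccc1", "COc1ccccc1", "Clc1ccccc1", "Fc1ccccc1",
      "Brc1ccccc1", "Cc1ccc(O)cc1", "Clc1ccc(Cl)cc1", "CC(C)c1ccccc1"
    ),
    heteroaromatics = c(
      "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1cc[nH]c1", "c1cncnc1",
      "Cc1ccncc1", "Cc1ccco1", "Cc1cccs1", "c1ccc2ncccc2c1", "Cc1cncnc1"
    )
  )
}

#' Enumerate toy solute molecules from a named family
#'
#' Draws `n` unique, parseable SMILES from one of the built-in template
#' families (`alkanes`, `alcohols`, `halides`, `aromatics`,
#' `heteroaromatics`), deterministically for a fixed seed.
#'
#' @param grammar Family name.
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @return Character vector of `n` unique SMILES.
#' @export
enumerate_solutes <- function(grammar, n, seed = 1L) {
  fams <- solute_grammars()
  if (!grammar %in% names(fams)) {
    ngnn_abort(sprintf("unknown solute grammar '%s' (available: %s)",
                       grammar, paste(names(fams), collapse = ", ")))
  }
  pool <- fams[[grammar]]
  if (n > length(pool)) {
    ngnn_abort(sprintf(
      "grammar '%s' holds %d unique molecules; %d requested",
      grammar, length(pool), n
    ))
  }
  with_seed(sub_seed(seed, 5L), sample(pool, n))
}

count_aromatic_atoms <- function(graph) sum(graph$atom_state$aromatic)
count_halogen_atoms <- function(graph) sum(graph$elements %in% HALOGENS)

#' Closed-form toy target value for a dissolved sample
#'
#' Built-in rules (constants alpha = 10, beta = 5, gamma = 3):
#' * `"solvent_linear"`: `y = alpha * SdP(solvent) + beta * n_aromatic_atoms
#'   + gamma * n_halogen_atoms` — a solvent-sensitive linear property.
#' * `"solute_only"`: `y = beta * n_aromatic_atoms + gamma * n_halogen_atoms`
#'   — independent of the solvent (ablation control).
#' * `"marked_sensitive"`: `y = gamma * n_halogen_atoms` — dominated by the
#'   halogen count, exercising the atom-marking experiment at toy scale.
#'
#' Noise is never added here; the dataset generator adds it at assembly.
#'
#' @param sample A `dissolved_sample`.
#' @param rule Rule name.
#' @return Exact numeric target value.
#' @export
synth_target <- function(sample, rule) {
  g <- sample$solute
  switch(rule,
    solvent_linear = RULE_ALPHA * sample$solvent_polarity[["sdp"]] +
      RULE_BETA * count_aromatic_atoms(g) +
      RULE_GAMMA * count_halogen_atoms(g),
    solute_only = RULE_BETA * count_aromatic_atoms(g) +
      RULE_GAMMA * count_halogen_atoms(g),
    marked_sensitive = RULE_GAMMA * count_halogen_atoms(g),
    ngnn_abort(sprintf("unknown target rule '%s'", rule))
  )
}

#' Specification of a toy dataset
#'
#' @param n_samples Number of rows.
#' @param solvent_pool Registry solvent names; defaults to four chemically
#'   spread solvents (water, hexane, DMSO, toluene) maximising the polarity
#'   spread.
#' @param solute_grammars Families sampled from (solutes are drawn with
#'   replacement across the union of the families' pools).
#' @param target_rule One of the [synth_target()] rules.
#' @param noise_sd Standard deviation of additive Gaussian noise on targets.
#' @param seed Integer seed.
#' @return A `toy_dataset_spec` list.
#' @export
toy_dataset_spec <- function(n_samples = 100L,
                             solvent_pool = c("H2O", "hexane", "DMSO",
                                              "toluene"),
                             solute_grammars = c("alkanes", "alcohols",
                                                 "halides", "aromatics",
                                                 "heteroaromatics"),
                             target_rule = "solvent_linear",
                             noise_sd = 0,
                             seed = 1L) {
  stopifnot(n_samples >= 1, length(solvent_pool) >= 1, noise_sd >= 0)
  structure(
    list(n_samples = as.integer(n_samples), solvent_pool = solvent_pool,
         solute_grammars = solute_grammars, target_rule = target_rule,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "toy_dataset_spec"
  )
}

#' Generate a toy dataset
#'
#' Solutes are drawn with replacement from the union of the requested
#' grammars; solvents are assigned round-robin (each pool solvent appears
#' `n_samples / pool size` times, up to remainder) and then shuffled by the
#' seed; targets are the exact rule value plus `N(0, noise_sd)` noise. Fully
#' reproducible: the same spec yields a byte-identical table.
#'
#' @param spec A [toy_dataset_spec()].
#' @param path Optional CSV output path (written with the pipeline's
#'   `sample_id,solute_smiles,solvent,target` header).
#' @return A tibble with columns `sample_id`, `solute_smiles`, `solvent`,
#'   `target`, plus `target_exact` (noise-free value) as attribute
#'   `"target_exact"`.
#' @export
generate_toy_dataset <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "toy_dataset_spec"))
  pool <- unique(unlist(solute_grammars()[spec$solute_grammars]))
  n <- spec$n_samples
  solutes <- with_seed(sub_seed(spec$seed, 6L),
                       sample(pool, n, replace = TRUE))
  solvents <- rep_len(spec$solvent_pool, n)
  solvents <- with_seed(sub_seed(spec$seed, 7L), sample(solvents))
  registry <- default_solvent_registry()
  exact <- vapply(seq_len(n), function(i) {
    s <- build_sample(solutes[i], solvents[i], 0, registry = registry,
                      sample_id = as.character(i))
    synth_target(s, spec$target_rule)
  }, numeric(1))
  noise <- if (spec$noise_sd > 0) {
    with_seed(sub_seed(spec$seed, 8L), stats::rnorm(n, 0, spec$noise_sd))
  } else {
    numeric(n)
  }
  out <- tibble::tibble(
    sample_id = sprintf("toy-%05d", seq_len(n)),
    solute_smiles = solutes,
    solvent = solvents,
    target = exact + noise
  )
  attr(out, "target_exact") <- exact
  if (!is.null(path)) {
    readr::write_csv(out, path, progress = FALSE)
  }
  out
}

#' Closed-form ceiling of a solute-only predictor on a toy dataset
#'
#' Under a solvent-sensitive rule, the best predictor that ignores the
#' solvent is the per-solute conditional mean; its residual variance is the
#' within-solute (solvent-term) variance plus the noise variance. The
#' attainable R-squared ceiling is therefore
#' `1 - (V_within + noise_sd^2) / (V_total + noise_sd^2)`, computed exactly
#' from the generator's noise-free values.
#'
#' @param dataset A tibble from [generate_toy_dataset()] (must carry the
#'   `target_exact` attribute).
#' @param noise_sd The generating noise standard deviation.
#' @return A single numeric ceiling in (0, 1].
#' @export
solute_only_ceiling <- function(dataset, noise_sd = 0) {
  exact <- attr(dataset, "target_exact")
  if (is.null(exact)) {
    ngnn_abort("dataset lacks the target_exact attribute; regenerate it")
  }
  mu <- tapply(exact, dataset$solute_smiles, mean)
  within <- mean((exact - as.numeric(mu[dataset$solute_smiles]))^2)
  total <- mean((exact - mean(exact))^2)
  1 - (within + noise_sd^2) / (total + noise_sd^2)
}
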