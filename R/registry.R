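# Solvent registry: per-solvent descriptor (66-dim) and polarity (5-dim)
# records, resolvable by conventional name, alias or canonical SMILES.

#' The bundled solvent registry
#'
#' Loads the shipped solvent table (name, SMILES, Et(30) in kcal/mol and the
#' Catalan polarity scales SP/SdP/SA/SB, with literature citations), computes
#' the 66 whole-molecule descriptors for every entry and caches the result.
#' Covers the 12 solvents of the multi-solvent spectroscopic datasets
#' (toluene, THF, MeOH, MeCN, hexane, H2O, EtOH, ethyl acetate, DMSO, DMF,
#' CHCl3, CH2Cl2).
#'
#' @return An object of class `solvent_registry`: a tibble of entries plus a
#'   descriptor matrix attribute.
#' @export
default_solvent_registry <- function() {
  if (!is.null(.ngnn_env$registry)) return(.ngnn_env$registry)
  path <- system.file("extdata", "solvent_polarity.tsv", package = "ngnn")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$canonical_smiles <- vapply(tab$smiles, ob_canonical, character(1))
  desc <- t(vapply(tab$canonical_smiles, compute_solvent_descriptors,
                   numeric(66)))
  rownames(desc) <- tab$name
  reg <- structure(
    tab,
    descriptors = desc,
    registry_version = descriptor_registry_version(),
    class = c("solvent_registry", class(tab))
  )
  .ngnn_env$registry <- reg
  reg
}

#' Resolve a solvent identifier to its descriptor and polarity vectors
#'
#' The identifier may be a registered name (e.g. `"DMSO"`), a registered alias
#' (`"water"`), or a SMILES string; name- and SMILES-based lookup of the same
#' solvent return the same entry. A SMILES not present in the registry gets
#' its descriptors computed on the fly; its polarity parameters are unknown
#' and this is an error unless `allow_missing_polarity = TRUE`, in which case
#' they are zero-filled.
#'
#' @param identifier Solvent name, alias or SMILES.
#' @param registry A `solvent_registry` (default: the bundled one).
#' @param allow_missing_polarity Zero-fill the 5 polarity values for solvents
#'   outside the registry instead of erroring.
#' @return List with elements `name`, `smiles`, `descriptors` (length 66),
#'   `polarity` (named length 5: et30, sp, sdp, sa, sb), `citation`.
#' @export
lookup_solvent <- function(identifier, registry = default_solvent_registry(),
                           allow_missing_polarity = FALSE) {
  stopifnot(is.character(identifier), length(identifier) == 1)
  tab <- registry
  idx <- which(tolower(tab$name) == tolower(identifier))
  if (!length(idx)) {
    alias_hit <- vapply(tab$aliases, function(a) {
      tolower(identifier) %in% tolower(trimws(strsplit(a, ",")[[1]]))
    }, logical(1))
    idx <- which(alias_hit)
  }
  if (!length(idx)) {
    canon <- tryCatch(ob_canonical(identifier), error = function(e) NA_character_)
    if (!is.na(canon)) idx <- which(tab$canonical_smiles == canon)
    if (!length(idx)) {
      if (!is.na(canon) && allow_missing_polarity) {
        return(list(
          name = canon, smiles = canon,
          descriptors = compute_solvent_descriptors(canon),
          polarity = c(et30 = 0, sp = 0, sdp = 0, sa = 0, sb = 0),
          citation = NA_character_
        ))
      }
      if (!is.na(canon)) {
        ngnn_abort(sprintf(
          "solvent '%s' parsed but has no polarity record in the registry (set allow_missing_polarity = TRUE to zero-fill)",
          identifier
        ), class = "ngnn_unknown_solvent")
      }
      ngnn_abort(sprintf("unknown solvent '%s'", identifier),
                 class = "ngnn_unknown_solvent")
    }
  }
  idx <- idx[1]
  list(
    name = tab$name[idx],
    smiles = tab$canonical_smiles[idx],
    descriptors = attr(registry, "descriptors")[idx, ],
    polarity = c(et30 = tab$et30[idx], sp = tab$sp[idx], sdp = tab$sdp[idx],
                 sa = tab$sa[idx], sb = tab$sb[idx]),
    citation = tab$citation[idx]
  )
}

#' Assemble a dissolved sample: solute graph + solvent vectors + target
#'
#' @param solute_smiles SMILES of the solute.
#' @param solvent_id Solvent name, alias or SMILES (see [lookup_solvent()]).
#' @param target Finite numeric property value (units per task).
#' @param marking_rules Character vector of marking rules to apply to the
#'   solute, in order.
#' @param registry Solvent registry.
#' @param sample_id Optional identifier carried through predictions.
#' @return An object of class `dissolved_sample`.
#' @export
build_sample <- function(solute_smiles, solvent_id, target,
                         marking_rules = character(0),
                         registry = default_solvent_registry(),
                         sample_id = NA_character_) {
  if (!is.numeric(target) || length(target) != 1 || !is.finite(target)) {
    ngnn_abort(sprintf(
      "sample '%s': target must be a finite number (got %s)",
      sample_id %||% solute_smiles, format(target)
    ), class = "ngnn_bad_target")
  }
  graph <- parse_smiles(solute_smiles)
  for (rule in marking_rules) graph <- mark_atoms(graph, rule)
  solv <- lookup_solvent(solvent_id, registry)
  structure(
    list(
      sample_id = sample_id,
      solute = graph,
      solvent_name = solv$name,
      solvent_descriptors = solv$descriptors,
      solvent_polarity = solv$polarity,
      target = target
    ),
    class = "dissolved_sample"
  )
}

#' @export
print.dissolved_sample <- function(x, ...) {
  cat(sprintf("<dissolved_sample> %s in %s, target = %g\n",
              x$solute$smiles, x$solvent_name, x$target))
  invisible(x)
}

#' Read a dataset CSV of (solute, solvent, target) rows
#'
#' Expects exactly the header `sample_id,solute_smiles,solvent,target`.
#'
#' @param path CSV path.
#' @return A tibble with those four columns.
#' @export
read_dataset_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c("sample_id", "solute_smiles", "solvent", "target")
  if (!identical(names(df), expected)) {
    ngnn_abort(sprintf(
      "dataset header must be exactly '%s' (got '%s')",
      paste(expected, collapse = ","), paste(names(df), collapse = ",")
    ), class = "ngnn_bad_dataset")
  }
  df
}

#' Featurize a dataset tibble into dissolved samples
#'
#' Vectorised, caching wrapper around [build_sample()]: identical solute
#' SMILES are parsed once. Errors are reported with the offending row's
#' `sample_id`.
#'
#' @param data Tibble with columns `sample_id`, `solute_smiles`, `solvent`,
#'   `target`.
#' @param marking_rules Marking rules applied to every solute.
#' @param registry Solvent registry.
#' @return List of `dissolved_sample` objects.
#' @export
featurize_dataset <- function(data, marking_rules = character(0),
                              registry = default_solvent_registry()) {
  stopifnot(all(c("sample_id", "solute_smiles", "solvent", "target") %in%
                  names(data)))
  graph_cache <- new.env(parent = emptyenv())
  solv_cache <- new.env(parent = emptyenv())
  purrr::map(seq_len(nrow(data)), function(i) {
    sid <- as.character(data$sample_id[i])
    tryCatch({
      key <- data$solute_smiles[i]
      g <- graph_cache[[key]]
      if (is.null(g)) {
        g <- parse_smiles(key)
        for (rule in marking_rules) g <- mark_atoms(g, rule)
        graph_cache[[key]] <- g
      }
      sv <- solv_cache[[data$solvent[i]]]
      if (is.null(sv)) {
        sv <- lookup_solvent(data$solvent[i], registry)
        solv_cache[[data$solvent[i]]] <- sv
      }
      tgt <- data$target[i]
      if (!is.finite(tgt)) {
        ngnn_abort("target must be a finite number", class = "ngnn_bad_target")
      }
      structure(
        list(sample_id = sid, solute = g, solvent_name = sv$name,
             solvent_descriptors = sv$descriptors,
             solvent_polarity = sv$polarity, target = tgt),
        class = "dissolved_sample"
      )
    }, error = function(e) {
      ngnn_abort(sprintf("sample '%s' (row %d): %s", sid, i,
                         conditionMessage(e)),
                 class = "ngnn_featurize_error")
    })
  })
}
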