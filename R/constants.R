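#' Bundled periodic-table constants
#'
#' Returns the table of per-element physical constants used for inherent atom
#' features and for descriptor computation: covalent radius (Angstrom, Cordero
#' consensus values), Pauling electronegativity, atomic number, atomic mass
#' (amu), first ionization energy (eV), electron affinity (eV), plus auxiliary
#' columns (van der Waals radius, valence-electron count, principal quantum
#' number) used internally by the solvent descriptor engine.
#'
#' Any element present in this table is usable even if it never occurs in a
#' training set; elements absent from it are rejected at parse time.
#'
#' @return A tibble with one row per supported element.
#' @export
atomic_constants <- function() {
  if (is.null(.ngnn_env$atomic_constants)) {
    path <- system.file("extdata", "atomic_constants.tsv", package = "ngnn")
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    .ngnn_env$atomic_constants <- tab
  }
  .ngnn_env$atomic_constants
}

# fast named lookup: list of one-row lists keyed by symbol
atomic_constants_map <- function() {
  if (is.null(.ngnn_env$atomic_map)) {
    tab <- atomic_constants()
    m <- split(tab, tab$symbol)
    .ngnn_env$atomic_map <- m
  }
  .ngnn_env$atomic_map
}

#' Inherent atomic features for one element
#'
#' The six element-level constants, in fixed order: covalent radius,
#' electronegativity, atomic number, atomic mass, first ionization energy,
#' electron affinity. These are encoded "naturally" (as their physical values),
#' not one-hot, so the model can interpolate to elements unseen in training.
#'
#' @param element_symbol Element symbol, e.g. `"C"`.
#' @return Named numeric vector of length 6.
#' @export
encode_inherent <- function(element_symbol) {
  row <- atomic_constants_map()[[element_symbol]]
  if (is.null(row)) {
    ngnn_abort(sprintf(
      "element '%s' is not in the bundled constants table", element_symbol
    ), class = "ngnn_unknown_element")
  }
  c(
    covalent_radius = row$covalent_radius,
    electronegativity = row$electronegativity,
    atomic_number = as.numeric(row$atomic_number),
    atomic_mass = row$atomic_mass,
    first_ionization_energy = row$first_ionization_energy,
    electron_affinity = row$electron_affinity
  )
}

#' The descriptor registry
#'
#' Identity and definition of the 66 whole-molecule solvent descriptors, in
#' registry order, spanning four families: electrotopological state (E-state),
#' VSA-type surface-area contributions, topological indices and connectivity
#' indices.
#'
#' @return A tibble with columns `index`, `family`, `name`, `definition`.
#' @export
descriptor_registry <- function() {
  if (is.null(.ngnn_env$descriptor_registry)) {
    path <- system.file("extdata", "descriptor_registry.tsv", package = "ngnn")
    .ngnn_env$descriptor_registry <-
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  .ngnn_env$descriptor_registry
}

#' @rdname descriptor_registry
#' @export
descriptor_registry_version <- function() "ngnn-descriptors-1.0"
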