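# SMILES -> heavy-atom molecular graph with multiscale raw feature blocks.
#
# Structure perception is delegated to OpenBabel (via ChemmineOB) and
# ChemmineR: canonicalisation, implicit-hydrogen completion, kekulized bond
# orders and ring/aromaticity perception. The featurization conventions on top
# (hybridization, conjugation, one-hot layouts) are this package's own and are
# documented in the methods vignette.

HALOGENS <- c("F", "Cl", "Br", "I")

ob_canonical <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- trimws(gsub("[\t\n].*$", "", out))
  if (!nzchar(out)) {
    ngnn_abort(sprintf("unparsable SMILES: '%s'", smiles),
               class = "ngnn_bad_smiles")
  }
  out
}

# raw V2000 molblock text (explicit H added) -> parsed pieces
ob_molblock <- function(smiles) {
  txt <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "SDF", smiles, options = data.frame(names = "h", args = "")
  ))
  if (!nzchar(trimws(txt))) {
    ngnn_abort(sprintf("unparsable SMILES: '%s'", smiles),
               class = "ngnn_bad_smiles")
  }
  txt
}

parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (n_bonds > 0) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    cbind(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    matrix(integer(0), 0, 3, dimnames = list(NULL, c("a1", "a2", "order")))
  }
  # formal charges from M  CHG property lines
  charge <- rep(0L, n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    nn <- fields[1]
    for (k in seq_len(nn)) {
      charge[fields[2 * k]] <- fields[2 * k + 1]
    }
  }
  list(elements = elements, bonds = bonds, charge = charge)
}

# all rings + aromatic flags on the heavy-atom graph (indices into heavy atoms)
perceive_rings <- function(n, edges_undirected, elements, orders) {
  ring_atom <- logical(n)
  arom_atom <- logical(n)
  ring_bond <- logical(nrow(edges_undirected))
  arom_bond <- logical(nrow(edges_undirected))
  if (n < 3 || nrow(edges_undirected) == 0) {
    return(list(ring_atom = ring_atom, arom_atom = arom_atom,
                ring_bond = ring_bond, arom_bond = arom_bond))
  }
  g <- igraph::graph_from_edgelist(edges_undirected, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  # bonds lying on cycles: removing a non-ring (bridge) edge disconnects
  bridges <- igraph::bridges(g)
  ring_bond <- !(seq_len(nrow(edges_undirected)) %in% as.integer(bridges))
  ring_atom[unique(as.vector(edges_undirected[ring_bond, , drop = FALSE]))] <- TRUE

  # aromaticity: smallest rings in which every atom is sp2-capable and the
  # ring pi-electron count satisfies Hueckel 4m+2 under the kekulized orders
  key <- paste(pmin(edges_undirected[, 1], edges_undirected[, 2]),
               pmax(edges_undirected[, 1], edges_undirected[, 2]))
  bond_of <- stats::setNames(seq_along(key), key)
  deg <- tabulate(as.vector(edges_undirected), nbins = n)
  for (cyc in find_rings(n, edges_undirected, max_size = 7)) {
    m <- length(cyc)
    nxt <- c(cyc[-1], cyc[1])
    bidx <- bond_of[paste(pmin(cyc, nxt), pmax(cyc, nxt))]
    # pi electrons: atom in an in-ring double bond contributes 1; an exocyclic
    # double bond contributes 0 (sp2 but no ring pi electron, e.g. quinones);
    # else a heteroatom lone pair contributes 2; an sp3 carbon breaks aromaticity
    pi_e <- 0
    ok <- TRUE
    for (idx in seq_len(m)) {
      a <- cyc[idx]
      incident <- which(edges_undirected[, 1] == a | edges_undirected[, 2] == a)
      dbl_in_ring <- any(orders[intersect(incident, bidx)] == 2)
      dbl_any <- any(orders[incident] == 2)
      if (dbl_in_ring) {
        pi_e <- pi_e + 1
      } else if (dbl_any) {
        pi_e <- pi_e + 0
      } else if (elements[a] %in% c("N", "O", "S", "P", "Se", "Te")) {
        pi_e <- pi_e + 2
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok && pi_e %% 4 == 2) {
      arom_atom[cyc] <- TRUE
      arom_bond[bidx] <- TRUE
    }
  }
  list(ring_atom = ring_atom, arom_atom = arom_atom,
       ring_bond = ring_bond, arom_bond = arom_bond)
}

# enumerate simple cycles up to max_size atoms (molecules here are small)
find_rings <- function(n, edges_undirected, max_size = 7) {
  g <- igraph::graph_from_edgelist(edges_undirected, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  rings <- list()
  seen <- character(0)
  adj <- igraph::as_adj_list(g)
  for (start in seq_len(n)) {
    stack <- list(c(start))
    while (length(stack)) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (nb in as.integer(adj[[last]])) {
        if (nb == start && length(path) >= 3) {
          key <- paste(sort(path), collapse = ",")
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            rings[[length(rings) + 1]] <- path
          }
        } else if (!(nb %in% path) && length(path) < max_size && nb > start) {
          stack[[length(stack) + 1]] <- c(path, nb)
        }
      }
    }
  }
  rings
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Builds the raw multiscale feature blocks of one molecule: per-atom inherent
#' constants (natural coding), per-atom environmental one-hots
#' (valence, H count, formal charge, hybridization, ring/aromatic flags) and
#' per-directed-edge bond one-hots (type, conjugation, aromatic, ring).
#' Hydrogens are implicit: they enter only through the H-count block. The atom
#' order follows the parser's canonical ranking (the string is canonicalised
#' first), so two SMILES of the same molecule give identical graphs.
#'
#' Every chemical bond appears twice, once per direction, with identical
#' features. Indices are 1-based.
#'
#' @param smiles A valid single-fragment SMILES string.
#' @return An object of class `molecular_graph`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, !is.na(smiles))
  canon <- ob_canonical(smiles)
  if (grepl(".", canon, fixed = TRUE)) {
    ngnn_abort(sprintf(
      "multi-fragment SMILES not supported (dissolved-graph message passing is defined for connected solutes): '%s'",
      smiles
    ), class = "ngnn_bad_smiles")
  }
  mol <- parse_molblock(ob_molblock(canon))

  heavy <- which(mol$elements != "H")
  unknown <- setdiff(unique(mol$elements[heavy]), atomic_constants()$symbol)
  if (length(unknown)) {
    ngnn_abort(sprintf(
      "element(s) outside the bundled constants table: %s",
      paste(unknown, collapse = ", ")
    ), class = "ngnn_unknown_element")
  }
  n <- length(heavy)
  new_idx <- integer(length(mol$elements))
  new_idx[heavy] <- seq_len(n)
  elements <- mol$elements[heavy]
  charge <- mol$charge[heavy]

  b <- mol$bonds
  is_h_bond <- mol$elements[b[, "a1"]] == "H" | mol$elements[b[, "a2"]] == "H"
  h_count <- integer(n)
  if (any(is_h_bond)) {
    hb <- b[is_h_bond, , drop = FALSE]
    for (r in seq_len(nrow(hb))) {
      hv <- if (mol$elements[hb[r, "a1"]] == "H") hb[r, "a2"] else hb[r, "a1"]
      if (mol$elements[hv] != "H") h_count[new_idx[hv]] <- h_count[new_idx[hv]] + 1L
    }
  }
  hb_heavy <- b[!is_h_bond, , drop = FALSE]
  eu <- cbind(new_idx[hb_heavy[, "a1"]], new_idx[hb_heavy[, "a2"]])
  orders <- hb_heavy[, "order"]
  if (nrow(eu) > 0 && any(eu[, 1] == eu[, 2])) {
    ngnn_abort("self-loop bond in parsed structure", class = "ngnn_bad_smiles")
  }

  rg <- perceive_rings(n, eu, elements, orders)

  # per-atom valence: sum of kekulized bond orders including bonds to H
  valence <- h_count
  if (nrow(eu) > 0) {
    for (r in seq_len(nrow(eu))) {
      valence[eu[r, 1]] <- valence[eu[r, 1]] + orders[r]
      valence[eu[r, 2]] <- valence[eu[r, 2]] + orders[r]
    }
  }

  # hybridization from aromaticity and kekulized multiplicities
  n_double <- n_triple <- integer(n)
  if (nrow(eu) > 0) {
    for (r in seq_len(nrow(eu))) {
      if (orders[r] == 2) {
        n_double[eu[r, 1]] <- n_double[eu[r, 1]] + 1L
        n_double[eu[r, 2]] <- n_double[eu[r, 2]] + 1L
      } else if (orders[r] == 3) {
        n_triple[eu[r, 1]] <- n_triple[eu[r, 1]] + 1L
        n_triple[eu[r, 2]] <- n_triple[eu[r, 2]] + 1L
      }
    }
  }
  hybridization <- ifelse(
    rg$arom_atom, "sp2",
    ifelse(n_triple > 0 | n_double >= 2, "sp",
           ifelse(n_double > 0, "sp2", "sp3"))
  )

  # conjugation: pi participants and lone-pair donors
  pi_part <- n_double > 0 | n_triple > 0 | rg$arom_atom
  lp_donor <- elements %in% c("N", "O", "S", "P", HALOGENS) & charge <= 0
  conj <- logical(nrow(eu))
  if (nrow(eu) > 0) {
    nbr <- vector("list", n)
    for (r in seq_len(nrow(eu))) {
      nbr[[eu[r, 1]]] <- c(nbr[[eu[r, 1]]], eu[r, 2])
      nbr[[eu[r, 2]]] <- c(nbr[[eu[r, 2]]], eu[r, 1])
    }
    for (r in seq_len(nrow(eu))) {
      i <- eu[r, 1]; j <- eu[r, 2]
      if (rg$arom_bond[r]) {
        conj[r] <- TRUE
      } else if (orders[r] >= 2) {
        others <- setdiff(c(nbr[[i]], nbr[[j]]), c(i, j))
        conj[r] <- any(pi_part[others] | lp_donor[others])
      } else {
        conj[r] <- (pi_part[i] || lp_donor[i]) &&
          (pi_part[j] || lp_donor[j]) && (pi_part[i] || pi_part[j])
      }
    }
  }

  atom_state <- tibble::tibble(
    element = elements,
    valence = as.integer(valence),
    h_count = as.integer(h_count),
    formal_charge = as.integer(charge),
    hybridization = hybridization,
    in_ring = as.integer(rg$ring_atom),
    aromatic = as.integer(rg$arom_atom)
  )

  inherent <- t(vapply(elements, encode_inherent, numeric(6)))
  rownames(inherent) <- NULL
  env <- t(vapply(seq_len(n), function(i) {
    encode_environment(as.list(atom_state[i, ]), integer(0))
  }, numeric(23)))
  rownames(env) <- NULL
  if (n == 1 && is.null(dim(env))) env <- matrix(env, 1, 23)

  # directed duplication of bonds, identical features per direction
  if (nrow(eu) > 0) {
    bond_type <- ifelse(rg$arom_bond, "aromatic",
                        c("single", "double", "triple")[orders])
    bf1 <- t(vapply(seq_len(nrow(eu)), function(r) {
      encode_bond(bond_type[r], conj[r], rg$arom_bond[r], rg$ring_bond[r])
    }, numeric(7)))
    edges <- rbind(eu, eu[, 2:1, drop = FALSE])
    bond_features <- rbind(bf1, bf1)
  } else {
    edges <- matrix(integer(0), 0, 2)
    bond_features <- matrix(numeric(0), 0, 7)
  }
  colnames(edges) <- c("src", "dst")

  structure(
    list(
      smiles = canon,
      n_atoms = n,
      elements = elements,
      atom_state = atom_state,
      inherent = inherent,
      env = env,
      custom_flags = matrix(numeric(0), n, 0),
      marking_rules = character(0),
      edges = edges,
      bond_features = bond_features
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf(
    "<molecular_graph> %s: %d heavy atoms, %d directed edges, %d marking rule(s)\n",
    x$smiles, x$n_atoms, nrow(x$edges), length(x$marking_rules)
  ))
  invisible(x)
}

# one-hot layout of the environmental block (offsets are part of the contract)
ENV_VALENCE <- 0:6
ENV_HCOUNT <- 0:4
ENV_CHARGE <- c(-1L, -2L, 1L, 2L, 0L)
ENV_HYBRID <- c("s", "sp", "sp2", "sp3")

#' One-hot encode the environmental state of one atom
#'
#' Concatenates, in fixed order: valence (7 categories, 0-6), H count
#' (5, 0-4), formal charge (5, in the listed order -1, -2, 1, 2, 0),
#' hybridization (4: s, sp, sp2, sp3), an in-ring bit, an aromatic bit, then
#' any custom marking flags. Total length 23 + k.
#'
#' @param atom_state List or one-row data frame with fields `valence`,
#'   `h_count`, `formal_charge`, `hybridization`, `in_ring`, `aromatic`.
#' @param custom_flags Numeric 0/1 vector of task-defined marking bits
#'   (possibly length 0).
#' @return Numeric 0/1 vector of length `23 + length(custom_flags)`.
#' @export
encode_environment <- function(atom_state, custom_flags = integer(0)) {
  onehot <- function(value, categories, field) {
    pos <- match(value, categories)
    if (is.na(pos)) {
      ngnn_abort(sprintf(
        "atom field '%s' value '%s' outside its category set (%s)",
        field, value, paste(categories, collapse = ", ")
      ), class = "ngnn_bad_category")
    }
    v <- numeric(length(categories))
    v[pos] <- 1
    v
  }
  bit <- function(value, field) {
    if (!value %in% c(0, 1)) {
      ngnn_abort(sprintf("atom field '%s' must be 0/1", field),
                 class = "ngnn_bad_category")
    }
    as.numeric(value)
  }
  if (length(custom_flags) && !all(custom_flags %in% c(0, 1))) {
    ngnn_abort("custom flags must be 0/1", class = "ngnn_bad_category")
  }
  c(
    onehot(atom_state$valence, ENV_VALENCE, "valence"),
    onehot(atom_state$h_count, ENV_HCOUNT, "h_count"),
    onehot(atom_state$formal_charge, ENV_CHARGE, "formal_charge"),
    onehot(atom_state$hybridization, ENV_HYBRID, "hybridization"),
    bit(atom_state$in_ring, "in_ring"),
    bit(atom_state$aromatic, "aromatic"),
    as.numeric(custom_flags)
  )
}

BOND_TYPES <- c("single", "double", "triple", "aromatic")

encode_bond <- function(type, conjugated, aromatic, ring) {
  v <- numeric(4)
  v[match(type, BOND_TYPES)] <- 1
  c(v, as.numeric(conjugated), as.numeric(aromatic), as.numeric(ring))
}

#' Full environmental feature matrix of a graph (base block + marking flags)
#'
#' @param graph A `molecular_graph`.
#' @return Numeric matrix `n_atoms x (23 + k)`.
#' @export
env_features <- function(graph) {
  cbind(graph$env, graph$custom_flags)
}

# ---- atom marking rules -----------------------------------------------------

marking_rules_registry <- function() {
  if (is.null(.ngnn_env$marking_rules)) {
    .ngnn_env$marking_rules <- list(
      # hydrophobic halogens, relevant e.g. for aqueous solubility
      hydrophobic_halogen = function(graph) {
        as.numeric(graph$elements %in% HALOGENS)
      }
    )
  }
  .ngnn_env$marking_rules
}

#' Label task-relevant atoms with a custom marking flag
#'
#' Appends exactly one 0/1 custom flag column per applied rule to the graph's
#' environmental features. The built-in rule `"hydrophobic_halogen"` marks
#' F, Cl, Br and I atoms (hydrophobic groups relevant to water-solubility
#' prediction). Reapplying a rule already present is an error.
#'
#' @param graph A `molecular_graph`.
#' @param rule_name Name of a registered marking rule.
#' @return The graph with one appended custom flag column.
#' @export
mark_atoms <- function(graph, rule_name) {
  stopifnot(inherits(graph, "molecular_graph"))
  rules <- marking_rules_registry()
  if (!rule_name %in% names(rules)) {
    ngnn_abort(sprintf("unknown marking rule '%s'", rule_name),
               class = "ngnn_unknown_rule")
  }
  if (rule_name %in% graph$marking_rules) {
    ngnn_abort(sprintf("marking rule '%s' already applied", rule_name),
               class = "ngnn_rule_reapplied")
  }
  flags <- rules[[rule_name]](graph)
  stopifnot(length(flags) == graph$n_atoms, all(flags %in% c(0, 1)))
  graph$custom_flags <- cbind(graph$custom_flags, matrix(flags, ncol = 1))
  graph$marking_rules <- c(graph$marking_rules, rule_name)
  graph
}
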