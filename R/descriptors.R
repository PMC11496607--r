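# Whole-molecule solvent descriptors: E-state, VSA-type, topological and
# connectivity families. Definitions follow the classical literature
# (Kier-Hall electrotopological states and valence deltas, Labute's
# approximate van der Waals surface areas, Wiener/Balaban/Zagreb/Kier-kappa
# indices, Randic-type chi connectivity). The exact 66-descriptor identity is
# fixed by the versioned registry (see `descriptor_registry()`).

# Kier-Hall valence delta: second-row atoms Zv - nH; heavier rows scaled by
# (Z - Zv - 1) to damp the core-electron count.
kier_hall_deltas <- function(graph) {
  tab <- atomic_constants_map()
  n <- graph$n_atoms
  # each undirected bond appears twice in edges, once per direction, so the
  # directed out-degree equals the chemical degree
  delta <- tabulate(graph$edges[, 1], nbins = n)
  dv <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    row <- tab[[graph$elements[i]]]
    zv <- row$n_valence_electrons
    z <- row$atomic_number
    nh <- graph$atom_state$h_count[i]
    dv[i] <- if (row$principal_quantum_number <= 2) {
      zv - nh
    } else {
      (zv - nh) / (z - zv - 1)
    }
    L[i] <- row$principal_quantum_number
  }
  list(delta = as.numeric(delta), dv = dv, L = L)
}

topo_distances <- function(graph) {
  n <- graph$n_atoms
  if (nrow(graph$edges) == 0) {
    return(matrix(0, n, n))
  }
  und <- graph$edges[graph$edges[, 1] < graph$edges[, 2], , drop = FALSE]
  g <- igraph::graph_from_edgelist(und, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::distances(g)
}

# E-state indices: intrinsic state I = ((2/L)^2 dv + 1)/d perturbed by
# topological field sum (I_i - I_j)/(d_ij + 1)^2
estate_indices <- function(graph, kd = kier_hall_deltas(graph),
                           D = topo_distances(graph)) {
  I <- ((2 / kd$L)^2 * kd$dv + 1) / pmax(kd$delta, 1)
  n <- graph$n_atoms
  S <- I
  if (n > 1) {
    for (i in seq_len(n)) {
      S[i] <- I[i] + sum((I[i] - I[-i]) / (D[i, -i] + 1)^2)
    }
  }
  list(I = I, S = S)
}

# Labute-style approximate per-atom van der Waals surface area: sphere area
# minus the spherical caps buried by bonded neighbours (including implicit H),
# with ideal bond length = sum of covalent radii.
approx_vsa <- function(graph) {
  tab <- atomic_constants_map()
  n <- graph$n_atoms
  h_row <- tab[["H"]]
  area <- numeric(n)
  und <- graph$edges[graph$edges[, 1] < graph$edges[, 2], , drop = FALSE]
  for (i in seq_len(n)) {
    ri <- tab[[graph$elements[i]]]$vdw_radius
    rci <- tab[[graph$elements[i]]]$covalent_radius
    a <- 4 * pi * ri^2
    nbrs <- c(
      graph$edges[graph$edges[, 1] == i, 2]
    )
    nbr_elts <- graph$elements[nbrs]
    nbr_elts <- c(nbr_elts, rep("H", graph$atom_state$h_count[i]))
    for (e in nbr_elts) {
      rj <- tab[[e]]$vdw_radius
      d <- rci + tab[[e]]$covalent_radius
      d <- min(max(d, abs(ri - rj) + 1e-6), ri + rj - 1e-6)
      cap <- 2 * pi * ri * (ri - (ri^2 + d^2 - rj^2) / (2 * d))
      a <- a - cap
    }
    area[i] <- max(a, 0)
  }
  area
}

# simple paths with `len` edges, each counted once (endpoints ordered)
simple_paths <- function(graph, len) {
  n <- graph$n_atoms
  if (nrow(graph$edges) == 0 || len < 1) return(list())
  adj <- vector("list", n)
  und <- graph$edges[graph$edges[, 1] < graph$edges[, 2], , drop = FALSE]
  for (r in seq_len(nrow(und))) {
    adj[[und[r, 1]]] <- c(adj[[und[r, 1]]], und[r, 2])
    adj[[und[r, 2]]] <- c(adj[[und[r, 2]]], und[r, 1])
  }
  out <- list()
  walk <- function(path) {
    if (length(path) == len + 1) {
      if (path[1] < path[length(path)]) {
        out[[length(out) + 1]] <<- path
      }
      return(invisible())
    }
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  for (s in seq_len(n)) walk(s)
  out
}

chi_index <- function(paths, d) {
  if (!length(paths)) return(0)
  sum(vapply(paths, function(p) {
    dd <- d[p]
    if (any(dd <= 0)) return(0)
    1 / sqrt(prod(dd))
  }, numeric(1)))
}

ESTATE_VSA_BINS <- c(-Inf, -0.390, 0.290, 0.717, 1.165, 1.540, 1.807,
                     2.050, 4.690, 9.170, Inf)
EN_VSA_BINS <- c(-Inf, 2.10, 2.60, 3.00, 3.50, 3.90, Inf)

binned_sums <- function(value, weight, breaks) {
  idx <- cut(value, breaks = breaks, labels = FALSE, right = TRUE)
  out <- numeric(length(breaks) - 1)
  for (b in seq_along(out)) out[b] <- sum(weight[idx == b])
  out
}

# the 66 descriptors for an already-parsed graph, in registry order
solvent_descriptors_from_graph <- function(graph) {
  n <- graph$n_atoms
  kd <- kier_hall_deltas(graph)
  D <- topo_distances(graph)
  es <- estate_indices(graph, kd, D)
  S <- es$S; I <- es$I
  elements <- graph$elements
  hetero <- elements != "C"
  halogen <- elements %in% HALOGENS

  d_estate <- c(
    estate_sum = sum(S),
    estate_mean = mean(S),
    estate_max = max(S),
    estate_min = min(S),
    estate_range = max(S) - min(S),
    estate_sum_C = sum(S[elements == "C"]),
    estate_sum_hetero = sum(S[hetero]),
    estate_sum_O = sum(S[elements == "O"]),
    estate_sum_N = sum(S[elements == "N"]),
    estate_sum_halogen = sum(S[halogen]),
    istate_sum = sum(I),
    istate_mean = mean(I),
    istate_max = max(I),
    istate_min = min(I),
    estate_abs_sum = sum(abs(S)),
    estate_frac_positive = mean(S > 0),
    estate_sum_sq = sum(S^2),
    estate_hetero_mean = if (any(hetero)) mean(S[hetero]) else 0
  )

  vsa <- approx_vsa(graph)
  en <- vapply(elements, function(e) atomic_constants_map()[[e]]$electronegativity,
               numeric(1))
  d_vsa <- c(
    labute_asa = sum(vsa),
    stats::setNames(binned_sums(S, vsa, ESTATE_VSA_BINS),
                    paste0("estate_vsa_", 1:10)),
    stats::setNames(binned_sums(en, vsa, EN_VSA_BINS),
                    paste0("en_vsa_", 1:6))
  )

  und <- graph$edges[graph$edges[, 1] < graph$edges[, 2], , drop = FALSE]
  m <- nrow(und)
  delta <- kd$delta
  mu <- m - n + 1  # cyclomatic number (connected solute)
  srow <- rowSums(D)
  balaban <- if (m > 0) {
    m / (mu + 1) * sum(1 / sqrt(srow[und[, 1]] * srow[und[, 2]]))
  } else 0
  ecc <- apply(D, 1, max)
  p1 <- m
  p2 <- length(simple_paths(graph, 2))
  p3 <- length(simple_paths(graph, 3))
  kappa <- function(A, P, order) {
    if (P <= 0) return(0)
    if (order == 1) A * (A - 1)^2 / P^2
    else if (order == 2) (A - 1) * (A - 2)^2 / P^2
    else if (A %% 2 == 1) (A - 1) * (A - 3)^2 / P^2
    else (A - 3) * (A - 2)^2 / P^2
  }
  # Hall-Kier alpha from covalent radius ratio to sp3 carbon
  alpha <- sum(vapply(elements, function(e) {
    atomic_constants_map()[[e]]$covalent_radius / 0.76 - 1
  }, numeric(1)))
  d_topo <- c(
    wiener_index = sum(D) / 2,
    balaban_j = balaban,
    zagreb_m1 = sum(delta^2),
    zagreb_m2 = if (m > 0) sum(delta[und[, 1]] * delta[und[, 2]]) else 0,
    graph_radius = min(ecc),
    graph_diameter = max(ecc),
    eccentric_connectivity = sum(ecc * delta),
    n_heavy_atoms = n,
    n_bonds = m,
    n_rings = max(mu, 0),
    kappa1 = kappa(n, p1, 1),
    kappa2 = kappa(n, p2, 2),
    kappa3 = kappa(n, p3, 3),
    kappa1_alpha = kappa(n + alpha, p1 + alpha, 1),
    kappa2_alpha = kappa(n + alpha, p2 + alpha, 2),
    kappa3_alpha = kappa(n + alpha, p3 + alpha, 3)
  )

  dv <- kd$dv
  paths2 <- simple_paths(graph, 2)
  paths3 <- simple_paths(graph, 3)
  paths4 <- simple_paths(graph, 4)
  paths1 <- lapply(seq_len(m), function(r) c(und[r, 1], und[r, 2]))
  chi0 <- sum(1 / sqrt(delta[delta > 0]))
  chi0v <- sum(1 / sqrt(dv[dv > 0]))
  chi1 <- chi_index(paths1, delta)
  d_conn <- c(
    chi0 = chi0,
    chi1 = chi1,
    chi2 = chi_index(paths2, delta),
    chi3 = chi_index(paths3, delta),
    chi4 = chi_index(paths4, delta),
    chi0v = chi0v,
    chi1v = chi_index(paths1, dv),
    chi2v = chi_index(paths2, dv),
    chi3v = chi_index(paths3, dv),
    chi4v = chi_index(paths4, dv),
    mean_randic = if (m > 0) chi1 / m else 0,
    delta_mean = mean(delta),
    deltav_mean = mean(dv),
    chi1_per_atom = chi1 / n,
    platt_index = if (m > 0) sum(delta[und[, 1]] + delta[und[, 2]] - 2) else 0
  )

  out <- c(d_estate, d_vsa, d_topo, d_conn)
  reg <- descriptor_registry()
  out <- out[reg$name]
  bad <- reg$name[!is.finite(out)]
  if (length(bad)) {
    ngnn_abort(sprintf(
      "descriptor computation failed for '%s': non-finite %s",
      graph$smiles, paste(bad, collapse = ", ")
    ), class = "ngnn_descriptor_failure")
  }
  out
}

#' Compute the 66 whole-molecule solvent descriptors
#'
#' One vector per solvent molecule, in registry order, spanning the E-state,
#' VSA-type, topological and connectivity families. The vector is computed
#' once per canonical solvent structure (results are cached) and later
#' broadcast to every solute atom during node dissolution.
#'
#' @param solvent_smiles SMILES of the solvent molecule.
#' @return Named numeric vector of length 66 with attribute
#'   `registry_version`.
#' @export
compute_solvent_descriptors <- function(solvent_smiles) {
  canon <- ob_canonical(solvent_smiles)
  cache <- .ngnn_env$descriptor_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .ngnn_env$descriptor_cache <- cache
  }
  if (!is.null(cache[[canon]])) return(cache[[canon]])
  graph <- parse_smiles(canon)
  v <- solvent_descriptors_from_graph(graph)
  attr(v, "registry_version") <- descriptor_registry_version()
  cache[[canon]] <- v
  v
}
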