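# Optional geometric mode: conformer and minimization contracts, the
# stereochemistry duplication module, and 3D distance gating.
#
# Geometric mode is OFF by default and all headline analyses run
# topologically: these contracts preserve the architecture of a
# coordinate-driven pipeline (external force field / semi-empirical
# engines) while the bundled stubs — a template embedder with a harmonic
# relaxer and a torsion-scan conformer generator — keep the mode testable
# and self-contained. Topological-mode results are a constitutional
# superset of geometric-mode results: the gates only remove candidate
# reactions.

#' Geometric-mode configuration
#'
#' @param dihedral_window_deg Half-width (degrees) of the diagnostic
#'   dihedral window that triggers the stereochemistry module; default 45,
#'   boundary inclusive.
#' @param default_bond_length Bond length (Angstrom) used when placing a
#'   reflected atom from the cation plane normal; default 1.54 (C-C single).
#' @param distance_cutoff_A Donor-acceptor distance gate for hydride shifts
#'   and proton transfers; default 5.0 Angstrom, boundary inclusive.
#' @param gate_after_round Round index after which the distance gate
#'   applies (default 5: early rounds are unrestricted, modelling the
#'   long-range shifts that enzyme active sites can mediate).
#' @param conformer_rounds Number of initial rounds with conformational
#'   sampling; default 5.
#' @return A `geometry_config` object.
#' @export
geometry_config <- function(dihedral_window_deg = 45,
                            default_bond_length = 1.54,
                            distance_cutoff_A = 5.0,
                            gate_after_round = 5L,
                            conformer_rounds = 5L) {
  stopifnot(dihedral_window_deg > 0, dihedral_window_deg <= 90,
            default_bond_length > 0, distance_cutoff_A > 0)
  structure(
    list(dihedral_window_deg = dihedral_window_deg,
         default_bond_length = default_bond_length,
         distance_cutoff_A = distance_cutoff_A,
         gate_after_round = as.integer(gate_after_round),
         conformer_rounds = as.integer(conformer_rounds)),
    class = "geometry_config"
  )
}

need_coords <- function(g) {
  if (is.null(g$coords)) stop("this operation requires coordinates (geometric mode)")
  g$coords
}

#' Distance gate for long-range hydride shifts and proton transfers
#'
#' Rounds up to `gate_after_round` are always allowed; afterwards the
#' Euclidean donor-acceptor distance must not exceed the cutoff
#' (inclusive).
#'
#' @param g A [cation_graph()] with coordinates.
#' @param donor_atom,acceptor_atom Atom indices.
#' @param round_idx Current enumeration round.
#' @param cfg A [geometry_config()].
#' @return `TRUE` if the reaction is allowed.
#' @export
distance_gate <- function(g, donor_atom, acceptor_atom, round_idx,
                          cfg = geometry_config()) {
  xyz <- need_coords(g)
  if (round_idx <= cfg$gate_after_round) return(TRUE)
  sqrt(sum((xyz[donor_atom, ] - xyz[acceptor_atom, ])^2)) <= cfg$distance_cutoff_A
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Stereochemistry module: placement variants of a reactive atom
#'
#' When the diagnostic dihedral of the reacting frame (reactive atom, the
#' two atoms on its shortest bond path towards the cation, the cation
#' centre) lies within the window, the facial preference of the attack is
#' ambiguous and both placements are generated: the two opposite unit
#' normals of the cation's sp2 plane, scaled by the default bond length
#' from the cation carbon, define the final positions; the translation is
#' applied to the reactive atom and, when it is a carbon, rigidly to its
#' bonded substituents. Outside the window a single placement (the
#' original) is returned.
#'
#' @param g A [cation_graph()] with coordinates.
#' @param reactive_atom Index of the attacking/migrating atom.
#' @param cfg A [geometry_config()].
#' @return List of coordinate matrices (length 1 or 2).
#' @export
stereo_placements <- function(g, reactive_atom, cfg = geometry_config()) {
  xyz <- need_coords(g)
  cs <- g$charge_site
  if (is.na(cs)) stop("stereochemistry module requires a cation")
  a <- as.integer(reactive_atom)
  # frame: a - n1 - n2 - cs along the shortest bond path
  bo <- bond_matrix(g)
  n <- length(g$atoms)
  prev <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
  dist[a] <- 0L; queue <- a
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in which(bo[u, ] > 0 & is.na(dist))) {
      dist[v] <- dist[u] + 1L; prev[v] <- u; queue <- c(queue, v)
    }
  }
  if (is.na(dist[cs]) || dist[cs] < 3)
    stop("diagnostic dihedral undefined: reactive atom too close to the cation")
  path <- cs
  while (path[1] != a) path <- c(prev[path[1]], path)
  n1 <- path[2]; n2 <- path[3]
  dih <- dihedral_deg(xyz[a, ], xyz[n1, ], xyz[n2, ], xyz[cs, ])
  if (abs(dih) > cfg$dihedral_window_deg) return(list(xyz))
  nb <- which(bo[cs, ] > 0)
  if (length(nb) < 2) stop("undefined cation plane")
  v1 <- xyz[nb[1], ] - xyz[cs, ]
  v2 <- xyz[nb[2], ] - xyz[cs, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  len <- sqrt(sum(nrm^2))
  if (len < 1e-8) stop("undefined cation plane (collinear neighbours)")
  nrm <- nrm / len
  moved <- a
  if (g$atoms[a] == "C") moved <- c(a, which(bo[a, ] > 0))
  lapply(c(1, -1), function(sgn) {
    target <- xyz[cs, ] + sgn * nrm * cfg$default_bond_length
    shift <- target - xyz[a, ]
    out <- xyz
    out[moved, ] <- sweep(out[moved, , drop = FALSE], 2, shift, `+`)
    out
  })
}

# ---------------------------------------------------------------------------
# bundled stubs: template embedder + harmonic relaxer, torsion conformers
# ---------------------------------------------------------------------------

ideal_length <- function(g, i, j) {
  bo <- bond_matrix(g)
  if (g$atoms[i] == "H" || g$atoms[j] == "H") 1.09
  else if (bo[i, j] == 2) 1.33
  else 1.54
}

bond_sanity <- function(g, xyz, lo = 0.9, hi = 1.8) {
  b <- g$bonds
  d <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] - xyz[b[, 2], , drop = FALSE])^2))
  all(d >= lo & d <= hi)
}

harmonic_energy <- function(g, xyz) {
  b <- g$bonds
  d <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] - xyz[b[, 2], , drop = FALSE])^2))
  r0 <- vapply(seq_len(nrow(b)), function(k) ideal_length(g, b[k, 1], b[k, 2]),
               numeric(1))
  e <- sum(100 * (d - r0)^2)
  # soft repulsion between non-bonded pairs
  n <- nrow(xyz)
  bo <- bond_matrix(g)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (bo[i, j] == 0) {
        dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (dij < 2.2) e <- e + 20 * (2.2 - dij)^2
      }
  e
}

relax_coords <- function(g, xyz, maxit = 300) {
  n <- nrow(xyz)
  fn <- function(par) harmonic_energy(g, matrix(par, n, 3))
  res <- stats::optim(as.vector(xyz), fn, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  matrix(res$par, n, 3)
}

# deterministic template embedding: breadth-first placement on a tetrahedral
# lattice followed by harmonic relaxation; adequate for the small fixtures
# the geometric mode is exercised on
embed_coords <- function(g, cfg = geometry_config()) {
  n <- length(g$atoms)
  bo <- bond_matrix(g)
  xyz <- matrix(NA_real_, n, 3)
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                c(1, 1, -1), c(-1, -1, -1)) / sqrt(3)
  xyz[1, ] <- 0
  queue <- 1L
  placed <- c(TRUE, rep(FALSE, n - 1))
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    k <- 0L
    for (v in which(bo[u, ] > 0)) {
      if (placed[v]) next
      k <- k + 1L
      jitter <- 0.03 * ((u * 7 + v * 3) %% 5 - 2) # break lattice symmetry
      xyz[v, ] <- xyz[u, ] + dirs[(k - 1L) %% nrow(dirs) + 1L, ] *
        ideal_length(g, u, v) + jitter
      placed[v] <- TRUE
      queue <- c(queue, v)
    }
  }
  relax_coords(g, xyz)
}

#' Identity minimization plugin
#'
#' @return A minimizer plugin that returns the input coordinates unchanged.
#' @export
identity_minimizer <- function() {
  structure(list(minimize = function(g) need_coords(g)),
            class = "minimizer_plugin")
}

#' Bundled harmonic relaxer plugin
#'
#' A deterministic minimizer stub: quadratic bond-length springs towards
#' ideal lengths (1.54/1.33/1.09 Angstrom) plus a soft non-bonded
#' repulsion, relaxed by BFGS. Its role is the contract's role: restore
#' reasonable local geometry after a connectivity change.
#'
#' @return A minimizer plugin.
#' @export
harmonic_minimizer <- function() {
  structure(list(minimize = function(g) relax_coords(g, need_coords(g))),
            class = "minimizer_plugin")
}

#' Minimize a structure through a pluggable engine
#'
#' Contract: the plugin returns updated coordinates that are deterministic
#' for a fixed input and satisfy bond-length sanity (all bonded pairs
#' within 0.9 to 1.8 Angstrom); violations raise an error.
#'
#' @param g A [cation_graph()] with coordinates.
#' @param plugin A minimizer plugin ([harmonic_minimizer()] by default).
#' @return `g` with updated coordinates.
#' @export
minimize_structure <- function(g, plugin = harmonic_minimizer()) {
  stopifnot(inherits(plugin, "minimizer_plugin"))
  xyz <- plugin$minimize(g)
  if (!bond_sanity(g, xyz))
    stop("minimizer returned unreasonable bond lengths")
  g$coords <- xyz
  g
}

rotate_about_axis <- function(points, p, q, theta) {
  k <- q - p
  k <- k / sqrt(sum(k^2))
  sweep(t(apply(sweep(points, 2, p), 1, function(v) {
    v * cos(theta) +
      c(k[2] * v[3] - k[3] * v[2],
        k[3] * v[1] - k[1] * v[3],
        k[1] * v[2] - k[2] * v[1]) * sin(theta) +
      k * sum(k * v) * (1 - cos(theta))
  })), 2, p, `+`)
}

# rotatable bonds: acyclic C-C single bonds with substituents on both sides
rotatable_bonds <- function(g) {
  bo <- bond_matrix(g)
  n <- length(g$atoms)
  out <- list()
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    if (g$bonds[k, 3] != 1 || g$atoms[i] != "C" || g$atoms[j] != "C") next
    if (sum(bo[i, ] > 0) < 2 || sum(bo[j, ] > 0) < 2) next
    # acyclic: removing the bond must disconnect j's side from i
    seen <- logical(n); seen[i] <- TRUE; queue <- j; seen[j] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(bo[u, ] > 0 & !seen)) {
        if (u == j && v == i) next
        seen[v] <- TRUE; queue <- c(queue, v)
      }
    }
    side <- which(seen & seq_len(n) != i)
    if (length(side) < n - 1) out[[length(out) + 1L]] <- list(i = i, j = j, side = side)
  }
  out
}

#' Bundled torsion-scan conformer generator
#'
#' Scans staggered torsions (0, +120, -120 degrees) over up to three
#' rotatable acyclic C-C single bonds, relaxes every candidate with the
#' harmonic stub, and deduplicates by the sorted interatomic-distance
#' signature. When more torsion combinations exist than `n_conformers`, a
#' seeded sample (always containing the unrotated combination) is scanned,
#' so repeated runs with one seed give identical lists.
#'
#' @param n_conformers Maximum number of conformers to return.
#' @return A conformer generator plugin.
#' @export
torsion_conformer_generator <- function(n_conformers = 4) {
  structure(list(n_conformers = as.integer(n_conformers),
                 generate = function(g, seed) {
                   base <- if (is.null(g$coords)) embed_coords(g) else g$coords
                   rb <- utils::head(rotatable_bonds(g), 3)
                   combos <- expand.grid(rep(list(c(0, 2 * pi / 3, -2 * pi / 3)),
                                             length(rb)))
                   rng <- get0(".Random.seed", envir = globalenv())
                   on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
                   set.seed(seed)
                   limit <- max(n_conformers, 1L)
                   if (nrow(combos) > limit) {
                     pick <- c(1L, sample(2:nrow(combos), limit - 1L))
                     combos <- combos[pick, , drop = FALSE]
                   }
                   out <- list()
                   sigs <- character(0)
                   for (r in seq_len(max(nrow(combos), 1L))) {
                     cand <- base
                     for (b in seq_along(rb)) {
                       th <- combos[r, b]
                       if (is.na(th) || th == 0) next
                       sel <- rb[[b]]
                       cand[sel$side, ] <- rotate_about_axis(
                         cand[sel$side, , drop = FALSE],
                         cand[sel$i, ], cand[sel$j, ], th)
                     }
                     cand <- relax_coords(g, cand)
                     if (!bond_sanity(g, cand)) next
                     sig <- paste(round(sort(stats::dist(cand)), 1), collapse = ",")
                     if (sig %in% sigs) next
                     sigs <- c(sigs, sig)
                     out[[length(out) + 1L]] <- cand
                   }
                   out
                 }),
            class = "conformer_plugin")
}

#' Generate conformers through a pluggable sampler
#'
#' Contract: at least one conformer is returned, every conformer passes
#' bond sanity, and the generator is seeded for reproducibility. A failing
#' generator falls back to the single input conformer with a warning.
#'
#' @param g A [cation_graph()] (coordinates embedded if absent).
#' @param generator A conformer plugin ([torsion_conformer_generator()] by
#'   default).
#' @param seed RNG seed forwarded to the generator.
#' @return List of coordinate matrices.
#' @export
generate_conformers <- function(g, generator = torsion_conformer_generator(),
                                seed = 1L) {
  stopifnot(inherits(generator, "conformer_plugin"))
  confs <- tryCatch(generator$generate(g, seed), error = function(e) {
    warning("conformer generator failed (", conditionMessage(e),
            "); falling back to the input conformer")
    NULL
  })
  if (is.null(confs) || !length(confs)) {
    confs <- list(if (is.null(g$coords)) embed_coords(g) else g$coords)
  }
  keep <- vapply(confs, function(x) bond_sanity(g, x), logical(1))
  confs <- confs[keep]
  if (!length(confs)) stop("no conformer passed bond sanity")
  confs
}
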