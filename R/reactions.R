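# The five rearrangement operators, as pure edits on explicit-H graphs.
#
# These are the reference implementations of the operator surface; the
# breadth-first engine (run_enumeration) uses an independent C++
# implementation of the same rules, and the two are cross-checked in the
# test suite. Each operator returns the product graph plus a typed
# reaction_event; structural preconditions raise errors, which
# enumerate_products() converts to skips.

reaction_event <- function(g, product, rtype, atoms) {
  structure(
    list(reactant_key = canonical_key(g),
         product_key = canonical_key(product),
         rtype = rtype,
         atoms = as.integer(atoms)),
    class = "reaction_event"
  )
}

reaction_result <- function(graph, event) {
  structure(list(graph = graph, event = event), class = "reaction_result")
}

excluded_atoms <- function(g) {
  cs <- g$charge_site
  if (is.na(cs)) stop("neutral species has no reactive-atom list")
  bo <- bond_matrix(g)
  c(cs, which(bo[cs, ] > 0))
}

#' Reactive atoms of a carbocation
#'
#' The atom-iteration rule of the enumeration engine: every atom of the
#' reactant is reactive except the cationic carbon and its three directly
#' bonded atoms. Note that hydrogens on the carbons *adjacent* to the charge
#' site are two bonds away and therefore reactive — this is what makes
#' 1,2-hydride shifts possible.
#'
#' @param g A charged [cation_graph()].
#' @return Integer vector of atom indices.
#' @examples
#' # tert-butyl cation: the 9 methyl hydrogens are reactive
#' length(reactive_atoms(parse_smiles("C[C+](C)C")))
#' @export
reactive_atoms <- function(g) {
  stopifnot(inherits(g, "cation_graph"))
  setdiff(seq_along(g$atoms), excluded_atoms(g))
}

# carbon-to-carbon through-bond separation
bond_distance <- function(g, from, to) {
  bo <- bond_matrix(g)
  n <- length(g$atoms)
  d <- rep(NA_integer_, n)
  d[from] <- 0L
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- which(bo[u, ] > 0 & is.na(d))
    d[nb] <- d[u] + 1L
    queue <- c(queue, nb)
  }
  d[to]
}

# rebuild a cation_graph after a bond edit, revalidating all invariants
rebuild <- function(g, bonds, charge_site) {
  cation_graph(g$atoms, bonds, charge_site = charge_site)
}

alkene_partner <- function(g, a) {
  b <- g$bonds
  k <- which(b[, 3] == 2 & (b[, 1] == a | b[, 2] == a))
  if (!length(k)) return(integer(0))
  setdiff(as.vector(b[k, 1:2]), a)
}

set_bond_order <- function(bonds, i, j, order) {
  k <- which((bonds[, 1] == i & bonds[, 2] == j) |
             (bonds[, 1] == j & bonds[, 2] == i))
  if (order == 0) bonds[-k, , drop = FALSE]
  else { bonds[k, 3] <- order; bonds }
}

#' Intramolecular alkylation (cyclization)
#'
#' The cationic carbon attacks a reactive carbon of a C=C double bond: a new
#' single bond closes a ring of size at least 3, the double bond becomes
#' single, and the charge moves to the other alkene carbon. Both carbons of
#' the attacked alkene must lie outside the excluded-atom set: an alkene
#' conjugated to the cation is the allylic resonance system, whose charge
#' interaction is the zero-step resonance edge, not a cyclization.
#'
#' @param g A charged [cation_graph()].
#' @param alkene_carbon Index of the attacked alkene carbon; must be in
#'   [reactive_atoms()].
#' @return A list of `reaction_result` objects (length 1; the list form
#'   mirrors the operator family interface).
#' @export
apply_alkylation <- function(g, alkene_carbon) {
  t <- as.integer(alkene_carbon)
  if (g$atoms[t] != "C") stop("alkene_carbon must be a carbon")
  o <- alkene_partner(g, t)
  if (!length(o)) stop("alkene_carbon is not part of a C=C double bond")
  o <- o[1]
  if (!t %in% reactive_atoms(g)) stop("alkene_carbon is excluded (adjacent to the charge site)")
  if (o %in% excluded_atoms(g))
    stop("attacked alkene is conjugated to the cation (resonance, not alkylation)")
  cs <- g$charge_site
  bonds <- set_bond_order(g$bonds, t, o, 1L)
  bonds <- rbind(bonds, c(cs, t, 1L))
  p <- rebuild(g, bonds, charge_site = o)
  list(reaction_result(p, reaction_event(g, p, "ALKYLATION", c(cs, t))))
}

#' 1,2-hydride shift
#'
#' A reactive hydrogen moves to the cationic carbon; the charge moves to the
#' carbon that lost it. In topological mode the through-bond separation
#' between that carbon and the charge site must not exceed `range`
#' (longer-range shifts model the proton shuttling seen in enzymatic
#' systems; the geometric mode gates them by 3D distance instead).
#'
#' @param g A charged [cation_graph()].
#' @param h_atom Index of the migrating hydrogen (must be reactive).
#' @param range Maximum through-bond carbon separation; `Inf` for unlimited.
#' @return A `reaction_result`.
#' @export
apply_hydride_shift <- function(g, h_atom, range = Inf) {
  h <- as.integer(h_atom)
  if (g$atoms[h] != "H") stop("h_atom must be a hydrogen")
  if (!h %in% reactive_atoms(g)) stop("h_atom is bonded to the charge site")
  co <- setdiff(as.vector(g$bonds[g$bonds[, 1] == h | g$bonds[, 2] == h, 1:2]), h)
  cs <- g$charge_site
  if (co == cs) stop("h_atom is on the charge site")
  if (is.finite(range) && bond_distance(g, co, cs) > range)
    stop("carbon separation exceeds the shift range")
  bonds <- set_bond_order(g$bonds, h, co, 0L)
  bonds <- rbind(bonds, c(h, cs, 1L))
  p <- rebuild(g, bonds, charge_site = co)
  reaction_result(p, reaction_event(g, p, "HYDRIDE_SHIFT", c(co, cs)))
}

shift_origins <- function(g, m) {
  # carbons bonded to m by a single bond that are themselves bonded to C+
  cs <- g$charge_site
  bo <- bond_matrix(g)
  which(bo[m, ] == 1 & bo[cs, ] == 1 & g$atoms == "C" & seq_along(g$atoms) != cs)
}

is_methyl <- function(g, m) {
  bo <- bond_matrix(g)
  g$atoms[m] == "C" && sum(g$atoms[bo[m, ] > 0] == "H") == 3
}

apply_carbon_shift <- function(g, migrating_carbon, origin, methyl) {
  m <- as.integer(migrating_carbon)
  if (g$atoms[m] != "C") stop("migrating atom must be a carbon")
  if (!m %in% reactive_atoms(g)) stop("migrating carbon is excluded (bonded to the charge site)")
  if (is_methyl(g, m) != methyl)
    stop(if (methyl) "migrating carbon is not a methyl group"
         else "migrating carbon is a methyl group (use the methyl-shift operator)")
  ca <- if (is.null(origin)) {
    cand <- shift_origins(g, m)
    if (!length(cand)) stop("no origin carbon adjacent to both the migrating carbon and the charge site")
    if (length(cand) > 1) stop("ambiguous origin carbon; supply `origin`")
    cand
  } else {
    origin <- as.integer(origin)
    if (!origin %in% shift_origins(g, m)) stop("origin is not adjacent to both the migrating carbon and the charge site")
    origin
  }
  cs <- g$charge_site
  bonds <- set_bond_order(g$bonds, ca, m, 0L)
  bonds <- rbind(bonds, c(cs, m, 1L))
  p <- rebuild(g, bonds, charge_site = ca)
  rtype <- if (methyl) "METHYL_SHIFT" else "ALKYL_SHIFT"
  reaction_result(p, reaction_event(g, p, rtype, c(m, ca)))
}

#' 1,2-alkyl shift (non-methyl)
#'
#' A carbon bonded to a neighbour of the charge site migrates to the
#' cationic carbon; the charge moves to the origin carbon. When the
#' migrating bond is part of a ring this performs a ring expansion or
#' contraction (ring opening of a bond adjacent to the cation — the reverse
#' of an alkylation — is realized through this operator). Methyl groups are
#' handled by the separate methyl-shift operator.
#'
#' @param g A charged [cation_graph()].
#' @param migrating_carbon Index of the migrating carbon (reactive, not a
#'   methyl).
#' @param origin Origin carbon, required only when the migrating carbon has
#'   several neighbours adjacent to the charge site.
#' @return A `reaction_result`.
#' @export
apply_alkyl_shift <- function(g, migrating_carbon, origin = NULL)
  apply_carbon_shift(g, migrating_carbon, origin, methyl = FALSE)

#' 1,2-methyl shift
#'
#' As [apply_alkyl_shift()], but the migrating carbon must be a methyl group
#' (a carbon bearing three hydrogens). The two operators are separate
#' because the enumeration engine can enable them independently.
#'
#' @inheritParams apply_alkyl_shift
#' @param methyl_carbon Index of the migrating methyl carbon.
#' @return A `reaction_result`.
#' @export
apply_methyl_shift <- function(g, methyl_carbon, origin = NULL)
  apply_carbon_shift(g, methyl_carbon, origin, methyl = TRUE)

#' Intramolecular proton transfer
#'
#' One concerted edit: a hydrogen on a carbon adjacent to the charge site
#' leaves (forming a new alkene with the old charge site), and a remote
#' existing C=C is protonated at `acceptor_carbon` (the charge lands on the
#' other carbon of the accepting alkene). An acceptor alkene containing the
#' donor carbon is rejected: that move degenerates to an allylic resonance
#' shift.
#'
#' @param g A charged [cation_graph()].
#' @param donor_h Index of the leaving hydrogen; its carbon must be adjacent
#'   to the charge site.
#' @param acceptor_carbon Carbon of an existing C=C that receives the proton.
#' @param range Maximum donor-to-acceptor through-bond carbon separation;
#'   `Inf` for unlimited.
#' @return A `reaction_result`.
#' @export
apply_proton_transfer <- function(g, donor_h, acceptor_carbon, range = Inf) {
  h <- as.integer(donor_h)
  ac <- as.integer(acceptor_carbon)
  if (g$atoms[h] != "H") stop("donor_h must be a hydrogen")
  cd <- setdiff(as.vector(g$bonds[g$bonds[, 1] == h | g$bonds[, 2] == h, 1:2]), h)
  cs <- g$charge_site
  bo <- bond_matrix(g)
  if (cd == cs || bo[cd, cs] != 1) stop("donor hydrogen must sit on a carbon adjacent to the charge site")
  oc <- alkene_partner(g, ac)
  if (!length(oc)) stop("acceptor_carbon is not part of a C=C double bond")
  oc <- oc[1]
  if (cd %in% c(ac, oc)) stop("acceptor alkene contains the donor carbon (resonance, not proton transfer)")
  if (is.finite(range) && bond_distance(g, cd, ac) > range)
    stop("donor-acceptor separation exceeds the transfer range")
  bonds <- set_bond_order(g$bonds, h, cd, 0L)
  bonds <- set_bond_order(bonds, cd, cs, 2L)
  bonds <- set_bond_order(bonds, ac, oc, 1L)
  bonds <- rbind(bonds, c(ac, h, 1L))
  p <- rebuild(g, bonds, charge_site = oc)
  reaction_result(p, reaction_event(g, p, "PROTON_TRANSFER", c(cd, ac)))
}

#' All products of one reactant under the enabled operators
#'
#' Runs the two key iterations of the enumeration engine on a single
#' reactant: over the reactive atoms, and over the enabled reaction types.
#' Every operator whose structural precondition matches is applied;
#' candidate products that violate the cation-graph invariants (for
#' example, a charge landing on an sp2 carbon) are dropped. Allylic
#' resonance forms are appended as zero-step `RESONANCE` products when
#' enabled. Degenerate products equal to the reactant are *not* suppressed
#' here — the network deduplication removes them — so the operators stay
#' pure and locally testable.
#'
#' @param g A charged [cation_graph()].
#' @param config An [enum_config()]; only `enabled_types` and
#'   `shift_range_bonds` are consulted here.
#' @return A list of `reaction_result` objects.
#' @export
enumerate_products <- function(g, config = enum_config()) {
  stopifnot(inherits(g, "cation_graph"))
  enabled <- config$enabled_types
  range <- config$shift_range_bonds
  out <- list()
  grab <- function(expr) {
    r <- tryCatch(expr, error = function(e) NULL)
    if (is.null(r)) return()
    if (inherits(r, "reaction_result")) r <- list(r)
    out[seq_along(r) + length(out)] <<- r
  }
  bo <- bond_matrix(g)
  for (a in reactive_atoms(g)) {
    if (g$atoms[a] == "C") {
      if ("ALKYLATION" %in% enabled && length(alkene_partner(g, a)))
        grab(apply_alkylation(g, a))
      if (any(c("ALKYL_SHIFT", "METHYL_SHIFT") %in% enabled)) {
        for (ca in shift_origins(g, a)) {
          if ("ALKYL_SHIFT" %in% enabled && !is_methyl(g, a))
            grab(apply_carbon_shift(g, a, ca, methyl = FALSE))
          if ("METHYL_SHIFT" %in% enabled && is_methyl(g, a))
            grab(apply_carbon_shift(g, a, ca, methyl = TRUE))
        }
      }
    } else {
      co <- which(bo[a, ] > 0)
      if ("HYDRIDE_SHIFT" %in% enabled)
        grab(apply_hydride_shift(g, a, range = range))
      if ("PROTON_TRANSFER" %in% enabled && bo[co, g$charge_site] == 1) {
        acceptors <- unique(as.vector(g$bonds[g$bonds[, 3] == 2, 1:2]))
        for (ac in acceptors)
          grab(apply_proton_transfer(g, a, ac, range = range))
      }
    }
  }
  if ("RESONANCE" %in% enabled) {
    forms <- resonance_forms(g)
    self <- canonical_key(g)
    for (key in setdiff(names(forms), self)) {
      p <- forms[[key]]
      out[[length(out) + 1L]] <-
        reaction_result(p, reaction_event(g, p, "RESONANCE",
                                          c(g$charge_site, p$charge_site)))
    }
  }
  out
}
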