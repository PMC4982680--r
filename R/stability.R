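# Stability filtering of candidate cations.
#
# The production filter chain of the original workflow was a semi-empirical
# QM energy cutoff relative to the linear substrate cation. Here that step
# is a pluggable contract: any deterministic energy engine can be supplied,
# and a class-based heuristic (reject non-allylic primary cations) is the
# default desk-scale stand-in. Permissive mode disables filtering entirely.

#' Stability filter configuration
#'
#' @param mode `"heuristic"` (reject by cation class, the default),
#'   `"permissive"` (accept everything), or `"energy_plugin"` (relative
#'   energy cutoff against a reference cation, requires an [energy_plugin()]).
#' @param cutoff_kcal Relative energy threshold in kcal/mol against the
#'   reference cation; only meaningful in `energy_plugin` mode. The default
#'   0 accepts species no higher in energy than the reference (boundary
#'   inclusive, so the reference itself always passes).
#' @param reference Reference cation ([cation_graph()] or SMILES) for
#'   relative energies; defaults to the linear monoterpene substrate cation
#'   when first needed.
#' @param reject_classes Cation classes rejected in heuristic mode (default
#'   `"primary"`). Tertiary cations can never be rejected, and allylic
#'   cations of any substitution are always exempt — the linear substrate
#'   itself is an allylic primary cation and must survive its own filter.
#' @return A `stability_config` object.
#' @export
stability_config <- function(mode = c("heuristic", "permissive", "energy_plugin"),
                             cutoff_kcal = 0,
                             reference = NULL,
                             reject_classes = "primary") {
  mode <- match.arg(mode)
  reject_classes <- as.character(reject_classes)
  if (any(!reject_classes %in% c("primary", "secondary")))
    stop("reject_classes may only contain 'primary' and/or 'secondary'")
  if (!is.null(reference) && is.character(reference))
    reference <- parse_smiles(reference)
  structure(
    list(mode = mode, cutoff_kcal = as.numeric(cutoff_kcal),
         reference = reference, reject_classes = reject_classes),
    class = "stability_config"
  )
}

#' Energy-engine plugin contract
#'
#' Wraps an energy evaluator into the contract the stability filter expects:
#' `evaluate(g)` returns a potential energy in kcal/mol and must be
#' deterministic for a fixed input. Engines that work from 3D structures set
#' `requires_coords = TRUE` (the default), and the filter then refuses
#' species without coordinates; purely key-based evaluators such as
#' [table_energy_plugin()] opt out.
#'
#' @param evaluate Function of one [cation_graph()] returning a numeric
#'   energy in kcal/mol.
#' @param requires_coords Whether `evaluate` needs `g$coords`.
#' @return An `energy_plugin` object.
#' @export
energy_plugin <- function(evaluate, requires_coords = TRUE) {
  stopifnot(is.function(evaluate))
  structure(list(evaluate = evaluate, requires_coords = isTRUE(requires_coords)),
            class = "energy_plugin")
}

#' Table-lookup energy plugin
#'
#' A deterministic stub engine backed by a fixed table of energies keyed by
#' canonical SMILES; useful for testing filter behaviour (for example the
#' cutoff-monotonicity property) without an external QM engine.
#'
#' @param energies Named numeric vector, names are canonical SMILES keys,
#'   values kcal/mol.
#' @return An `energy_plugin` that does not require coordinates.
#' @export
table_energy_plugin <- function(energies) {
  stopifnot(is.numeric(energies), !is.null(names(energies)))
  force(energies)
  energy_plugin(function(g) {
    key <- canonical_key(g)
    if (!key %in% names(energies)) stop("no tabulated energy for ", key)
    unname(energies[[key]])
  }, requires_coords = FALSE)
}

#' Executable energy-plugin adapter
#'
#' Discovers an external engine as an executable adapter: the species is
#' written to the adapter's standard input as one JSON structure (atoms,
#' bonds, charge site, coordinates) and the adapter must print one JSON
#' object with a single `energy_kcal` number.
#'
#' @param path Path to the adapter executable.
#' @return An `energy_plugin` requiring coordinates.
#' @export
executable_energy_plugin <- function(path) {
  if (!file.exists(path)) stop("no such adapter executable: ", path)
  force(path)
  energy_plugin(function(g) {
    payload <- jsonlite::toJSON(list(
      atoms = g$atoms,
      bonds = unname(apply(g$bonds, 1, as.list)),
      charge_site = g$charge_site,
      coords = g$coords
    ), auto_unbox = TRUE)
    out <- system2(path, input = as.character(payload), stdout = TRUE)
    res <- jsonlite::fromJSON(paste(out, collapse = ""))
    as.numeric(res$energy_kcal)
  }, requires_coords = TRUE)
}

#' Apply the stability filter to one species
#'
#' Permissive mode accepts everything. Heuristic mode rejects a species iff
#' its cation class is in `reject_classes` *and* the class is not allylic.
#' Energy-plugin mode accepts iff
#' `energy(g) - energy(reference) <= cutoff_kcal` (boundary inclusive).
#'
#' @param g A charged [cation_graph()].
#' @param cfg A [stability_config()].
#' @param plugin An [energy_plugin()]; required in `energy_plugin` mode.
#' @return `TRUE` to keep the species, `FALSE` to discard it.
#' @export
passes_filter <- function(g, cfg = stability_config(), plugin = NULL) {
  stopifnot(inherits(cfg, "stability_config"))
  switch(cfg$mode,
    permissive = TRUE,
    heuristic = {
      cls <- classify_cation(g)
      !(cls %in% cfg$reject_classes)  # allylic_* labels never match the bases
    },
    energy_plugin = {
      if (is.null(plugin)) stop("energy_plugin mode requires a plugin")
      stopifnot(inherits(plugin, "energy_plugin"))
      if (plugin$requires_coords && is.null(g$coords))
        stop("this energy plugin requires coordinates")
      ref <- cfg$reference
      if (is.null(ref)) ref <- linear_monoterpene_cation()
      plugin$evaluate(g) - plugin$evaluate(ref) <= cfg$cutoff_kcal
    }
  )
}

#' Fraction of secondary carbocations in a node set
#'
#' The summary statistic used to monitor how a stability filter reshapes
#' the network: the share of nodes whose cation class is secondary or
#' allylic secondary.
#'
#' @param nodes A list of charged [cation_graph()] objects, or a
#'   [run_enumeration()] network (its stored classes are used).
#' @return A fraction in `[0, 1]`.
#' @export
secondary_fraction <- function(nodes) {
  cls <- if (inherits(nodes, "reaction_network")) {
    nodes$nodes$cation_class
  } else {
    if (!length(nodes)) stop("empty node set")
    vapply(nodes, classify_cation, character(1))
  }
  if (!length(cls)) stop("empty node set")
  mean(cls %in% c("secondary", "allylic_secondary"))
}
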