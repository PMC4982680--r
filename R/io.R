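# Serialization and command entry points.
#
# Tables are TSV (tab-separated, UTF-8, header row); the network graph is
# GraphML; run manifests and configuration echoes are JSON; molecules
# travel as SMILES, one species per line with optional tab-separated
# annotation columns.

config_as_list <- function(config) {
  list(
    enabled_types = config$enabled_types,
    max_rounds = if (is.infinite(config$max_rounds)) "unbounded" else config$max_rounds,
    stability = list(mode = config$stability$mode,
                     cutoff_kcal = config$stability$cutoff_kcal,
                     reject_classes = config$stability$reject_classes),
    stereo_enabled = config$stereo_enabled,
    geometry_enabled = config$geometry_enabled,
    shift_range_bonds = if (is.infinite(config$shift_range_bonds)) "unlimited"
                        else config$shift_range_bonds,
    step_offset = config$step_offset
  )
}

#' Write a reaction network to a directory
#'
#' Writes `nodes.tsv` (key, formula, class, round_found, energy),
#' `edges.tsv` (reactant_key, product_key, rtype, atom indices),
#' `network.graphml`, and `manifest.json` (configuration echo, seeds,
#' per-round counters, totals, wall clock, package version). The manifest
#' totals match the serialized files exactly.
#'
#' @param net A `reaction_network`.
#' @param dir Output directory (created if missing).
#' @param wall_clock Optional elapsed seconds to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir, wall_clock = NA_real_) {
  stopifnot(inherits(net, "reaction_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- cation_formula(parse_smiles(net$nodes$key[1]))
  formula_str <- sprintf("C%dH%d%s", f[["nC"]], f[["nH"]],
                         if (f[["charge"]] > 0) "+" else "")
  nodes <- data.frame(
    key = net$nodes$key,
    formula = formula_str,
    class = net$nodes$cation_class,
    round_found = net$nodes$round_found,
    energy = ifelse(is.na(net$nodes$energy_kcal), "",
                    format(net$nodes$energy_kcal)),
    stringsAsFactors = FALSE
  )
  write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  edges <- net$edges[, c("reactant_key", "product_key", "rtype", "a1", "a2")]
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               rtype = net$edges$rtype, a1 = net$edges$a1, a2 = net$edges$a2),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(net$nodes)),
                          key = net$nodes$key,
                          class = net$nodes$cation_class,
                          round_found = net$nodes$round_found)
  )
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  uk <- unique(net$nodes$skeleton_key)
  n_cyc <- sum(vapply(uk, function(k)
    nzchar(k) && classify_topology(k) != "ACYCLIC", logical(1)))
  manifest <- list(
    package = "cationet",
    version = as.character(utils::packageVersion("cationet")),
    config = config_as_list(net$config),
    seeds = net$seeds,
    rounds = net$rounds,
    totals = list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                  cyclic_skeletons = n_cyc),
    wall_clock_sec = wall_clock
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reaction network from a directory
#'
#' Rebuilds a `reaction_network` from `nodes.tsv` and `edges.tsv` written
#' by [write_network()]; node graphs, classes and skeletons are recomputed
#' from the stored keys (round-trip: parsing a stored key reproduces it
#' exactly).
#'
#' @param dir Directory containing the serialized network.
#' @return A `reaction_network`.
#' @export
read_network <- function(dir) {
  nf <- file.path(dir, "nodes.tsv")
  ef <- file.path(dir, "edges.tsv")
  if (!file.exists(nf) || !file.exists(ef))
    stop("not a network directory (missing nodes.tsv / edges.tsv): ", dir)
  nt <- read.delim(nf, stringsAsFactors = FALSE)
  if (!nrow(nt)) stop("empty network file: ", nf)
  et <- read.delim(ef, stringsAsFactors = FALSE)
  graphs <- lapply(nt$key, parse_smiles)
  nodes <- data.frame(
    key = nt$key,
    round_found = nt$round_found,
    cation_class = nt$class,
    skeleton_key = vapply(graphs, function(g) extract_skeleton(g)$key, character(1)),
    energy_kcal = suppressWarnings(as.numeric(nt$energy)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = match(et$reactant_key, nodes$key),
    to = match(et$product_key, nodes$key),
    reactant_key = et$reactant_key,
    product_key = et$product_key,
    rtype = et$rtype, a1 = et$a1, a2 = et$a2,
    stringsAsFactors = FALSE
  )
  mf <- file.path(dir, "manifest.json")
  seeds <- nodes$key[nodes$round_found == 0]
  config <- enum_config()
  if (file.exists(mf)) {
    man <- jsonlite::fromJSON(mf)
    if (!is.null(man$seeds)) seeds <- man$seeds
    if (!is.null(man$config$step_offset))
      config$step_offset <- as.integer(man$config$step_offset)
  }
  structure(list(nodes = nodes, edges = edges, seeds = seeds,
                 rounds = NULL, config = config),
            class = "reaction_network")
}

#' Write a skeleton report
#'
#' Writes the clustered skeleton table as `skeletons.tsv` and
#' `skeletons.json` with columns framework key (SMILES), topology,
#' n_carbocation, log10_n, min_step, and the EC-reference flag.
#'
#' @param tbl A table from [cluster_network()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_skeleton_report <- function(tbl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- tbl
  names(out)[names(out) == "skeleton_key"] <- "framework_key"
  write.table(out, file.path(dir, "skeletons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out, file.path(dir, "skeletons.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Generate fixture SMILES files
#'
#' Writes the programmatic test fixtures as SMILES files (one species per
#' line, tab-separated name column): `alkanes` (linear alkane cations
#' C4-C10), `textbook_cations` (allyl, homoallyl, neopentyl,
#' cyclopropylcarbinyl, tert-butyl and friends), or `monoterpene_seeds`
#' (geranyl/neryl- and linalyl-type cations plus the cyclized
#' intermediates).
#'
#' @param kind One of `"alkanes"`, `"textbook_cations"`,
#'   `"monoterpene_seeds"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
fixture_generator <- function(kind = c("alkanes", "textbook_cations",
                                       "monoterpene_seeds"),
                              path) {
  kind <- match.arg(kind)
  entries <- switch(kind,
    alkanes = {
      sm <- vapply(4:10, function(n)
        canonical_key(linear_alkane_cation(n)), character(1))
      data.frame(smiles = sm, name = paste0("1-C", 4:10, "-cation"))
    },
    textbook_cations = data.frame(
      smiles = c("[CH2+]C=C", "C=CC[CH2+]", "CC(C)(C)[CH2+]",
                 "[CH2+]C1CC1", "C[C+](C)C", "CC[CH+]C", "CC(C)[CH2+]",
                 "[CH+]1CCC1"),
      name = c("allyl", "homoallyl", "neopentyl", "cyclopropylcarbinyl",
               "tert-butyl", "2-butyl", "isobutyl", "cyclobutyl")
    ),
    monoterpene_seeds = {
      seeds <- cyclization_seeds()
      lin <- linear_monoterpene_cation()
      lina <- resonance_forms(lin)
      keys <- names(lina)
      data.frame(
        smiles = c(keys, canonical_key(seeds$ring6), canonical_key(seeds$ring7)),
        name = c("linear-allylic(geranyl/neryl)",
                 rep("linalyl-type", length(keys) - 1),
                 "1,6-cyclized(alpha-terpinyl-type)", "1,7-cyclized")
      )
    })
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(entries$smiles, entries$name, sep = "\t"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# command entry points (the CLI script is a thin wrapper over these)
# ---------------------------------------------------------------------------

#' Run an enumeration and serialize the results
#'
#' @param seeds Character vector of seed SMILES (default: the linear
#'   monoterpene cation).
#' @param out Output directory.
#' @param rounds Maximum rounds (`Inf` for fixpoint).
#' @param types Enabled reaction types.
#' @param filter Stability mode.
#' @param cutoff Energy cutoff (kcal/mol), energy-plugin mode only.
#' @param shift_range Through-bond shift range (`Inf` for unlimited).
#' @param stereo,geometry Mode toggles.
#' @param plugin Optional [energy_plugin()].
#' @return The `reaction_network`, invisibly; side effect: files in `out`.
#' @export
cmd_enumerate <- function(seeds = NULL, out,
                          rounds = 10, types = reaction_types(),
                          filter = "heuristic", cutoff = 0,
                          shift_range = 4, stereo = FALSE, geometry = FALSE,
                          plugin = NULL) {
  if (is.null(seeds) || !length(seeds))
    seeds <- canonical_key(linear_monoterpene_cation())
  config <- enum_config(
    enabled_types = types, max_rounds = rounds,
    stability = stability_config(filter, cutoff_kcal = cutoff),
    stereo_enabled = stereo, geometry_enabled = geometry,
    shift_range_bonds = shift_range
  )
  t0 <- proc.time()[["elapsed"]]
  net <- run_enumeration(as.list(seeds), config, plugin = plugin)
  write_network(net, out, wall_clock = proc.time()[["elapsed"]] - t0)
  for (r in seq_len(nrow(net$rounds)))
    message(sprintf("round %d: +%d nodes, +%d edges (cumulative %d / %d)",
                    net$rounds$round[r], net$rounds$new_nodes[r],
                    net$rounds$new_edges[r],
                    cumsum(net$rounds$new_nodes)[r],
                    cumsum(net$rounds$new_edges)[r]))
  invisible(net)
}

#' Cluster a serialized network into a skeleton report
#'
#' @param network_dir Directory written by [cmd_enumerate()].
#' @param out Output directory for the report (defaults to `network_dir`).
#' @return The skeleton table, invisibly.
#' @export
cmd_skeletons <- function(network_dir, out = network_dir) {
  net <- read_network(network_dir)
  tbl <- cluster_network(net)
  write_skeleton_report(tbl, out)
  counts <- table(tbl$topology)
  message(sprintf("%d cyclic skeletons (%s)", nrow(tbl),
                  paste(names(counts), counts, sep = "=", collapse = ", ")))
  invisible(tbl)
}

#' Run the alkane-cation validation and report
#'
#' @param carbons Integer vector of chain lengths in 4..10.
#' @return The validation table, invisibly; signals an error if any row
#'   mismatches (the CLI maps this to a nonzero exit).
#' @export
cmd_validate_alkanes <- function(carbons = 4:8) {
  tbl <- validate_alkanes(carbons)
  for (r in seq_len(nrow(tbl)))
    message(sprintf("C%d: found %d, oracle %d, %s", tbl$n[r], tbl$found[r],
                    tbl$oracle[r], if (tbl$match[r]) "match" else "MISMATCH"))
  if (!all(tbl$match)) stop("alkane validation mismatch")
  invisible(tbl)
}
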