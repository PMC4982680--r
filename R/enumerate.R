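# Breadth-first closure engine: rounds of product generation, canonical
# deduplication, stability filtering, and network assembly.
#
# Two execution paths build identical structures: a C++ kernel (the fast
# path for permissive/heuristic topological runs, used by default) and an R
# reference path built directly on enumerate_products(), used when an
# energy plugin or geometric gating is active. The suite cross-checks the
# two on small closures.

#' Enumeration run configuration
#'
#' @param enabled_types Reaction types to apply; see [reaction_types()].
#'   `RESONANCE` enables the zero-step allylic bookkeeping edges (resonance
#'   partners are inserted in the same round as the node that generated
#'   them and never increment route length).
#' @param max_rounds Maximum number of breadth-first rounds, or `Inf` to run
#'   to fixpoint. The default 10 saturates the monoterpene skeleton space:
#'   products needing more than 5 rearrangement steps are already unusual in
#'   characterized enzymes.
#' @param stability A [stability_config()].
#' @param stereo_enabled Reserved flag for configurational keys (default
#'   off; constitutional mode collapses stereoisomers).
#' @param geometry_enabled Use 3D distance gating (see [geometry_config()])
#'   instead of the topological shift range; runs on the R reference path.
#' @param shift_range_bonds Through-bond carbon separation limit for hydride
#'   shifts and proton transfers in topological mode (default 4; `Inf` for
#'   unlimited, mirroring unrestricted early rounds).
#' @param geometry A [geometry_config()] consulted when `geometry_enabled`.
#' @param step_offset Added to breadth-first hop counts when reporting route
#'   "steps": with the default linear seed the offset 2 makes step 1 the
#'   creation of the trans linear cation and step 2 the trans/cis
#'   isomerization (which constitutional mode collapses), so the first
#'   cyclic skeletons appear at step 3. Seeding directly from cyclized
#'   intermediates uses offset 3.
#' @return An `enum_config` object.
#' @export
enum_config <- function(enabled_types = reaction_types(),
                        max_rounds = 10,
                        stability = stability_config(),
                        stereo_enabled = FALSE,
                        geometry_enabled = FALSE,
                        shift_range_bonds = 4,
                        geometry = geometry_config(),
                        step_offset = 2L) {
  enabled_types <- match.arg(enabled_types, reaction_types(), several.ok = TRUE)
  if (!is.infinite(max_rounds) && max_rounds < 1) stop("max_rounds must be >= 1")
  structure(
    list(enabled_types = enabled_types,
         max_rounds = max_rounds,
         stability = stability,
         stereo_enabled = isTRUE(stereo_enabled),
         geometry_enabled = isTRUE(geometry_enabled),
         shift_range_bonds = shift_range_bonds,
         geometry = geometry,
         step_offset = as.integer(step_offset)),
    class = "enum_config"
  )
}

#' The linear monoterpene substrate cation
#'
#' The C10H17+ allylic cation formed by ionization of the linear C10
#' diphosphate substrate. The cis (neryl) and trans (geranyl) forms are
#' constitutional-mode equivalents and collapse to one node; the tertiary
#' allylic (linalyl-type) resonance partner is added automatically by
#' [run_enumeration()].
#'
#' @param isomer `"neryl"` (cis, the cyclization-competent default) or
#'   `"geranyl"` (trans); identical under constitutional keys.
#' @return A [cation_graph()].
#' @export
linear_monoterpene_cation <- function(isomer = c("neryl", "geranyl")) {
  match.arg(isomer)
  parse_smiles("CC(C)=CCCC(C)=C[CH2+]")
}

#' The cyclized monoterpene intermediates
#'
#' The first-cyclization intermediates: the 1,6-ring closure
#' (alpha-terpinyl-type cyclohexene cation) and the 1,7-ring closure
#' (cycloheptenyl cation) of the cis-linear substrate cation. In
#' constitutional mode the stereo-differing pair of 1,6 closures collapses
#' to one species. These sit at shortest-route step 3 (step 1 creates the
#' trans linear cation, step 2 is trans/cis isomerization).
#'
#' @return Named list of [cation_graph()] objects
#'   (`ring6` = 1,6-closure, `ring7` = 1,7-closure).
#' @export
cyclization_seeds <- function() {
  lin <- linear_monoterpene_cation()
  prods <- enumerate_products(
    lin, enum_config(enabled_types = "ALKYLATION", shift_range_bonds = Inf))
  keys <- vapply(prods, function(p) p$event$product_key, character(1))
  rings <- vapply(prods, function(p) {
    sk <- extract_skeleton(p$graph)
    nrow(sk$bonds) - sk$n_carbons + 1L  # cyclomatic number
  }, integer(1))
  size6 <- vapply(prods, function(p) {
    sk <- extract_skeleton(p$graph); sk$n_carbons
  }, integer(1))
  out <- list(ring6 = prods[[which(rings == 1 & size6 == 6)[1]]]$graph,
              ring7 = prods[[which(rings == 1 & size6 == 7)[1]]]$graph)
  out
}

normalize_seeds <- function(seeds) {
  if (inherits(seeds, "cation_graph")) seeds <- list(seeds)
  seeds <- lapply(seeds, function(s) if (is.character(s)) parse_smiles(s) else s)
  if (!length(seeds)) stop("empty seed list")
  ok <- vapply(seeds, inherits, logical(1), what = "cation_graph")
  if (!all(ok)) stop("seeds must be cation_graph objects or SMILES strings")
  f <- vapply(seeds, function(s) paste(cation_formula(s), collapse = "/"), character(1))
  if (length(unique(f)) != 1) stop("seeds have inconsistent formulas")
  if (any(vapply(seeds, function(s) is.na(s$charge_site), logical(1))))
    stop("seeds must be cations")
  seeds
}

#' Enumerate the carbocation rearrangement network
#'
#' Breadth-first closure: every enabled operator is applied to every
#' reactive atom of every frontier species; products are canonicalized,
#' deduplicated, stability-filtered, and become the next round's frontier.
#' Terminates at fixpoint (no new species) or after `max_rounds`. Allylic
#' resonance partners of every inserted node are inserted in the same round,
#' joined by zero-step `RESONANCE` edges. Seeds are always retained
#' (the reference species must be in-network). Edges are stored directed,
#' one per generating event; degenerate self-edges are dropped.
#'
#' @param seeds A [cation_graph()], SMILES string, or list of either; all
#'   seeds must share one formula.
#' @param config An [enum_config()].
#' @param plugin An [energy_plugin()], required when the stability mode is
#'   `energy_plugin`.
#' @return A `reaction_network`: list with `nodes` (data frame: `key`,
#'   `round_found`, `cation_class`, `skeleton_key`, `energy_kcal`), `edges`
#'   (data frame: `from`, `to`, `reactant_key`, `product_key`, `rtype`,
#'   `a1`, `a2` — participating carbons in the reactant's canonical atom
#'   order), `seeds`, `rounds` (per-round counters), and `config`.
#' @examples
#' net <- run_enumeration("C=CC[CH2+]", enum_config(
#'   stability = stability_config("permissive"), max_rounds = Inf,
#'   shift_range_bonds = Inf))
#' net$nodes$key  # the closed constitutional C4H7+ space of the homoallyl cation
#' @export
run_enumeration <- function(seeds, config = enum_config(), plugin = NULL) {
  stopifnot(inherits(config, "enum_config"))
  seeds <- normalize_seeds(seeds)
  slow <- config$stability$mode == "energy_plugin" || config$geometry_enabled
  net <- if (slow) r_enumerate(seeds, config, plugin)
         else kernel_enumerate(seeds, config)
  net$config <- config
  class(net) <- "reaction_network"
  net
}

kernel_enumerate <- function(seeds, config) {
  types <- rtype_code(config$enabled_types)
  range <- if (is.infinite(config$shift_range_bonds)) -1L
           else as.integer(config$shift_range_bonds)
  rounds <- if (is.infinite(config$max_rounds)) -1L
            else as.integer(config$max_rounds)
  fmode <- switch(config$stability$mode, permissive = 0L, heuristic = 1L)
  rmask <- sum(c(primary = 1L, secondary = 2L)[config$stability$reject_classes])
  res <- cpp_enumerate(lapply(seeds, as_heavy), types, range, rounds,
                       fmode, as.integer(rmask))
  nodes <- data.frame(
    key = res$smiles,
    round_found = res$round,
    cation_class = class_label(res$class),
    skeleton_key = res$skeleton,
    energy_kcal = NA_real_,
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = res$edges[, 1], to = res$edges[, 2],
    reactant_key = res$smiles[res$edges[, 1]],
    product_key = res$smiles[res$edges[, 2]],
    rtype = rtype_name(res$edges[, 3]),
    a1 = res$edges[, 4], a2 = res$edges[, 5],
    stringsAsFactors = FALSE
  )
  list(nodes = nodes, edges = edges,
       seeds = vapply(seeds, canonical_key, character(1)),
       rounds = data.frame(round = seq_along(res$round_new_nodes) - 1L,
                           new_nodes = res$round_new_nodes,
                           new_edges = res$round_new_edges))
}

# R reference path: used for energy-plugin filtering and geometric gating.
r_enumerate <- function(seeds, config, plugin = NULL) {
  st <- new.env(parent = emptyenv())
  st$keys <- character(0)
  st$graphs <- list()
  st$round <- integer(0)
  st$class <- character(0)
  st$energy <- numeric(0)
  st$edges <- list()
  st$edge_keys <- character(0)
  gate_types <- c("HYDRIDE_SHIFT", "PROTON_TRANSFER")

  keep <- function(g) passes_filter(g, config$stability, plugin)
  node_energy <- function(g) {
    if (config$stability$mode == "energy_plugin") plugin$evaluate(g) else NA_real_
  }
  insert <- function(g, round, force = FALSE) {
    key <- canonical_key(g)
    id <- match(key, st$keys)
    if (!is.na(id)) return(id)
    if (!force && !keep(g)) return(NA_integer_)
    st$keys <- c(st$keys, key)
    st$graphs[[length(st$graphs) + 1L]] <- g
    st$round <- c(st$round, round)
    st$class <- c(st$class, classify_cation(g))
    st$energy <- c(st$energy, node_energy(g))
    id <- length(st$keys)
    # resonance closure at the same round (zero-step edges)
    if ("RESONANCE" %in% config$enabled_types) {
      forms <- resonance_forms(g)
      for (rkey in setdiff(names(forms), key)) {
        rid <- insert(forms[[rkey]], round, force = force)
        if (!is.na(rid))
          add_edge(id, rid, "RESONANCE",
                   c(heavy_index(g, g$charge_site),
                     heavy_index(forms[[rkey]], forms[[rkey]]$charge_site)))
      }
    }
    id
  }
  add_edge <- function(from, to, rtype, atoms) {
    ek <- paste(from, to, rtype, paste(atoms, collapse = "."), sep = "|")
    if (ek %in% st$edge_keys) return(invisible())
    st$edge_keys <- c(st$edge_keys, ek)
    st$edges[[length(st$edges) + 1L]] <-
      list(from = from, to = to, rtype = rtype,
           a1 = atoms[1], a2 = atoms[2])
  }

  for (s in seeds) insert(s, 0L, force = TRUE)
  rounds_new_nodes <- length(st$keys)
  rounds_new_edges <- length(st$edges)
  pconf <- config
  if (config$geometry_enabled) pconf$shift_range_bonds <- Inf
  frontier <- seq_along(st$keys)
  round <- 0L
  while (length(frontier) &&
         (is.infinite(config$max_rounds) || round < config$max_rounds)) {
    round <- round + 1L
    nodes_before <- length(st$keys)
    edges_before <- length(st$edges)
    for (id in frontier) {
      g <- st$graphs[[id]]
      if (config$geometry_enabled && is.null(g$coords))
        g$coords <- embed_coords(g, config$geometry)
      for (p in enumerate_products(g, pconf)) {
        if (p$event$rtype == "RESONANCE") next # closure handles these
        if (config$geometry_enabled && p$event$rtype %in% gate_types) {
          pair <- p$event$atoms
          if (!distance_gate(g, pair[1], pair[2], round, config$geometry)) next
        }
        if (p$event$product_key == st$keys[id]) next # degenerate self edge
        pid <- insert(p$graph, round)
        if (!is.na(pid))
          add_edge(id, pid, p$event$rtype,
                   heavy_index(g, p$event$atoms))
      }
    }
    frontier <- seq_len(length(st$keys))[-seq_len(nodes_before)]
    rounds_new_nodes <- c(rounds_new_nodes, length(st$keys) - nodes_before)
    rounds_new_edges <- c(rounds_new_edges, length(st$edges) - edges_before)
    if (!length(frontier)) break
  }

  edges <- do.call(rbind, lapply(st$edges, as.data.frame))
  if (is.null(edges))
    edges <- data.frame(from = integer(0), to = integer(0),
                        rtype = character(0), a1 = integer(0), a2 = integer(0))
  edges$reactant_key <- st$keys[edges$from]
  edges$product_key <- st$keys[edges$to]
  edges <- edges[, c("from", "to", "reactant_key", "product_key", "rtype", "a1", "a2")]
  nodes <- data.frame(
    key = st$keys,
    round_found = st$round,
    cation_class = st$class,
    skeleton_key = vapply(st$graphs, function(g) extract_skeleton(g)$key, character(1)),
    energy_kcal = st$energy,
    stringsAsFactors = FALSE
  )
  list(nodes = nodes, edges = edges,
       seeds = vapply(seeds, canonical_key, character(1)),
       rounds = data.frame(round = seq_along(rounds_new_nodes) - 1L,
                           new_nodes = rounds_new_nodes,
                           new_edges = rounds_new_edges))
}

# index of an explicit-graph atom among the carbons (heavy-atom numbering);
# for an H atom, the bearing carbon is reported
heavy_index <- function(g, atoms) {
  cidx <- which(g$atoms == "C")
  vapply(as.integer(atoms), function(a) {
    if (g$atoms[a] == "H") {
      b <- g$bonds
      a <- setdiff(as.vector(b[b[, 1] == a | b[, 2] == a, 1:2]), a)
    }
    match(a, cidx)
  }, integer(1))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d nodes, %d edges, %d seed(s), %d round(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$seeds),
              max(x$nodes$round_found)))
  invisible(x)
}

#' Insert a candidate species into a network
#'
#' The deduplication step of the engine, exposed for incremental use: the
#' node is inserted iff its canonical key is unseen; the edge is recorded
#' unless an identical event already exists; degenerate self-edges
#' (product key equal to reactant key) are dropped.
#'
#' @param network A `reaction_network`.
#' @param candidate A [cation_graph()] that already passed filtering.
#' @param event A `reaction_event` whose `reactant_key` is in the network.
#' @return List with the updated `network` and `inserted` (`TRUE` iff a new
#'   node was created).
#' @export
dedup_insert <- function(network, candidate, event) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(candidate, "cation_graph"),
            inherits(event, "reaction_event"))
  key <- canonical_key(candidate)
  from <- match(event$reactant_key, network$nodes$key)
  if (is.na(from)) stop("event reactant is not in the network")
  inserted <- FALSE
  to <- match(key, network$nodes$key)
  if (is.na(to)) {
    network$nodes <- rbind(network$nodes, data.frame(
      key = key,
      round_found = network$nodes$round_found[from] + 1L,
      cation_class = classify_cation(candidate),
      skeleton_key = extract_skeleton(candidate)$key,
      energy_kcal = NA_real_, stringsAsFactors = FALSE))
    to <- nrow(network$nodes)
    inserted <- TRUE
  }
  if (key != event$reactant_key) {
    atoms <- heavy_index_safe(event$atoms)
    e <- network$edges
    dup <- e$from == from & e$to == to & e$rtype == event$rtype &
      e$a1 == atoms[1] & e$a2 == atoms[2]
    if (!any(dup, na.rm = TRUE)) {
      network$edges <- rbind(network$edges, data.frame(
        from = from, to = to,
        reactant_key = event$reactant_key, product_key = key,
        rtype = event$rtype, a1 = atoms[1], a2 = atoms[2],
        stringsAsFactors = FALSE))
    }
  }
  list(network = network, inserted = inserted)
}

heavy_index_safe <- function(atoms) {
  atoms <- as.integer(atoms)
  c(atoms, NA_integer_, NA_integer_)[1:2]
}

# ---------------------------------------------------------------------------
# alkane validation: closure from the linear cation vs brute-force oracle
# ---------------------------------------------------------------------------

linear_alkane_cation <- function(n) {
  stopifnot(n >= 2)
  bo <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) bo[i, i + 1] <- bo[i + 1, i] <- 1L
  heavy_to_graph(list(n = as.integer(n), charge = 1L, bo = bo))
}

#' Brute-force oracle: all constitutional alkane-cation isomers
#'
#' Independently of the reaction engine, generates every constitutional
#' CnH(2n+1)+ isomer: all carbon trees on `n` vertices with maximum degree 4
#' (grown one leaf at a time with canonical deduplication), crossed with
#' every cation placement on a hydrogen-bearing carbon (degree at most 3),
#' deduplicated by canonical key.
#'
#' @param n Number of carbons (2 to 10).
#' @return Character vector of canonical SMILES keys, sorted.
#' @export
alkane_cation_isomers <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2, n <= 10)
  trees <- list(list(n = 1L, charge = 0L, bo = matrix(0L, 1, 1)))
  for (k in 2:n) {
    grown <- list()
    seen <- character(0)
    for (tr in trees) {
      deg <- rowSums(tr$bo > 0)
      for (v in which(deg < 4)) {
        bo <- rbind(cbind(tr$bo, 0L), 0L)
        bo[v, k] <- bo[k, v] <- 1L
        cand <- list(n = k, charge = 0L, bo = bo)
        key <- cpp_canon(cand)$smiles
        if (!key %in% seen) { seen <- c(seen, key); grown[[length(grown) + 1L]] <- cand }
      }
    }
    trees <- grown
  }
  keys <- character(0)
  for (tr in trees) {
    deg <- rowSums(tr$bo > 0)
    for (v in which(deg <= 3)) {
      cat_mol <- tr
      cat_mol$charge <- v
      keys <- c(keys, cpp_canon(cat_mol)$smiles)
    }
  }
  sort(unique(keys))
}

#' Validate the engine against the alkane-cation oracle
#'
#' The engine's validation experiment: enumerate from the linear 1-alkyl
#' cation with reaction types 2-4 only (alkyl shift, hydride shift, methyl
#' shift; alkylation and proton transfer do not apply to saturated species),
#' permissive filter, unlimited shift range, and compare the closed set
#' against the independent brute-force isomer oracle.
#'
#' @param n_carbons Integer vector of chain lengths, each in 4..10.
#' @return Data frame with columns `n`, `found`, `oracle`, `match`.
#' @examples
#' validate_alkanes(4:6)
#' @export
validate_alkanes <- function(n_carbons) {
  n_carbons <- as.integer(n_carbons)
  if (any(n_carbons < 4 | n_carbons > 10))
    stop("n_carbons must be within 4..10")
  rows <- lapply(n_carbons, function(n) {
    net <- run_enumeration(
      linear_alkane_cation(n),
      enum_config(
        enabled_types = c("ALKYL_SHIFT", "HYDRIDE_SHIFT", "METHYL_SHIFT"),
        max_rounds = Inf,
        shift_range_bonds = Inf,
        stability = stability_config("permissive")
      )
    )
    found <- sort(net$nodes$key)
    oracle <- alkane_cation_isomers(n)
    data.frame(n = n, found = length(found), oracle = length(oracle),
               match = identical(found, oracle))
  })
  do.call(rbind, rows)
}
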