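# Skeleton extraction and ring-topology classification.
#
# A skeleton is the neutralized carbon framework of a cation with the
# saturated alkyl side chains pruned away: what remains is the ring system
# plus the double-bond placement, which is how the product chemical space is
# organized. Neutralization is a hydride quench at the cation centre — the
# unique convention that leaves the species' alkene pattern untouched
# (deprotonation would create a new alkene and change the skeleton
# identity).

#' Neutralize a carbocation by hydride quench
#'
#' Adds one hydrogen at the charge site and clears the charge; no double
#' bond is created or destroyed.
#'
#' @param g A charged [cation_graph()].
#' @return A neutral [cation_graph()] with one more hydrogen.
#' @examples
#' cation_formula(neutralize(parse_smiles("C[C+](C)C")))  # isobutane, C4H10
#' @export
neutralize <- function(g) {
  stopifnot(inherits(g, "cation_graph"))
  if (is.na(g$charge_site)) stop("species is already neutral")
  atoms <- c(g$atoms, "H")
  bonds <- rbind(g$bonds, c(g$charge_site, length(atoms), 1L))
  cation_graph(atoms, bonds, charge_site = NA_integer_)
}

#' Extract the skeleton of a species
#'
#' Neutralizes (if charged), drops hydrogens, and iteratively deletes
#' carbons of degree 1 that are not part of a double bond, to fixpoint;
#' the remaining framework is canonicalized. Exocyclic alkene carbons
#' survive pruning (a double bond is never a saturated side chain). The
#' operation is idempotent: pruning a pruned framework is the identity.
#'
#' @param g A [cation_graph()] (charged or neutral).
#' @return A `skeleton` object: list with `key` (canonical SMILES of the
#'   framework; `""` for a fully saturated acyclic species, which prunes to
#'   nothing), `n_carbons`, and `bonds` (carbon framework bond matrix).
#' @examples
#' # the alpha-terpinyl cation prunes to the cyclohexene framework
#' sk <- extract_skeleton(parse_smiles("CC=1CCC(CC=1)[C+](C)C"))
#' sk$key
#' @export
extract_skeleton <- function(g) {
  stopifnot(inherits(g, "cation_graph"))
  res <- cpp_skeleton(as_heavy(g))
  if (identical(res$smiles, "")) {
    return(structure(list(key = "", n_carbons = 0L,
                          bonds = matrix(integer(0), 0, 3)),
                     class = "skeleton"))
  }
  mol <- res$mol
  idx <- which(upper.tri(mol$bo) & mol$bo > 0, arr.ind = TRUE)
  bonds <- cbind(idx, mol$bo[idx])
  colnames(bonds) <- c("i", "j", "order")
  structure(list(key = res$smiles, n_carbons = mol$n, bonds = bonds),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %s (%d C, %s)\n",
              if (nzchar(x$key)) x$key else "<empty>",
              x$n_carbons,
              tryCatch(classify_topology(x), error = function(e) "?")))
  invisible(x)
}

skeleton_from_key <- function(key) {
  if (!nzchar(key))
    return(structure(list(key = "", n_carbons = 0L,
                          bonds = matrix(integer(0), 0, 3)),
                     class = "skeleton"))
  extract_skeleton(parse_smiles(key))
}

# ---------------------------------------------------------------------------
# ring perception (SSSR) for frameworks with cyclomatic number <= 2
# ---------------------------------------------------------------------------

skeleton_adjacency <- function(s) {
  n <- s$n_carbons
  adj <- matrix(FALSE, n, n)
  if (nrow(s$bonds)) {
    adj[s$bonds[, 1:2, drop = FALSE]] <- TRUE
    adj[s$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  adj
}

# shortest cycle through a given edge: BFS from i to j avoiding the edge
shortest_cycle_through <- function(adj, i, j) {
  n <- nrow(adj)
  prev <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  dist[i] <- 0L
  queue <- i
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in which(adj[u, ])) {
      if ((u == i && v == j) || (u == j && v == i)) next
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L; prev[v] <- u; queue <- c(queue, v)
      }
    }
  }
  if (is.na(dist[j])) return(NULL)
  path <- j
  while (path[1] != i) path <- c(prev[path[1]], path)
  path
}

#' Smallest set of smallest rings of a skeleton
#'
#' Ring perception for frameworks of cyclomatic number at most 2 (the bound
#' imposed by the degree of unsaturation of the C10H17+ space): for each
#' non-bridge edge the shortest cycle through it is found by breadth-first
#' search, and a minimal independent set of these cycles (greedily by size)
#' is returned.
#'
#' @param s A `skeleton`.
#' @return List of integer vectors, each the ordered atoms of one ring.
#' @export
skeleton_rings <- function(s) {
  n <- s$n_carbons
  if (n == 0) return(list())
  m <- nrow(s$bonds)
  mu <- m - n + 1L  # connected framework
  if (mu <= 0) return(list())
  adj <- skeleton_adjacency(s)
  cycles <- list()
  for (k in seq_len(m)) {
    cyc <- shortest_cycle_through(adj, s$bonds[k, 1], s$bonds[k, 2])
    if (!is.null(cyc)) cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles <- cycles[order(lengths(cycles))]
  # greedy independent selection via GF(2) edge-space rank
  edge_id <- function(cyc) {
    e <- cbind(cyc, c(cyc[-1], cyc[1]))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  basis <- list()
  vecs <- list()
  all_edges <- paste(pmin(s$bonds[, 1], s$bonds[, 2]),
                     pmax(s$bonds[, 1], s$bonds[, 2]))
  to_vec <- function(cyc) as.integer(all_edges %in% edge_id(cyc))
  reduce <- function(v, basis) {
    for (b in basis) {
      pivot <- which(b == 1L)[1]
      if (v[pivot] == 1L) v <- (v + b) %% 2L
    }
    v
  }
  for (cyc in cycles) {
    if (length(basis) == mu) break
    v <- reduce(to_vec(cyc), vecs)
    if (any(v == 1L)) {
      basis[[length(basis) + 1L]] <- cyc
      vecs[[length(vecs) + 1L]] <- v
    }
  }
  basis
}

#' Ring-topology class of a skeleton
#'
#' Classifies the framework into the five cyclic groups of the monoterpene
#' skeleton space (plus `ACYCLIC`): `MONOCYCLIC` (one ring — for C10H17+
#' skeletons necessarily one ring plus one double bond); for two-ring
#' systems, by the atoms the SSSR rings share: three or more atoms (or two
#' non-adjacent atoms) is `BRIDGED`, exactly one bond (two adjacent atoms)
#' is `FUSED`, exactly one atom is `SPIRO`, and none is `SEPARATED` (two
#' rings joined by an acyclic linker — fully disjoint rings cannot occur in
#' a connected molecule).
#'
#' @param s A `skeleton` (or a framework canonical key).
#' @return One of `"ACYCLIC"`, `"MONOCYCLIC"`, `"BRIDGED"`, `"FUSED"`,
#'   `"SPIRO"`, `"SEPARATED"`.
#' @export
classify_topology <- function(s) {
  if (is.character(s)) s <- skeleton_from_key(s)
  stopifnot(inherits(s, "skeleton"))
  rings <- skeleton_rings(s)
  if (length(rings) == 0) return("ACYCLIC")
  if (length(rings) == 1) return("MONOCYCLIC")
  if (length(rings) > 2)
    stop("more than two rings: outside the degree-of-unsaturation bound of this space")
  shared <- intersect(rings[[1]], rings[[2]])
  if (length(shared) == 0) return("SEPARATED")
  if (length(shared) == 1) return("SPIRO")
  if (length(shared) == 2) {
    adj <- skeleton_adjacency(s)
    if (adj[shared[1], shared[2]]) return("FUSED")
    return("BRIDGED")
  }
  "BRIDGED"
}

# ---------------------------------------------------------------------------
# clustering a network by skeleton
# ---------------------------------------------------------------------------

#' Reference skeletons of enzymatically characterized monoterpene products
#'
#' The five ring frameworks associated with EC-numbered monoterpene synthase
#' products: the menthane-type cyclohexene, and the pinane, bornane,
#' thujane, and carane ring frames. The list ships as an editable
#' configuration file (`inst/extdata/ec_reference_skeletons.smi`, one
#' SMILES and one name per line) and is canonicalized on load, so a curated
#' replacement list can be dropped in without code changes.
#'
#' @param file Optional path to an alternative reference list.
#' @return Named character vector: canonical framework keys, named by
#'   skeleton family.
#' @export
ec_reference_skeletons <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "ec_reference_skeletons.smi",
                        package = "cationet", mustWork = TRUE)
  tab <- read.delim(file, header = FALSE, comment.char = "#",
                    col.names = c("smiles", "name"), stringsAsFactors = FALSE)
  keys <- vapply(tab$smiles, function(s) canonical_key(parse_smiles(s)), character(1))
  setNames(keys, tab$name)
}

#' Cluster a reaction network by skeleton
#'
#' Groups the network's nodes by their skeleton framework and reports, per
#' distinct framework: the ring topology class, the number of member
#' carbocations (`n_carbocation`, with `log10_n` for the population-vs-step
#' scatter), the shortest-route step at which the skeleton is first reached
#' (`min_step`, in the step numbering where the linear substrate sits at
#' step 2 and the first cyclizations at step 3), and whether the framework
#' is on the EC reference list.
#'
#' @param net A `reaction_network` from [run_enumeration()].
#' @param ec_reference Named character vector of reference framework keys,
#'   as from [ec_reference_skeletons()], or `NULL` to skip the flag.
#' @param cyclic_only Drop acyclic frameworks (default `TRUE`; the skeleton
#'   space of interest is the cyclized one).
#' @return Data frame with columns `skeleton_key`, `topology`,
#'   `n_carbocation`, `log10_n`, `min_step`, `is_ec_reference`, sorted by
#'   `min_step` then descending population.
#' @export
cluster_network <- function(net, ec_reference = ec_reference_skeletons(),
                            cyclic_only = TRUE) {
  stopifnot(inherits(net, "reaction_network"))
  if (!nrow(net$nodes)) stop("empty network")
  steps <- node_steps(net)
  agg <- split(seq_len(nrow(net$nodes)), net$nodes$skeleton_key)
  tbl <- data.frame(
    skeleton_key = names(agg),
    n_carbocation = lengths(agg),
    min_step = vapply(agg, function(i) min(steps[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tbl$topology <- vapply(tbl$skeleton_key, classify_topology, character(1))
  tbl$log10_n <- log10(tbl$n_carbocation)
  tbl$is_ec_reference <- if (is.null(ec_reference)) NA else
    tbl$skeleton_key %in% ec_reference
  if (cyclic_only) tbl <- tbl[tbl$topology != "ACYCLIC", , drop = FALSE]
  tbl <- tbl[order(tbl$min_step, -tbl$n_carbocation, tbl$skeleton_key), ,
             drop = FALSE]
  rownames(tbl) <- NULL
  tbl[, c("skeleton_key", "topology", "n_carbocation", "log10_n",
          "min_step", "is_ec_reference")]
}
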