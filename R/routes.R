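# Shortest-route analysis over the reaction network.
#
# Step numbering follows the biogenetic ladder: step 1 is creation of the
# trans linear cation from the substrate, step 2 the trans/cis
# isomerization (both collapsed into the seed in constitutional mode), so a
# node h chemical transformations beyond the linear seed sits at step
# h + 2. RESONANCE edges cost 0: allylic partners never inflate step
# counts.

network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(net$nodes)))
  )
  igraph::E(g)$weight <- ifelse(net$edges$rtype == "RESONANCE", 0, 1)
  g
}

#' Shortest-route step count of every node
#'
#' Breadth-first shortest distances from the seed set over the directed
#' network, with zero-cost resonance edges, plus the step-numbering offset
#' stored in the run configuration.
#'
#' @param net A `reaction_network`.
#' @return Numeric vector of step counts aligned with `net$nodes`.
#' @export
node_steps <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  offset <- if (!is.null(net$config)) net$config$step_offset else 2L
  if (!nrow(net$edges))
    return(rep(offset, nrow(net$nodes)))
  g <- network_igraph(net)
  seed_ids <- match(net$seeds, net$nodes$key)
  d <- igraph::distances(g, v = seed_ids, mode = "out",
                         algorithm = "dijkstra")
  unname(apply(d, 2, min)) + offset
}

#' Shortest route from the seeds to a target species
#'
#' Deterministic shortest path (resonance edges free): among equally short
#' predecessors the lexicographically smallest node key is chosen, so the
#' reported route is reproducible across runs and platforms.
#'
#' @param net A `reaction_network`.
#' @param target Canonical key (or [cation_graph()]) of a network node.
#' @return A `route`: list with `node_keys` (seed to target), `events`
#'   (data frame of the edge per hop), and `step_count` (chemical hops plus
#'   the step-numbering offset; the seed itself sits at the offset, 2 for
#'   linear-seed runs).
#' @export
shortest_route <- function(net, target) {
  stopifnot(inherits(net, "reaction_network"))
  if (inherits(target, "cation_graph")) target <- canonical_key(target)
  tid <- match(target, net$nodes$key)
  if (is.na(tid)) stop("target is not in the network")
  offset <- if (!is.null(net$config)) net$config$step_offset else 2L
  seed_ids <- match(net$seeds, net$nodes$key)
  if (tid %in% seed_ids) {
    return(structure(list(node_keys = net$nodes$key[tid],
                          events = net$edges[0, ],
                          step_count = offset),
                     class = "route"))
  }
  g <- network_igraph(net)
  d <- igraph::distances(g, v = seed_ids, mode = "out")
  dist_to <- apply(d, 2, min)
  if (!is.finite(dist_to[tid])) stop("target is unreachable from the seeds")
  # walk back deterministically: predecessor with dist + w == dist, smallest key
  path <- tid
  events <- integer(0)
  cur <- tid
  while (!cur %in% seed_ids || dist_to[cur] > 0) {
    inc <- which(net$edges$to == cur)
    w <- ifelse(net$edges$rtype[inc] == "RESONANCE", 0, 1)
    ok <- inc[dist_to[net$edges$from[inc]] + w == dist_to[cur]]
    if (!length(ok)) stop("internal error: broken shortest-path tree")
    keys <- net$nodes$key[net$edges$from[ok]]
    pick <- ok[order(keys, net$edges$rtype[ok])][1]
    events <- c(pick, events)
    cur <- net$edges$from[pick]
    path <- c(cur, path)
  }
  structure(list(node_keys = net$nodes$key[path],
                 events = net$edges[events, , drop = FALSE],
                 step_count = unname(dist_to[tid]) + offset),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("<route> %d species, step count %d\n",
              length(x$node_keys), x$step_count))
  if (nrow(x$events)) {
    for (k in seq_len(nrow(x$events)))
      cat("  ", x$events$reactant_key[k], " --", x$events$rtype[k], "--> ",
          x$events$product_key[k], "\n", sep = "")
  } else {
    cat("  ", x$node_keys[1], " (seed)\n", sep = "")
  }
  invisible(x)
}

#' Fill per-skeleton minimum steps into a skeleton table
#'
#' Recomputes `min_step` for each skeleton as the minimum shortest-route
#' step count over its member nodes, and returns the table with the scatter
#' columns (`log10_n` vs `min_step`) refreshed.
#'
#' @param net A `reaction_network`.
#' @param skeleton_table A table from [cluster_network()].
#' @return The updated table.
#' @export
skeleton_min_steps <- function(net, skeleton_table) {
  stopifnot(inherits(net, "reaction_network"))
  steps <- node_steps(net)
  ms <- tapply(steps, net$nodes$skeleton_key, min)
  skeleton_table$min_step <- as.numeric(ms[skeleton_table$skeleton_key])
  skeleton_table
}
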