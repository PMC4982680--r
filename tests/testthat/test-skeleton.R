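test_that("neutralization is a hydride quench that preserves the alkene pattern", {
  ib <- neutralize(pg("tert_butyl"))
  expect_equal(cation_formula(ib), c(nC = 4L, nH = 10L, charge = 0L))
  ger <- neutralize(pg("geranyl"))
  expect_equal(cation_formula(ger), c(nC = 10L, nH = 18L, charge = 0L))
  expect_equal(sum(ger$bonds[, 3] == 2), sum(pg("geranyl")$bonds[, 3] == 2))
  expect_error(neutralize(ger), "already neutral")
})

test_that("skeleton extraction prunes saturated side chains to the ring frame", {
  ec <- ec_reference_skeletons()
  # alpha-terpinyl: methyl and isopropyl pruned, ring alkene kept
  sk <- extract_skeleton(pg("aterpinyl"))
  expect_identical(sk$key, unname(ec["menthane"]))
  expect_equal(sk$n_carbons, 6L)
  # pinyl-type cation (2nd-step alkylation of alpha-terpinyl) -> pinane frame
  at <- pg("aterpinyl")
  prods <- enumerate_products(at, permissive_cfg(enabled_types = "ALKYLATION"))
  frames <- vapply(prods, function(p) extract_skeleton(p$graph)$key, character(1))
  expect_true(ec["pinane"] %in% frames)
  expect_true(ec["bornane"] %in% frames)
  # an exocyclic methylene carbon is in a double bond and survives pruning
  exo <- parse_smiles("C=C1CCC[CH+]C1")
  expect_equal(extract_skeleton(exo)$n_carbons, 7L)
})

test_that("skeleton extraction is idempotent", {
  keys <- c(unname(ec_reference_skeletons()),
            extract_skeleton(pg("geranyl"))$key)
  for (k in keys)
    expect_identical(extract_skeleton(parse_smiles(k))$key, k)
  # fully saturated acyclic species prune to the empty framework
  expect_identical(extract_skeleton(pg("tert_butyl"))$key, "")
})

test_that("reference frameworks have the expected ring topologies", {
  ec <- ec_reference_skeletons()
  expect_length(ec, 5)
  top <- vapply(ec, classify_topology, character(1))
  expect_identical(unname(top["menthane"]), "MONOCYCLIC")
  expect_identical(unname(top["pinane"]), "BRIDGED")
  expect_identical(unname(top["bornane"]), "BRIDGED")
  expect_identical(unname(top["thujane"]), "FUSED")
  expect_identical(unname(top["carane"]), "FUSED")
})

test_that("topology classification covers the textbook two-ring archetypes", {
  expect_identical(classify_topology("C1CC2CCC1C2"), "BRIDGED")   # norbornane
  expect_identical(classify_topology("C1CC2CC2C1"), "FUSED")      # thujane core
  expect_identical(classify_topology("C1CCC2(CC1)CCCC2"), "SPIRO") # spiro[4.5]decane
  expect_identical(classify_topology("C1CC1C1CC1"), "SEPARATED")  # linked cyclopropanes
  expect_identical(classify_topology("C1CCC=CC1"), "MONOCYCLIC")
})

# construct a two-ring framework directly as a bond matrix
make_frame <- function(edges, n) {
  structure(list(key = "synthetic", n_carbons = n,
                 bonds = cbind(edges, rep(1L, nrow(edges)))),
            class = "skeleton")
}

theta_frame <- function(p, q, r) {
  # two branch vertices joined by three internally disjoint paths of
  # p, q, r edges
  n <- 2L
  edges <- NULL
  for (len in c(p, q, r)) {
    prev <- 1L
    if (len == 1) { edges <- rbind(edges, c(1L, 2L)); next }
    for (k in seq_len(len - 1)) {
      n <- n + 1L
      edges <- rbind(edges, c(prev, n))
      prev <- n
    }
    edges <- rbind(edges, c(prev, 2L))
  }
  make_frame(edges, n)
}

ring_path_frame <- function(a, b, link) {
  # rings of a and b atoms joined by a path of `link` edges (0 = spiro)
  ring <- function(start, size) {
    idx <- start:(start + size - 1)
    cbind(idx, c(idx[-1], idx[1]))
  }
  e1 <- ring(1L, a)
  if (link == 0) {
    idx2 <- c(1L, (a + 1L):(a + b - 1L))
    e2 <- cbind(idx2, c(idx2[-1], idx2[1]))
    return(make_frame(rbind(e1, e2), a + b - 1L))
  }
  n <- a
  prev <- 1L
  for (k in seq_len(link - 1)) {
    n <- n + 1L
    e1 <- rbind(e1, c(prev, n))
    prev <- n
  }
  start2 <- n + 1L
  e1 <- rbind(e1, c(prev, start2))
  idx2 <- start2:(start2 + b - 1L)
  e2 <- cbind(idx2, c(idx2[-1], idx2[1]))
  make_frame(rbind(e1, e2), start2 + b - 1L)
}

igraph_topology_oracle <- function(s) {
  g <- igraph::graph_from_edgelist(s$bonds[, 1:2, drop = FALSE], directed = FALSE)
  bc <- igraph::biconnected_components(g)
  blocks <- Filter(function(v) length(v) >= 3, bc$components)
  if (length(blocks) == 0) return("ACYCLIC")
  if (length(blocks) == 1) {
    sub <- igraph::induced_subgraph(g, blocks[[1]])
    if (igraph::ecount(sub) == igraph::vcount(sub)) return("MONOCYCLIC")
    branch <- igraph::V(sub)[igraph::degree(sub) >= 3]
    if (igraph::are_adjacent(sub, branch[1], branch[2])) "FUSED" else "BRIDGED"
  } else {
    shared <- length(intersect(as.integer(blocks[[1]]), as.integer(blocks[[2]])))
    if (shared >= 1) "SPIRO" else "SEPARATED"
  }
}

test_that("the SSSR classifier agrees with a biconnectivity oracle on all small two-ring frames", {
  frames <- list()
  for (p in 1:6) for (q in max(p, 2):6) for (r in q:6)
    if (p + q + r - 1 <= 10) frames[[length(frames) + 1L]] <- theta_frame(p, q, r)
  for (a in 3:7) for (b in a:7) for (link in 0:3)
    if (a + b - (link == 0) + max(link - 1, 0) <= 10)
      frames[[length(frames) + 1L]] <- ring_path_frame(a, b, link)
  expect_gt(length(frames), 50)
  for (s in frames)
    expect_identical(classify_topology(s), igraph_topology_oracle(s))
})

test_that("frameworks beyond two rings are refused", {
  tri <- make_frame(rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(4, 2), c(2, 5),
                          c(5, 3)), 5L)
  expect_error(classify_topology(tri), "two rings")
})

test_that("network clustering groups members by framework", {
  at <- pg("aterpinyl")
  net <- run_enumeration(at, permissive_cfg(enabled_types = "RESONANCE",
                                            max_rounds = 1))
  tbl <- cluster_network(net)
  expect_equal(nrow(tbl), 1)
  expect_identical(tbl$topology, "MONOCYCLIC")
  expect_equal(tbl$n_carbocation, 1L)
  # the terpinen-4-yl-type cation shares the cyclohexene frame: still 1 row
  t4 <- parse_smiles("CC1=CC[C+](C(C)C)CC1")
  expect_identical(extract_skeleton(t4)$key, extract_skeleton(at)$key)
  expect_equal(log10(tbl$n_carbocation), tbl$log10_n)
  expect_error(cluster_network(structure(list(nodes = data.frame()),
                                         class = "reaction_network")),
               "empty")
})
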