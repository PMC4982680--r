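test_that("the allyl cation space is closed under all operators", {
  net <- run_enumeration(pg("allyl"), permissive_cfg(max_rounds = Inf))
  expect_identical(net$nodes$key, key_of(fx$allyl))
  expect_equal(nrow(net$edges), 0)  # the symmetric resonance shift is degenerate
})

test_that("every node of a closure shares the seed formula", {
  net <- run_enumeration(linear_monoterpene_cation(),
                         permissive_cfg(max_rounds = 3))
  f <- vapply(net$nodes$key,
              function(k) paste(cation_formula(parse_smiles(k)), collapse = "-"),
              character(1))
  expect_identical(unname(unique(f)), "10-17-1")
  # per-round counters are consistent with the totals
  expect_equal(sum(net$rounds$new_nodes), nrow(net$nodes))
  expect_equal(sum(net$rounds$new_edges), nrow(net$edges))
  expect_true(all(net$rounds$new_nodes >= 0))
})

test_that("seed validation catches empty and inconsistent input", {
  expect_error(run_enumeration(list(), enum_config()), "empty")
  expect_error(run_enumeration(list(fx$allyl, fx$tert_butyl), enum_config()),
               "inconsistent")
  expect_error(run_enumeration("CCC", enum_config()), "cations")
})

test_that("the alkane validation harness matches the brute-force oracle", {
  tbl <- validate_alkanes(4:6)
  expect_true(all(tbl$match))
  expect_equal(tbl$found, c(4L, 8L, 17L))
  expect_equal(tbl$oracle, c(4L, 8L, 17L))
  expect_error(validate_alkanes(2), "4..10")
})

test_that("the C4 oracle lists exactly the four butyl cations", {
  expect_setequal(alkane_cation_isomers(4),
                  vapply(c("butyl1", "butyl2", "isobutyl", "tert_butyl"),
                         function(n) key_of(fx[[n]]), character(1)))
  # neopentane's quaternary centre carries no H: C5 contributes 8, not 9
  expect_length(alkane_cation_isomers(5), 8)
})

test_that("completed closures are fixpoints: reseeding adds nothing", {
  net <- run_enumeration(linear_alkane_cation(6), permissive_cfg(
    enabled_types = c("ALKYL_SHIFT", "HYDRIDE_SHIFT", "METHYL_SHIFT"),
    max_rounds = Inf))
  again <- run_enumeration(lapply(net$nodes$key, parse_smiles),
                           permissive_cfg(
    enabled_types = c("ALKYL_SHIFT", "HYDRIDE_SHIFT", "METHYL_SHIFT"),
    max_rounds = Inf))
  expect_setequal(again$nodes$key, net$nodes$key)
  expect_true(all(again$nodes$round_found == 0))
})

test_that("node and edge sets are independent of seed atom numbering", {
  set.seed(11)
  g <- linear_monoterpene_cation()
  h <- permute_graph(g, sample(length(g$atoms)))
  n1 <- run_enumeration(g, permissive_cfg(max_rounds = 2))
  n2 <- run_enumeration(h, permissive_cfg(max_rounds = 2))
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges, n2$edges)
})

test_that("the closure property holds: expanding any node stays inside the network", {
  net <- run_enumeration(pg("homoallyl"), permissive_cfg(max_rounds = Inf))
  for (k in net$nodes$key) {
    prods <- product_keys(enumerate_products(parse_smiles(k), permissive_cfg()))
    expect_true(all(prods %in% net$nodes$key), info = k)
  }
})

test_that("the kernel and the R reference engine build the same network", {
  # an all-zero energy table with cutoff 0 is filter-equivalent to
  # permissive mode but runs on the R path
  iso <- alkane_cation_isomers(5)
  plug <- table_energy_plugin(setNames(numeric(length(iso)), iso))
  cfg_types <- c("ALKYL_SHIFT", "HYDRIDE_SHIFT", "METHYL_SHIFT")
  fast <- run_enumeration(linear_alkane_cation(5), permissive_cfg(
    enabled_types = cfg_types, max_rounds = Inf))
  slow <- run_enumeration(linear_alkane_cation(5), enum_config(
    enabled_types = cfg_types, max_rounds = Inf, shift_range_bonds = Inf,
    stability = stability_config("energy_plugin", cutoff_kcal = 0,
                                 reference = linear_alkane_cation(5))),
    plugin = plug)
  expect_setequal(fast$nodes$key, slow$nodes$key)
  expect_identical(
    fast$nodes$round_found[order(fast$nodes$key)],
    slow$nodes$round_found[order(slow$nodes$key)])
})

test_that("heuristic filtering yields a subnetwork of the permissive run", {
  cfg <- function(st) enum_config(max_rounds = 3, shift_range_bonds = Inf,
                                  stability = st)
  perm <- run_enumeration(linear_monoterpene_cation(),
                          cfg(stability_config("permissive")))
  heur <- run_enumeration(linear_monoterpene_cation(),
                          cfg(stability_config("heuristic")))
  expect_true(all(heur$nodes$key %in% perm$nodes$key))
  expect_lt(nrow(heur$nodes), nrow(perm$nodes))
  rejected <- setdiff(perm$nodes$key, heur$nodes$key)
  # a rejected species is non-allylic primary, or orphaned by one
  cls <- vapply(rejected, function(k) classify_cation(parse_smiles(k)), character(1))
  expect_gt(mean(cls == "primary"), 0)
  expect_false(any(heur$nodes$cation_class == "primary"))
})

test_that("dedup_insert deduplicates nodes and events and drops self edges", {
  net <- run_enumeration(pg("butyl2"), permissive_cfg(
    enabled_types = "HYDRIDE_SHIFT", max_rounds = 1))
  n0 <- nrow(net$nodes)
  b2a <- pg("butyl2")
  ra <- reactive_atoms(b2a)
  res <- apply_hydride_shift(b2a, ra[b2a$atoms[ra] == "H"][1])
  # inserting an already-present product twice: one node, one edge
  r1 <- dedup_insert(net, res$graph, res$event)
  r2 <- dedup_insert(r1$network, res$graph, res$event)
  expect_false(r2$inserted)
  expect_equal(nrow(r2$network$nodes), max(n0, nrow(r1$network$nodes)))
  expect_equal(nrow(r2$network$edges), nrow(r1$network$edges))
  # degenerate self edge is dropped
  b2 <- pg("butyl2")
  bo <- matrix(0L, length(b2$atoms), length(b2$atoms))
  bo[b2$bonds[, 1:2]] <- 1L; bo[b2$bonds[, 2:1]] <- 1L
  h2 <- which(b2$atoms == "H" & bo[2, ] > 0)[1]  # degenerate 2-butyl move
  deg <- apply_hydride_shift(b2, h2)
  expect_identical(deg$event$product_key, deg$event$reactant_key)
  r3 <- dedup_insert(net, deg$graph, deg$event)
  expect_equal(nrow(r3$network$edges), nrow(net$edges))
  # distinct events between the same pair coexist
  expect_true(any(duplicated(net$edges[, c("from", "to", "rtype")])))
})
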