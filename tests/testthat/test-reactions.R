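test_that("the reactive-atom list excludes the cation and its three bonded atoms", {
  tb <- pg("tert_butyl")
  ra <- reactive_atoms(tb)
  expect_length(ra, 9)
  expect_true(all(tb$atoms[ra] == "H"))  # the nine methyl hydrogens

  et <- pg("ethyl")
  expect_length(reactive_atoms(et), 3)   # the three beta hydrogens

  al <- pg("allyl")
  expect_length(reactive_atoms(al), 4)   # far CH2's C + its 2 H + the CH's H
})

test_that("alkylation closes 1,6 and 1,7 rings from the linear monoterpene cation", {
  lin <- linear_monoterpene_cation()
  prods <- enumerate_products(lin, permissive_cfg(enabled_types = "ALKYLATION"))
  keys <- product_keys(prods)
  expect_length(keys, 2)
  expect_true(key_of(fx$aterpinyl) %in% keys)  # 1,6: alpha-terpinyl-type
  rings <- vapply(keys, ring_count, integer(1))
  expect_setequal(unname(rings), c(1L, 1L))
  sk <- vapply(keys, function(k) extract_skeleton(parse_smiles(k))$n_carbons,
               integer(1))
  expect_setequal(unname(sk), c(6L, 7L))       # cyclohexene + cycloheptene
})

test_that("alkylation on the homoallyl cation gives cyclopropylcarbinyl and cyclobutyl", {
  ha <- pg("homoallyl")  # atoms in SMILES order: C1=C2-C3-C4(+)
  near <- apply_alkylation(ha, 2)
  expect_identical(near[[1]]$event$product_key, key_of(fx$cpcarbinyl))
  far <- apply_alkylation(ha, 1)
  expect_identical(far[[1]]$event$product_key, key_of(fx$cyclobutyl))
})

test_that("alkylation refuses the alkene conjugated to the cation", {
  al <- pg("allyl")
  ra <- reactive_atoms(al)
  carbons <- ra[al$atoms[ra] == "C"]
  expect_length(carbons, 1)
  expect_error(apply_alkylation(al, carbons), "resonance")
  expect_length(Filter(function(p) p$event$rtype == "ALKYLATION",
                       enumerate_products(al, permissive_cfg())), 0)
})

test_that("hydride shifts move charge along the chain, including degenerate moves", {
  b2 <- pg("butyl2")  # CH3-CH2-CH+-CH3, atoms 1..4 then H
  bo <- matrix(0L, length(b2$atoms), length(b2$atoms))
  bo[b2$bonds[, 1:2]] <- 1L; bo[b2$bonds[, 2:1]] <- 1L
  h_on <- function(g, c) which(g$atoms == "H" & bo[c, seq_along(g$atoms)] > 0)

  # C2 hydride (adjacent CH2) -> 2-butyl again: degenerate
  r <- apply_hydride_shift(b2, h_on(b2, 2)[1])
  expect_identical(r$event$product_key, canonical_key(b2))
  # terminal C1 hydride -> 1-butyl
  r <- apply_hydride_shift(b2, h_on(b2, 1)[1])
  expect_identical(r$event$product_key, key_of(fx$butyl1))

  # isobutyl methine H -> tert-butyl
  ib <- pg("isobutyl")
  methine <- which(ib$atoms == "H" &
    vapply(seq_along(ib$atoms), function(a) {
      if (ib$atoms[a] != "H") return(FALSE)
      co <- setdiff(as.vector(ib$bonds[ib$bonds[, 1] == a | ib$bonds[, 2] == a, 1:2]), a)
      sum(ib$atoms[setdiff(as.vector(ib$bonds[ib$bonds[, 1] == co | ib$bonds[, 2] == co, 1:2]), co)] == "H") == 1
    }, logical(1)))
  r <- apply_hydride_shift(ib, methine[1])
  expect_identical(r$event$product_key, key_of(fx$tert_butyl))
})

test_that("the shift range gates long hydride moves in topological mode", {
  hexyl <- parse_smiles("CCCCC[CH2+]")
  cfg_short <- enum_config(enabled_types = "HYDRIDE_SHIFT", shift_range_bonds = 2,
                           stability = stability_config("permissive"))
  cfg_long <- permissive_cfg(enabled_types = "HYDRIDE_SHIFT")
  k_short <- product_keys(enumerate_products(hexyl, cfg_short))
  k_long <- product_keys(enumerate_products(hexyl, cfg_long))
  expect_true(all(k_short %in% k_long))
  expect_gt(length(k_long), length(k_short))
})

test_that("alkyl shifts expand and contract rings and exclude methyls", {
  cpc <- pg("cpcarbinyl")  # [CH2+]-C1CC1, atoms: 1 CH2+, 2 CH ring, 3/4 CH2 ring
  r <- apply_alkyl_shift(cpc, 3)
  expect_identical(r$event$product_key, key_of(fx$cyclobutyl))  # ring expansion
  cb <- pg("cyclobutyl")   # [CH+]1CCC1, ring atoms 1..4, charge at 1
  r <- apply_alkyl_shift(cb, 3, origin = 2)
  expect_identical(r$event$product_key, key_of(fx$cpcarbinyl))  # contraction back

  np <- pg("neopentyl")
  shifts <- Filter(function(p) p$event$rtype == "ALKYL_SHIFT",
                   enumerate_products(np, permissive_cfg()))
  expect_length(shifts, 0)  # every candidate migrating group is a methyl
})

test_that("methyl shifts are the methyl-only 1,2 migrations", {
  np <- pg("neopentyl")
  ms <- Filter(function(p) p$event$rtype == "METHYL_SHIFT",
               enumerate_products(np, permissive_cfg()))
  expect_identical(product_keys(ms), key_of(fx$tert_amyl))

  tb <- pg("tert_butyl")
  expect_length(Filter(function(p) p$event$rtype == "METHYL_SHIFT",
                       enumerate_products(tb, permissive_cfg())), 0)

  d <- pg("dmb33")  # pinacol-type: 3,3-dimethyl-2-butyl -> 2,3-dimethyl-2-butyl
  ms <- Filter(function(p) p$event$rtype == "METHYL_SHIFT",
               enumerate_products(d, permissive_cfg()))
  expect_true(key_of(fx$dmb23) %in% product_keys(ms))
})

test_that("proton transfer performs the concerted deprotonation/protonation edit", {
  p <- pg("pent4en1yl")  # [CH2+]CCC=C, atoms 1..5 in SMILES order
  # donor H on C2 (adjacent to the charge), acceptor the terminal alkene C5
  donor <- which(p$atoms == "H" &
    vapply(seq_along(p$atoms), function(a) {
      if (p$atoms[a] != "H") return(FALSE)
      co <- setdiff(as.vector(p$bonds[p$bonds[, 1] == a | p$bonds[, 2] == a, 1:2]), a)
      co == 2
    }, logical(1)))
  r <- apply_proton_transfer(p, donor[1], 5)
  expect_identical(r$event$product_key, key_of(fx$pentenyl2))
  expect_equal(cation_formula(r$graph), cation_formula(p))

  # conservation on ring systems: every proton-transfer product of the
  # alpha-terpinyl cation keeps rings + double bonds = 2
  at <- pg("aterpinyl")
  pts <- Filter(function(q) q$event$rtype == "PROTON_TRANSFER",
                enumerate_products(at, permissive_cfg()))
  expect_gt(length(pts), 0)
  for (q in pts) expect_equal(dbe(q$graph), 2L)

  # no alkene, no transfer
  expect_length(Filter(function(q) q$event$rtype == "PROTON_TRANSFER",
                       enumerate_products(pg("butyl2"), permissive_cfg())), 0)
})

test_that("every operator conserves formula and degree of unsaturation", {
  for (name in c("homoallyl", "neopentyl", "aterpinyl", "geranyl", "cyclobutyl",
                 "pent4en1yl")) {
    g <- pg(name)
    for (p in enumerate_products(g, permissive_cfg())) {
      expect_equal(cation_formula(p$graph), cation_formula(g))
      expect_equal(dbe(p$graph), dbe(g))
      if (p$event$rtype == "ALKYLATION")
        expect_equal(ring_count(p$event$product_key),
                     ring_count(p$event$reactant_key) + 1L)
    }
  }
})

test_that("tert-butyl products are exactly the hydride-shift isobutyl family", {
  prods <- enumerate_products(pg("tert_butyl"), permissive_cfg())
  expect_true(all(vapply(prods, function(p) p$event$rtype, character(1)) ==
                    "HYDRIDE_SHIFT"))
  expect_identical(product_keys(prods), key_of(fx$isobutyl))
})

test_that("shift and transfer operators are reversible within the operator set", {
  # exhaustive on C5 cations: for each product, some operator application on
  # the product (or a resonance partner) regenerates the reactant. Ring
  # formation is excluded: every operator either closes a ring or conserves
  # the cyclomatic number (a 1,2-shift breaks one C-C bond and makes one),
  # so no operator in the algebra can undo an alkylation.
  seeds <- c("CCCC[CH2+]", "CC(C)(C)[CH2+]", "[CH2+]CCC=C")
  for (s in seeds) {
    g <- parse_smiles(s)
    gkey <- canonical_key(g)
    for (p in enumerate_products(g, permissive_cfg())) {
      if (p$event$rtype %in% c("RESONANCE", "ALKYLATION")) next
      back <- character(0)
      for (f in resonance_forms(p$graph))
        back <- c(back, product_keys(enumerate_products(f, permissive_cfg())))
      expect_true(gkey %in% back,
                  info = paste(s, "->", p$event$product_key, "not reversible"))
    }
  }
})

test_that("enumerate_products is invariant under atom relabeling", {
  set.seed(7)
  for (name in c("geranyl", "aterpinyl", "homoallyl")) {
    g <- pg(name)
    h <- permute_graph(g, sample(length(g$atoms)))
    expect_identical(product_keys(enumerate_products(g, permissive_cfg())),
                     product_keys(enumerate_products(h, permissive_cfg())))
  }
})

test_that("the C++ kernel and the R operators generate identical product sets", {
  cfg <- permissive_cfg(max_rounds = 1)
  for (name in c("tert_butyl", "neopentyl", "homoallyl", "cpcarbinyl",
                 "aterpinyl", "geranyl", "cyclobutyl")) {
    g <- pg(name)
    # R route: expand every resonance form of the seed and close products
    # over resonance, mirroring the kernel's same-round resonance insertion
    keys <- character(0)
    for (f in resonance_forms(g)) {
      keys <- c(keys, names(resonance_forms(f)))
      for (p in enumerate_products(f, cfg))
        keys <- c(keys, names(resonance_forms(p$graph)))
    }
    net <- run_enumeration(g, cfg)
    expect_identical(sort(net$nodes$key), sort(unique(keys)), info = name)
  }
})
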