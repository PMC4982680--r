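test_that("SMILES parsing materializes explicit hydrogens and the charge site", {
  g <- parse_smiles("CC(C)=CCC/C(C)=C/[CH2+]")
  expect_equal(cation_formula(g), c(nC = 10L, nH = 17L, charge = 1L))
  expect_false(is.na(g$charge_site))

  p <- parse_smiles("[CH2+]CC")
  v <- sum(p$bonds[p$bonds[, 1] == p$charge_site | p$bonds[, 2] == p$charge_site, 3])
  expect_equal(v, 3)  # trivalent cationic carbon

  # identity round trip through the canonical renderer
  tb <- pg("tert_butyl")
  expect_identical(canonical_key(parse_smiles(render_smiles(tb))),
                   canonical_key(tb))
})

test_that("malformed or unsupported SMILES are rejected", {
  expect_error(parse_smiles("CC(C"), "unbalanced")
  expect_error(parse_smiles("CN"), "unsupported")
  expect_error(parse_smiles("C[O+]C"), "unsupported bracket")
  expect_error(parse_smiles("[CH2+]C[CH2+]"), "one charged atom")
  expect_error(parse_smiles("[CH2-]C"), "anion")
  expect_error(parse_smiles("C#C"), "triple")
  expect_error(parse_smiles("C.C"), "disconnected")
})

test_that("canonical keys are permutation invariant and separate isomers", {
  expect_identical(canonical_key(parse_smiles("[CH2+]C=C")),
                   canonical_key(parse_smiles("C=C[CH2+]")))
  expect_false(key_of(fx$butyl1) == key_of(fx$tert_butyl))

  set.seed(42)
  for (name in c("aterpinyl", "geranyl", "cpcarbinyl")) {
    g <- pg(name)
    keys <- replicate(100, canonical_key(permute_graph(g, sample(length(g$atoms)))))
    expect_length(unique(keys), 1)
    expect_identical(keys[1], canonical_key(g))
  }
})

test_that("canonical-key equivalence classes agree with an independent canonicalizer", {
  # pairs that must merge and pairs that must stay distinct, checked against
  # OpenBabel's canonical SMILES as the external oracle
  entries <- c("[CH2+]C=C", "C=C[CH2+]", "CC(C)=CCCC(C)=C[CH2+]",
               "[CH2+]/C=C(\\C)CCC=C(C)C", "C[C+](C)C", "CCC[CH2+]",
               "CC[CH+]C", "[CH+]1CCC1", "[CH2+]C1CC1", "CC=1CCC(CC=1)[C+](C)C")
  ours <- vapply(entries, key_of, character(1), USE.NAMES = FALSE)
  theirs <- obabel_canonical(entries)
  same_ours <- outer(ours, ours, "==")
  same_theirs <- outer(theirs, theirs, "==")
  expect_identical(same_ours, same_theirs)
})

test_that("formula bookkeeping covers charged and neutralized species", {
  expect_equal(cation_formula(pg("tert_butyl")), c(nC = 4L, nH = 9L, charge = 1L))
  expect_equal(cation_formula(neutralize(pg("geranyl"))),
               c(nC = 10L, nH = 18L, charge = 0L))
})

test_that("cation classification matches a direct neighbour-count oracle", {
  expect_identical(classify_cation(pg("tert_butyl")), "tertiary")
  expect_identical(classify_cation(parse_smiles("[CH2+]CC")), "primary")
  expect_identical(classify_cation(pg("geranyl")), "allylic_primary")

  oracle <- function(g) {
    bo <- matrix(0L, length(g$atoms), length(g$atoms))
    bo[g$bonds[, 1:2]] <- g$bonds[, 3]; bo[g$bonds[, 2:1]] <- g$bonds[, 3]
    cs <- g$charge_site
    nb <- which(bo[cs, ] > 0 & g$atoms == "C")
    base <- c("primary", "primary", "secondary", "tertiary")[length(nb) + 1]
    allylic <- any(vapply(nb, function(a) any(bo[a, ] == 2), logical(1)))
    if (allylic) paste0("allylic_", base) else base
  }
  for (name in c("allyl", "homoallyl", "ethyl", "propyl", "butyl1", "butyl2",
                 "isobutyl", "tert_butyl", "neopentyl", "tert_amyl",
                 "cpcarbinyl", "cyclobutyl", "pent4en1yl")) {
    g <- pg(name)
    expect_identical(classify_cation(g), oracle(g))
  }
})

test_that("resonance forms shift allylic charge and conserve unsaturation", {
  expect_length(resonance_forms(pg("allyl")), 1)       # symmetric shift
  expect_length(resonance_forms(pg("tert_butyl")), 1)  # no adjacent alkene

  forms <- resonance_forms(pg("geranyl"))
  expect_length(forms, 2)
  expect_true(key_of(fx$linalyl) %in% names(forms))
  cls <- vapply(forms, classify_cation, character(1))
  expect_setequal(unname(cls), c("allylic_primary", "allylic_tertiary"))
  for (f in forms) {
    expect_equal(cation_formula(f), cation_formula(pg("geranyl")))
    expect_equal(dbe(f), dbe(pg("geranyl")))
  }
})

test_that("stereo-aware keys separate tagged configurations only on request", {
  g <- pg("butyl2")
  tags <- rep(NA_character_, length(g$atoms))
  tags[g$charge_site] <- "R"
  g$stereo_tags <- tags
  h <- g
  h$stereo_tags[g$charge_site] <- "S"
  expect_identical(canonical_key(g), canonical_key(h))
  expect_false(canonical_key(g, use_stereo = TRUE) ==
                 canonical_key(h, use_stereo = TRUE))
})
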