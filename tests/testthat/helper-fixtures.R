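# Shared fixtures and small utilities. All fixtures are built in code from
# SMILES; nothing is read from disk.

fx <- list(
  allyl       = "[CH2+]C=C",
  homoallyl   = "C=CC[CH2+]",
  ethyl       = "[CH2+]C",
  propyl      = "[CH2+]CC",
  butyl1      = "CCC[CH2+]",
  butyl2      = "CC[CH+]C",
  isobutyl    = "CC(C)[CH2+]",
  tert_butyl  = "C[C+](C)C",
  neopentyl   = "CC(C)(C)[CH2+]",
  tert_amyl   = "CC[C+](C)C",
  dmb33       = "CC(C)(C)[CH+]C",  # 3,3-dimethyl-2-butyl
  dmb23       = "CC(C)[C+](C)C",   # 2,3-dimethyl-2-butyl
  cpcarbinyl  = "[CH2+]C1CC1",
  cyclobutyl  = "[CH+]1CCC1",
  pent4en1yl  = "[CH2+]CCC=C",
  pentenyl2   = "C=CC[CH+]C",      # pent-1-en-4-yl
  geranyl     = "CC(C)=CCCC(C)=C[CH2+]",
  linalyl     = "CC(C)=CCC[C+](C)C=C",
  aterpinyl   = "CC=1CCC(CC=1)[C+](C)C"
)

pg <- function(name) parse_smiles(fx[[name]])
key_of <- function(smiles) canonical_key(parse_smiles(smiles))

# relabel the atoms of a graph by a permutation (new position k holds old
# atom perm[k]); canonical keys must be invariant under this
permute_graph <- function(g, perm) {
  pos <- order(perm)  # pos[old] = new index
  bonds <- g$bonds
  bonds[, 1] <- pos[g$bonds[, 1]]
  bonds[, 2] <- pos[g$bonds[, 2]]
  cs <- if (is.na(g$charge_site)) NA_integer_ else pos[g$charge_site]
  cation_graph(g$atoms[perm], bonds, charge_site = cs)
}

# degree of unsaturation (rings + double bonds) of the carbon framework
dbe <- function(g) {
  cidx <- which(g$atoms == "C")
  cc <- g$atoms[g$bonds[, 1]] == "C" & g$atoms[g$bonds[, 2]] == "C"
  m <- sum(cc)
  d <- sum(cc & g$bonds[, 3] == 2)
  m - length(cidx) + 1L + d
}

ring_count <- function(key) {
  g <- parse_smiles(key)
  cc <- g$atoms[g$bonds[, 1]] == "C" & g$atoms[g$bonds[, 2]] == "C"
  sum(cc) - sum(g$atoms == "C") + 1L
}

product_keys <- function(results) {
  sort(unique(vapply(results, function(p) p$event$product_key, character(1))))
}

# independent canonicalization oracle (OpenBabel command-line tool);
# directional bond marks are stripped first because the package's
# constitutional keys deliberately erase configuration
obabel_canonical <- function(smiles) {
  smiles <- gsub("[/\\\\]", "", smiles)
  vapply(smiles, function(s) {
    out <- suppressWarnings(system2("obabel",
                                    c(shQuote(paste0("-:", s)), "-osmi", "--canonical"),
                                    stdout = TRUE, stderr = FALSE))
    trimws(out[length(out)])
  }, character(1), USE.NAMES = FALSE)
}

permissive_cfg <- function(...) {
  enum_config(stability = stability_config("permissive"),
              shift_range_bonds = Inf, ...)
}
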