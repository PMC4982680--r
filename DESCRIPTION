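Package: cationet
Title: Enumeration and Analysis of Terpenoid Carbocation Rearrangement Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Systematic enumeration of the carbocation rearrangement networks
    that underlie terpenoid synthase chemistry. Starting from a seed
    carbocation (by default the linear allylic monoterpene cation, C10H17+),
    five reaction operators (intramolecular alkylation of double bonds, 1,2-
    alkyl shifts, hydride shifts, 1,2-methyl shifts, and intramolecular proton
    transfers) are applied in breadth-first rounds with canonical-SMILES
    deduplication to build a reaction network of constitutional isomers.
    The package classifies cations (primary/secondary/tertiary, allylic),
    filters candidates by a stability heuristic or a pluggable energy engine,
    extracts neutralized ring-and-double-bond skeletons, classifies their ring
    topology (monocyclic, bridged, fused, spiro, separated), computes
    shortest reaction routes, and validates the engine against a brute-force
    alkane-cation isomer oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
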