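---
title: "Enumerating monoterpenoid carbocation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating monoterpenoid carbocation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Monoterpenoid synthases convert one substrate — the linear C10 diphosphate
— into hundreds of distinct products by routing a carbocation through
rearrangement cascades. `cationet` models that chemistry as a reaction
network over *constitutional isomers of the classical C10H17+ cation*:

- a species is a connected C/H molecular graph with single and double
  bonds and one trivalent cationic carbon that participates in no double
  bond (vinyl cations and non-classical, bridged two-electron–three-centre
  cations are excluded by construction);
- a reaction is one of five local graph edits (alkylation of a double
  bond, 1,2-alkyl shift, hydride shift, 1,2-methyl shift, proton
  transfer), applied to every *reactive atom* — every atom except the
  cationic carbon and its three bonded atoms;
- allylic resonance partners are distinct nodes joined by zero-cost
  `RESONANCE` edges, so a delocalized allyl system is represented by its
  localized extremes without inflating route lengths.

Two conservation laws pin the space down: the formula (C10H17+) and the
degree of unsaturation, rings + C=C = 2. Alkylation converts one double
bond into one ring; every other operator breaks exactly one bond and makes
exactly one, so the ring count is invariant under it. A corollary worth
stating explicitly: ring formation is *irreversible* inside this operator
algebra — no sequence of shifts can reopen a ring to an acyclic chain —
so the network's ring count is monotone along any route. The test suite
asserts this accounting over every edge of a full run.

## Hydrogens, keys, and deduplication

Hydrogens are explicit atoms in the user-facing `cation_graph`: the
reactive-atom rule and the hydride/proton operators address individual H
atoms, and keeping them concrete keeps the operators honest and testable.
The C++ engine works on the equivalent implicit-H carbon skeleton, where
hydrogen counts follow from valence.

Deduplication uses canonical SMILES computed in-package: colour refinement
over the carbon skeleton (charge as the initial colour, bond orders in the
refinement signatures) with individualization on ties, minimizing a
serialized adjacency code; the SMILES writer then emits a deterministic
string from the canonical labeling. For the ≤ 10-carbon graphs of this
domain the search tree is tiny and a key costs microseconds, which is what
makes exhaustive closure over ~10^5 candidate products per run practical.
The test suite cross-checks the equivalence classes against OpenBabel's
canonical SMILES on a fixture panel and asserts invariance under hundreds
of random atom relabelings.

Stereochemistry is deliberately erased in the default *constitutional*
mode: cis/trans forms of the linear cation collapse to one node, as do
configurational isomers of every ring system. Skeleton identities and
route lengths are unaffected by this collapse; member counts per skeleton
are of course smaller than in a stereo-resolved enumeration.

## Stability filtering

The engine's filter seam accepts three modes:

- `permissive` — no filtering; the full constitutional space.
- `heuristic` (default) — reject by cation class: plain primary cations
  are discarded; allylic cations of any substitution are exempt (the
  linear substrate cation itself is allylic primary and must survive);
  tertiary cations can never be rejected. Secondary cations are kept by
  default because they are ubiquitous in real cascades (the bornyl cation
  is the textbook example).
- `energy_plugin` — accept iff `E(g) − E(reference) ≤ cutoff` with an
  inclusive boundary (the reference species passes at cutoff 0). The
  evaluator is a contract: any deterministic engine can be attached,
  including an external executable speaking one JSON structure in, one
  `energy_kcal` out. A bundled table-lookup stub supports testing (it
  declares `requires_coords = FALSE`; engines that minimize real
  geometries keep the coordinate requirement). The accepted set is
  provably nested as the cutoff tightens, and the suite asserts that.

The heuristic is a *class* filter, not an *energy* filter: it keeps
strained frameworks (fused cyclobutanes, cyclopropenes) that a
quantum-chemical cutoff against the linear reference would remove. This is
the main caveat when comparing skeleton counts with energy-filtered
studies, and it is why the package reports the exhaustive constitutional
count as an upper bound of the energetically plausible space.

## Seeds and the step ladder

Route steps follow the biogenetic numbering: step 1 creates the trans
linear cation, step 2 is the trans/cis isomerization, so the first
cyclizations land at step 3. In constitutional mode steps 1–2 collapse
into the seed; `run_enumeration` applies a configurable `step_offset`
(2 for linear-seed runs) so reported steps match the ladder.

Two canonical run setups cover the analyses:

```r
# exhaustive constitutional space: cis-linear seed, no filter
net <- run_enumeration(linear_monoterpene_cation(),
                       enum_config(max_rounds = 10, shift_range_bonds = Inf,
                                   stability = stability_config("permissive")))

# the step ladder: seed the 1,6-/1,7-cyclized intermediates (step 3),
# one further round = step 4
ladder <- run_enumeration(cyclization_seeds(),
                          enum_config(max_rounds = 1, shift_range_bonds = Inf,
                                      step_offset = 3L))
```

The ladder run seeds from the cyclized intermediates rather than the
linear cation for a substantive reason: the linear seed's tertiary
(linalyl-type) resonance partner can close 4- and 5-membered rings
directly, flooding the early steps with small-ring frames that an
energy-aware treatment would suppress; seeding at the first cyclization
reproduces the enzymatically anchored ladder. The 1,6 closure is the
alpha-terpinyl-type cyclohexene cation and the 1,7 closure the
cycloheptenyl cation; in constitutional mode the stereo-differing pair of
1,6 closures is one node.

## Skeletons and topology

A skeleton is the neutralized carbon framework with saturated alkyl side
chains pruned to fixpoint. Two conventions needed fixing:

- *Neutralization is a hydride quench* (one H added at the cation centre).
  The alternative — deprotonation — would create a new alkene and change
  the skeleton identity of every group-1 framework; hydride quench is the
  unique choice that leaves the alkene pattern untouched.
- *Pruning* deletes degree-1 carbons not in a double bond, so exocyclic
  methylene and vinyl carbons survive (they are part of the unsaturation
  pattern, not side chains). A fully saturated acyclic cation prunes to
  the empty framework; this cannot occur for C10H17+ inputs.

Cyclic skeletons fall into five groups, decided from the two SSSR rings:
`MONOCYCLIC` (necessarily one ring plus one double bond here), `BRIDGED`
(≥ 3 shared atoms, or 2 non-adjacent), `FUSED` (one shared bond), `SPIRO`
(one shared atom), `SEPARATED` (rings joined only by an acyclic linker —
fully disjoint rings cannot occur in a connected molecule). SSSR is
computed in-package (shortest cycle through each edge, greedy independent
selection), which is exact at cyclomatic number ≤ 2; the suite checks it
against an igraph biconnectivity oracle on every two-ring frame up to 10
carbons. Frameworks with more than two rings are impossible at this
degree of unsaturation and raise an error.

The five EC-referenced frameworks (menthane-type cyclohexene, pinane,
bornane, thujane, carane) ship as an editable configuration file
(`inst/extdata/ec_reference_skeletons.smi`), canonicalized on load, so a
curated list can replace the default without code changes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_rounds` | 10 | breadth-first rounds; the monoterpene skeleton space saturates well before this, and >5-step products are already unusual enzymology |
| `shift_range_bonds` | 4 | through-bond gate for hydride shifts / proton transfers in topological mode; `Inf` mirrors unrestricted early rounds |
| `reject_classes` | `primary` | heuristic filter classes (allylic always exempt) |
| `cutoff_kcal` | 0 | energy-plugin threshold vs the linear reference, inclusive |
| `distance_cutoff_A` | 5.0 | geometric donor–acceptor gate, inclusive, active after round `gate_after_round` (5) |
| `dihedral_window_deg` | 45 | half-width of the stereochemistry-module trigger window, inclusive |
| `conformer_rounds` | 5 | rounds with conformational sampling in geometric mode |

Boundary conventions are inclusive everywhere (≤), chosen once so that
reference species and exact-boundary geometries pass.

## Geometric mode

Geometric mode is off by default and no headline analysis depends on it.
It preserves the architecture of a coordinate-driven pipeline as
contracts: a minimizer plugin (bond-length sanity 0.9–1.8 Å enforced), a
seeded conformer-generator plugin, a 3D distance gate replacing the
topological shift range, and a stereochemistry module that duplicates
placements when the diagnostic dihedral of the reacting frame lies within
the window. The bundled stubs — a template embedder with a harmonic
relaxer, and a torsion-scan generator — are deliberately simple
self-contained implementations of those contracts, adequate for the C5–C6
fixtures the mode is tested on and replaceable by real engines. Because
the gates only remove candidates, a geometric run is always a
constitutional subset of the topological run; the suite asserts this and
also that disabling the mode reproduces byte-identical topological output.

## What the tests do and do not show

The enumeration is exact at its own level of theory: constitutional
isomers of classical cations under five local operators. Green tests
therefore certify closure (expanding any node stays inside the network),
conservation, canonical-key correctness, agreement with the brute-force
alkane-cation oracle (the engine regenerates all 4, 8, 17, 39, 89
CnH2n+1+ isomers for n = 4..8 from the linear cation), and the
skeleton/route bookkeeping. They do not certify energetics: without a
quantum-chemical filter the cyclic-skeleton count of the exhaustive run
(102 at 10 rounds) is an upper bound, and the step-4 ladder retains one
strained fused-cyclobutane framework (bicyclo[3.2.0]heptane) that an
energy cutoff would plausibly remove — the package reports it rather than
hard-coding its exclusion, and the corresponding acceptance check is
expected to flag the surplus. Real enzymatic product spaces are further
narrowed by active-site sterics, which are outside any filter shipped
here.

## Numerical and procedural choices

- Determinism: topological runs contain no randomness; shortest-route
  tie-breaks use lexicographic node-key order; conformer generation is
  seeded.
- Degenerate products (product key = reactant key) are emitted by the
  operators and dropped at deduplication, keeping operators pure.
- Edges are stored directed, one per generating event (type + atom pair in
  the reactant's canonical frame); identical events are deduplicated,
  distinct events between the same pair coexist.
- Problem sizes in the shipped tests: 10-round monoterpene runs
  (~2–25 s each), alkane validation C4–C8, 100-permutation key checks,
  and small-fixture geometric runs — the full suite completes in a few
  minutes on one core.
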