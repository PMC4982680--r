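# cationet

Systematic enumeration of carbocation rearrangement networks for terpenoid
chemistry, in R with a C++ core.

## The problem

Terpenoid synthases build most of the structural diversity of terpenes by
steering a single substrate through cascades of carbocation rearrangements:
the linear C10 substrate (geranyl diphosphate) ionizes to the allylic
C10H17+ cation, cyclizes, and hops through hydride shifts, methyl and alkyl
shifts, further ring closures, and proton transfers before being quenched
to a product. Because single mutations can redirect the cascade, the space
of *possible* products — not just the characterized ones — is the right
object for function prediction and enzyme engineering. `cationet`
enumerates that space exhaustively at the level of constitutional isomers
and organizes it into carbon skeletons and shortest reaction routes.

## The algorithm

Starting from one or more seed cations, the engine runs breadth-first
rounds. For every species, each atom outside the *excluded set* (the
cationic carbon C+ and its three bonded atoms) is tested against five
reaction operators:

1. **intramolecular alkylation** — an alkene carbon attacks C+, closing a
   ring (ring size ≥ 3; an alkene conjugated to C+ is the resonance system
   and is exempt);
2. **1,2-alkyl shift** — a non-methyl carbon on a neighbour of C+ migrates
   to it (ring expansions/contractions);
3. **hydride shift** — an H migrates to C+ (through-bond range-gated by
   default, 3D distance-gated in geometric mode);
4. **1,2-methyl shift**;
5. **proton transfer** — concerted deprotonation β to C+ with protonation
   of a remote alkene.

Products are rejected if they violate classical-cation valence rules (the
charge never sits on an sp2 carbon; non-classical bridged cations are out
of scope), filtered for stability (class-based heuristic by default, or a
pluggable energy engine with a kcal/mol cutoff against the linear
reference cation), and deduplicated by canonical SMILES. Allylic resonance
partners are linked by zero-cost edges. The result is a directed reaction
network over which the package computes:

- **skeletons** — each cation is neutralized by hydride quench and its
  saturated side chains pruned; what remains (ring system + double-bond
  placement) is the skeleton, classified as monocyclic, bridged, fused,
  spiro, or separated from its SSSR rings;
- **shortest routes** — with the biogenetic step numbering: step 1 creates
  the trans linear cation, step 2 is trans/cis isomerization, so the first
  cyclic skeletons appear at step 3.

Formula (C10H17+) and degree of unsaturation (rings + C=C = 2) are
conserved network-wide; an independent brute-force oracle over all
constitutional alkane-cation isomers validates the engine (types 2–4
reproduce every CnH2n+1+ isomer from the linear cation for n = 4..10).

## Worked example

```r
library(cationet)
net <- run_enumeration(linear_monoterpene_cation(),
                       enum_config(max_rounds = 2, shift_range_bonds = Inf))
net
#> <reaction_network> 145 nodes, 338 edges, 1 seed(s), 2 round(s)

cluster_network(net)
#>     skeleton_key   topology n_carbocation log10_n min_step is_ec_reference
#> 1     C1CCC=CCC1 MONOCYCLIC            12   1.079        3           FALSE
#> 2      C1CCC=CC1 MONOCYCLIC            11   1.041        3            TRUE
#> ...
#> 14 C1CC2CC(C1)C2    BRIDGED             1   0.000        4            TRUE
#> 15   C1CC2CCC1C2    BRIDGED             1   0.000        4            TRUE
```

Two rounds from the linear cation already populate 17 cyclic skeletons.
The cyclohexene frame (`C1CCC=CC1`, the menthane family of limonene and
terpinolene) appears at step 3 with 11 member cations; the pinane and
bornane frames (`C1CC2CC(C1)C2`, `C1CC2CCC1C2`) appear one step later —
all three flagged as EC-referenced, i.e. frameworks of enzymatically
characterized products. The route query prints the chemistry behind a hop:

```r
shortest_route(net, "CC=1CCC(CC=1)[C+](C)C")  # the alpha-terpinyl cation
#> <route> 2 species, step count 3
#>   CC(C)=CCCC(C)=C[CH2+] --ALKYLATION--> CC=1CCC(CC=1)[C+](C)C

validate_alkanes(4:6)
#>   n found oracle match
#> 1 4     4      4  TRUE
#> 2 5     8      8  TRUE
#> 3 6    17     17  TRUE
```

A full run (`max_rounds = 10`, permissive filter) takes under a minute on
one core and yields 35297 cations clustered into 102 cyclic skeletons.

A thin command-line wrapper ships in `inst/scripts/cationet`
(`enumerate`, `skeletons`, `validate-alkanes`, `route`, `fixtures`).

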