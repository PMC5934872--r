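---
title: "Minimum local scenarios: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum local scenarios: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsdcj)
```

## The problem

Two genomes on the same set of uniquely labeled, directed syntenic blocks are
each represented as a set of *adjacencies*: unordered pairs of block
extremities that are neighbors on a chromosome (internal adjacencies), plus
single extremities at the two ends of each linear chromosome (external
adjacencies, i.e. telomeres). A double cut-and-join (DCJ) move cuts one or
two adjacencies and rejoins the loose ends, covering inversions,
translocations, fusions, fissions, and circularizations in one operation.

Classical DCJ studies minimize scenario *length*. Here the objective is
different: the adjacencies of genome *A* carry a *coloring* — a partition
into classes meant to capture spatial neighborhoods of the chromatin, for
instance clusters inferred from Hi-C contact maps. A DCJ acting on two
adjacencies of one color is *local* and free; a DCJ acting across colors is
*non-local* and costs 1. A split of an internal adjacency attributes one of
the two new telomeres an arbitrary color `z` and is free exactly when `z`
equals the consumed color. The *minimum local scenario* (MLS) problem asks
for a scenario from *A* to *B*, of any length, with as few non-local moves
as possible. Scenario length is deliberately not part of the objective; MLS
is a lower bound for the number of "implausible" moves any scenario must
contain.

## The junction graph and the closed-form cost

The *adjacency graph* AG(A, B) is the bipartite multigraph on the two
adjacency sets with one edge per shared extremity; every vertex has degree
at most two, so its components are paths and cycles. Contracting every
*A*-adjacency to its color yields the *junction graph* J(A, B, col): one
vertex per color, and one edge per internal adjacency of *B* joining the
colors of its two *A*-side neighbors (a loop when they agree). Local moves
leave J unchanged; a non-local move changes at most two edge endpoints — the
genome-level shadow of a *2-break* on J.

The central quantity is the *maximum edge-disjoint cycle packing* (MECP)
size c(J), where a cycle is a connected 2-regular edge subset: a loop, a
digon (two parallel edges), or a longer vertex-simple cycle. The cost of a
minimum local scenario is exactly

> w = e(J) − c(J),

with e(J) the number of junction edges. The two directions are both
constructive: sorting each packed cycle of length *l* needs *l* − 1
2-breaks, and a 2-break can raise the packing number by at most one, so no
scenario can do better.

Computing c(J) is the hard part — deciding MECP on Eulerian multigraphs is
NP-hard, and this package uses that reduction *backwards* as a test-instance
factory (`instance_from_eulerian_graph()`): any connected Eulerian
multigraph becomes a circular-genome instance whose junction graph is that
graph, with known optimal cost e − c.

### Exact packing

`mecp_exact()` follows the standard simplification: all loops and a maximum
set of digons (`floor(multiplicity/2)` per vertex pair) can be assumed to be
in some maximum packing, so they are stripped first; the remaining simple
graph's simple cycles are enumerated by depth-first search and a maximum set
packing over their edge sets is found by deterministic branch-and-bound
(include-first, ascending cycle index, so ties resolve to the
lexicographically smallest packing). The cycle count can be exponential in
the number of *colors* (not blocks); the enumeration cap (`cycle_cap`,
default 10^6) turns pathological palettes into an explicit error rather than
a silent truncation. No integer-programming backend is required; the
branch-and-bound is exact and is validated against an independent
subset-enumeration oracle (`mecp_bruteforce()`) that checks every edge
subset for being a single cycle and exhaustively searches disjoint families.

### The 3/2-approximation

`greedy_loops_digons_packing()` packs only loops and digons, in time linear
in the edges. The resulting scenario cost w' = e − c1 − c2 satisfies
w'/w ≤ 3/2 via the lower bound

> w ≥ (2/3) e(J) − (1/3) c2(J) − (2/3) c1(J),

which `mls_cost()` reports as `lower_bound`. The bound is tight: a triangle
junction graph has w = 2 but w' = 3.

## Scenario construction

`min_local_scenario()` must output the moves, not just the number. The
construction realizes the packing-guided 2-break schedule directly on the
genome:

* **Uncovered edges** (junction edges outside the packing, with endpoint
  colors x ≠ y) are resolved by one non-local move each: split the internal
  adjacency behind one endpoint (giving the new telomere the opposite
  color), or, when both endpoints sit on telomeres, join them. Either way
  the edge becomes a loop.
* **Packed cycles** of length *l* are sorted with *l* − 1 non-local moves.
  Each step exchanges two extremities between two *A*-adjacencies (a
  pair-pair or pair-telomere DCJ), which swaps the two corresponding
  junction-edge endpoints: one edge becomes a loop and the next edge of the
  cycle inherits the remaining color, exactly a 2-break splitting off a
  loop.
* **Telomere preparation.** A DCJ cannot exchange material between two
  telomeres, so when both chosen extremities are external the construction
  first makes one of them internal with zero-cost moves (a same-color join,
  after a same-color split if no same-colored telomere is free). Such a
  partner always exists: the junction vertex shared by the two cycle edges
  has two incident slots of its color, so its color class cannot be a lone
  telomere.
* **Completion.** Once the junction graph is terminal (all loops), every
  missing internal adjacency of *B* has two same-colored *A*-side
  neighbors and is created by a zero-cost move; surplus internal
  adjacencies whose extremities are telomeric in *B* are split at zero
  cost. The scenario is replay-validated before it is returned: it must
  reach *B* with exactly e − c non-local moves, else the solver aborts.

An earlier design lifted the 2-break scenario onto *capped* (circularized)
genomes and translated it back move by move. That translation is not always
possible: a capped pair-pair move whose real content is two telomeres — one
per consumed pair, the rest artificial — projects onto a recoloring of
telomeres, which is not a DCJ. (Smallest instance: *A* four telomeres with
four colors, *B* two internal adjacencies; every optimal capped 2-break
projects to a recolor.) The direct realization above avoids the round trip
entirely while producing the same 2-break schedule. The capping
construction itself remains available and fully tested
(`cap_instance()`): it builds genome extensions whose junction graph is
*non-loop equal* to any prescribed Eulerian extension J′ of J, which is the
device behind the cost formula's proof for genomes with telomeres.

Capping details that the theory leaves open were fixed as follows: the
Eulerian extension duplicates exactly the uncovered edges of a maximum
packing, so J′ − J can never contain a cycle (a cycle among uncovered edges
would contradict maximality) and the Eulerian subgraph *H* of the general
construction is empty on this path (arbitrary user-supplied extensions may
still have cycles; they are peeled off and realized as added circular
chromosomes). The forest J′ − J is partitioned into paths by repeated
leaf-to-end walks; open path ends, all on the *A*-side and colored, are
merged pairwise within each color in creation order. The constructed
instance is checked for non-loop equality with J′ and the solver aborts on
any violation.

## Hi-C driven colorings

`normalize_intra()` divides each within-chromosome contact by the mean
contact over **all** intra-chromosomal bin pairs at the same distance,
pooled across chromosomes, so the distance-wise mean of the normalized map
is 1 and distant contacts gain relative importance. Distances with zero
pooled mean become recorded missing values (`NA`), never divisions by zero.
`normalize_inter()` divides each between-chromosome contact by
`interaction_i * interaction_j / interaction_all` (total coverage of the
two bins over the whole-genome total), which is invariant under global
rescaling of the raw counts and promotes contacts between low-coverage
loci.

`adjacency_similarity()` maps each adjacency to the bin containing the
midpoint of its breakpoint region — the mapping rule is an interpretation
(nothing canonical fixes what to do with regions spanning bins) and is the
single place to change if a different rule is wanted. Two adjacencies in
the same bin read that bin's diagonal entry; this too is a documented
convention. Same-chromosome pairs read the intra-normalized matrix,
cross-chromosome pairs the inter-normalized one (or both the raw matrix in
`"raw"` mode).

Three coloring generators are provided:

* `kmedoids_coloring()` — k clusters around medoids, maximizing the
  *clustering weight*: per cluster, the maximum over members of the summed
  similarity to the other members (the medoid's sum), added over clusters.
  Random centroid initialization under a seed; assignment to the most
  similar centroid; medoid recomputation; stop when the weight stops
  increasing, with an iteration cap of 100. All ties break to the lowest
  element index, making runs reproducible. Because every centroid keeps
  itself, clusters cannot empty out, so no repair step is needed; the
  medoid-sum (not all-pairs) reading of the cluster weight follows the
  definition of a medoid as the element maximizing the similarity sum to
  the rest of its cluster.
* `linear_coloring()` — respects 1D structure: with C chromosomes and k
  colors it cuts at k − C blocks drawn uniformly without replacement; each
  cut separates the two adjacencies flanking the chosen block, so every
  segment keeps at least one adjacency by construction and no re-draws are
  ever needed. Only all-linear genomes are supported: the first cut of a
  circular chromosome merely linearizes it without increasing the segment
  count, which would break the k = C + #cuts bookkeeping.
* `random_coloring()` — surjective uniform baseline: one adjacency per
  color without replacement, the rest i.i.d. uniform.

`divergence_from_linearity()` quantifies how non-linear a coloring is: per
color, split its adjacencies by chromosome into *l* parts, count one *gap*
for each consecutive same-color pair with foreign adjacencies between them,
and add *l* − 1; sum over colors. It is zero exactly for colorings whose
classes are single contiguous runs — in particular every linear coloring.

## Synthetic data

`random_genome_pair()` builds an identity genome and scrambles a copy with
uniformly random legal DCJs; the number of moves applied upper-bounds the
MLS cost under any coloring, which the tests exploit. Default study sizes
follow the tests: up to 8 blocks, up to 10 moves, up to 4 colors — small
enough that an exhaustive search oracle can confirm optimality, large
enough to exercise telomere handling, fissions and fusions.

`synthetic_hic()` emulates three features of real contact maps: a
power-law-like distance decay within chromosomes, a flat weak background
between chromosomes, and elevated contacts within planted clusters. The
planted boost is mean-corrected per distance stratum so the average contact
at each distance equals the decay curve exactly — the distance-decay
contract holds regardless of where the clusters fall. What the generator
does **not** emulate: coverage biases, domain/compartment hierarchy,
translocation artifacts, and — importantly — comparable scales between
intra- and inter-chromosomal values. A consequence worth knowing: planted
clusters that span chromosomes are generally *not* the weight-optimal
clustering, because inter-chromosomal normalized values live on a smaller
scale than intra-chromosomal ones, so a chromosome-aligned clustering can
outweigh the planted one. The recovery checks therefore plant clusters
within a single chromosome, where the signal is identifiable; recovery runs
k-medoids from 10 seeded restarts and keeps the best weight, standard
practice for a local optimizer. This scale mismatch mirrors the real
observation that normalization choices materially change Hi-C-driven
clusterings.

## Oracles and test scale

Three independent oracles guard the theory-bearing code paths:

* `mecp_bruteforce()` — subset enumeration, no shared code with the exact
  solver;
* `min_two_break_sort_length()` — BFS over multigraph states under all
  2-breaks, validating both the sorting-distance formula e − c and
  `two_break_sort()`'s schedule length on every connected Eulerian
  multigraph with up to 4 vertices and 5 edges (enumerated up to
  relabeling);
* `exhaustive_min_cost_search()` — BFS over colored genome states ordered
  by non-local count. States are merged when they agree on the junction
  graph and on the colored component structure of the adjacency graph, and
  the search stops at the first state with a terminal junction graph (from
  which the target is reachable at zero cost by the completion argument
  above). The merge leans on the fact that these two summaries determine
  the cost-to-go; it is the abstraction that makes tiny-instance search
  tractable, and it is the one point where the oracle is less than fully
  agnostic. Instances up to 10 extremities and 4 colors are confirmed this
  way.

Test problem sizes are chosen so the whole suite runs in minutes: scenario
soundness on 200 random instances (up to 12 extremities), exhaustive
confirmation on dozens of 10-extremity instances, approximation-ratio
checks on 500 instances, and the local structural properties (a 2-break
changes c by at most 1) on all enumerated small Eulerian multigraphs with
up to 4 edges.

## Limitations

* The exact solver's cycle enumeration is exponential in the number of
  colors in the worst case; the cap makes this an explicit failure mode.
* Blocks must be shared one-to-one between the genomes: no insertions,
  deletions or duplications.
* The minimum local *parsimonious* scenario (shortest scenarios only) is
  out of scope; `mlps_gap_bound()` only propagates a user-supplied MLPS
  distance into the bound (d_MLPS − d_MLS)·α on the length excess of an
  optimum under the cost pair (1, 1 + α). The (1, 1 + α) optimization
  problem itself is open.
* The scenario builder emits *one* optimal scenario with deterministic
  tie-breaking; it makes no attempt to enumerate or sample the optimal
  scenario space.
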