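# mlsdcj — minimum local scenarios for DCJ genome rearrangement

Comparative genomics infers how one gene order evolved into another through
rearrangements — inversions, translocations, fusions, fissions — all
expressible as double cut-and-join (DCJ) moves on genome adjacencies.
Parsimonious scenarios are hugely non-unique, so extra biological signal is
needed to tell plausible scenarios from implausible ones. One such signal is
3D chromatin organization: rearrangements are more likely between breakpoints
that are spatially close, and Hi-C contact maps measure that proximity.

`mlsdcj` is for researchers studying rearrangement scenarios under such
positional constraints. The adjacencies of genome *A* are *colored* —
partitioned into classes such as spatial neighborhoods. A DCJ acting within
one color is **local** (cost 0); a DCJ acting across colors is **non-local**
(cost 1). The package computes the **minimum local scenario (MLS)**: a DCJ
scenario from *A* to *B*, of any length, with the fewest non-local moves.

## The method

For genomes *A*, *B* over the same syntenic blocks and a coloring *col* of
*A*'s adjacencies, build the **junction graph** *J(A, B, col)*: one vertex
per color and, for every internal adjacency of *B*, one edge joining the
colors of its two *A*-side neighbors in the adjacency graph. The MLS cost is
the closed form

```
w_MLS = e(J) − c(J)
```

where `e(J)` is the edge count and `c(J)` the size of a **maximum
edge-disjoint cycle packing** (MECP) of *J*. Non-local moves act on *J* as
2-breaks; a packed cycle of length *l* sorts into loops with *l* − 1 of
them, and no move can raise the packing number by more than one. Computing
`c(J)` is NP-hard (the package turns the hardness reduction around to make
verified test instances from Eulerian multigraphs), but exact solving is
practical because the difficulty scales with the number of colors, not
genes. Alongside the exact branch-and-bound the package provides the
linear-time loop/digon greedy giving a **3/2-approximation** and the lower
bound `(2/3)e(J) − (1/3)c2(J) − (2/3)c1(J)`, plus full constructive
scenario recovery with replay validation, genome capping, Hi-C contact-map
normalization (expected-at-distance within chromosomes, coverage-product
between them), k-medoids / linear / random adjacency clusterings, the
clustering weight, and the divergence-from-linearity score.

## Worked example

One linear chromosome with three blocks; the second genome inverts block 2.
Each adjacency of *A* gets its own color (`y`, `z` internal; `t`, `x` the
telomeres):

```r
library(mlsdcj)

A  <- block_to_adjacency(parse_block_genome("1 2 3 $"))$genome
B  <- block_to_adjacency(parse_block_genome("1 -2 3 $"))$genome
cr <- co_rename(A, B)   # canonical extremity labels 1..6
col <- coloring(cr$A, c("1-2" = "y", "3-4" = "z", "5" = "t", "6" = "x"))

res <- min_local_scenario(cr$A, cr$B, col)
res
#> minimum local scenario (exact):
#>   cost (non-local moves): 1
#>   junction edges e(J):    2
#>   packing size c(J):      1
#>   lower bound:            1
#>   scenario length:        1 moves
res$scenario
#> DCJ scenario, 1 move(s), cost 1
#>   (1,2|y),(3,4|z) -> (2,4|y),(1,3|z) cost=1
```

The junction graph has two parallel `y–z` edges (e = 2), which pack into one
digon (c = 1): the inversion needs exactly one move across the two colors,
and the returned scenario performs it. Costs are verified by replay:
`replay(cr$A, col, res$scenario)` reaches `cr$B` with 1 non-local move.

A triangle junction graph separates the exact solver from the greedy
3/2-approximation:

```r
tri  <- multigraph(c("u1", "u2", "u3"),
                   data.frame(u = c("u1", "u2", "u3"), v = c("u2", "u3", "u1")))
inst <- instance_from_eulerian_graph(tri)
mls_cost(inst$A, inst$B, inst$coloring)$cost        #> 2
approx_scenario(inst$A, inst$B, inst$coloring)$cost #> 3   (ratio 3/2, tight)
```

A thin command-line wrapper is installed as `exec/mlsr`
(`mlsr cost|scenario|approx genomeA+colors genomeB`), reading the
adjacency-set text format (one adjacency per line, trailing token = color).

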