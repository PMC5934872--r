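Package: mlsdcj
Title: Minimum Local Scenarios for Double Cut-and-Join Genome Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes rearrangement scenarios between two genomes on shared
    syntenic blocks that minimize the number of non-local double cut-and-join
    (DCJ) moves, given a coloring of one genome's adjacencies into spatial
    neighborhoods (for example, chromatin domains inferred from Hi-C contact
    maps). Implements the junction graph, maximum edge-disjoint cycle packing
    (exact branch-and-bound and a linear-time loop/digon greedy behind a
    3/2-approximation), the closed-form minimum local scenario cost, explicit
    scenario reconstruction with replay validation, genome capping, Hi-C
    contact-map normalization, k-medoids / linear / random adjacency
    clusterings with clustering weight and divergence-from-linearity, and
    synthetic instance generators including a reduction from edge-disjoint
    cycle packing on Eulerian multigraphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
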