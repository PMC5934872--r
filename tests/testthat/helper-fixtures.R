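# Shared fixtures: the worked small instance (one linear chromosome with an
# inverted block, four colors), the triangle reduction instance, and small
# helpers. Everything is built in code; no data files.

# A = {{1,2},{3,4},{5},{6}}, B = {{1,4},{3,2},{5},{6}},
# col = {1,2}->y, {3,4}->z, {5}->t, {6}->x
example1 <- function() {
  A <- genome(list(c(1, 2), c(3, 4), 5, 6))
  B <- genome(list(c(1, 4), c(3, 2), 5, 6))
  col <- coloring(A, c("1-2" = "y", "3-4" = "z", "5" = "t", "6" = "x"))
  list(A = A, B = B, col = col)
}

# triangle junction graph realized as a circular 6-extremity instance:
# A = {{1,2},{3,4},{5,6}}, B = {{2,3},{4,5},{6,1}}, colors u1,u2,u3
triangle_instance <- function() {
  A <- genome(list(c(1, 2), c(3, 4), c(5, 6)))
  B <- genome(list(c(2, 3), c(4, 5), c(6, 1)))
  col <- coloring(A, c("1-2" = "u1", "3-4" = "u2", "5-6" = "u3"))
  list(A = A, B = B, col = col)
}

triangle_graph <- function() {
  multigraph(c("a", "b", "c"),
             data.frame(u = c("a", "b", "c"), v = c("b", "c", "a"),
                        stringsAsFactors = FALSE))
}

# random instance with a random surjective coloring, deterministic under seed
random_colored_instance <- function(seed, max_blocks = 6, max_moves = 10,
                                    max_colors = 4) {
  nb <- 2 + (seed %% (max_blocks - 1))
  nl <- 1 + (seed %% min(2, nb))
  nm <- seed %% (max_moves + 1)
  inst <- random_genome_pair(nb, nl, nm, seed = seed)
  k <- 1 + (seed %% min(max_colors, length(inst$A$adjacencies)))
  col <- random_coloring(inst$A, k, seed = seed + 7919)
  list(A = inst$A, B = inst$B, col = col, n_moves = nm)
}

# do two label vectors agree up to a bijection of labels?
same_partition <- function(a, b) {
  ta <- table(a, b)
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# color every adjacency of A by its adjacency-graph component index
component_coloring <- function(A, B) {
  ag <- build_adjacency_graph(A, B)
  cols <- character(0)
  for (ci in seq_along(ag$components)) {
    av <- ag$components[[ci]]$vertices
    av <- substring(av[startsWith(av, "A:")], 3)
    cols[av] <- paste0("comp", ci)
  }
  coloring(A, cols)
}
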