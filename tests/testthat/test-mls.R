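# MLS cost formula, 2-break sorting, scenario construction, capping and the
# 3/2-approximation.

test_that("mls_cost matches e(J) - c(J) on the worked instances", {
  e1 <- example1()
  r <- mls_cost(e1$A, e1$B, e1$col)
  expect_identical(r$cost, 1L)
  expect_identical(r$junction_edges, 2L)
  expect_length(r$packing, 1L)

  # identical genomes cost nothing under any coloring
  inst <- random_colored_instance(4)
  expect_identical(mls_cost(inst$A, inst$A, inst$col)$cost, 0L)

  tri <- triangle_instance()
  rt <- mls_cost(tri$A, tri$B, tri$col)
  expect_identical(rt$cost, 2L)
  expect_identical(rt$junction_edges, 3L)
})

test_that("two_break_sort sorts cycle by cycle in e - c steps", {
  # terminal graph: nothing to do
  loops <- multigraph(c("a", "b"), data.frame(u = c("a", "b"), v = c("a", "b")))
  expect_length(two_break_sort(loops, mecp_bruteforce(loops)), 0L)

  # a single 4-cycle needs exactly 3 2-breaks
  c4 <- multigraph(c("a", "b", "c", "d"),
                   data.frame(u = c("a", "b", "c", "d"),
                              v = c("b", "c", "d", "a")))
  tbs <- two_break_sort(c4, mecp_bruteforce(c4))
  expect_length(tbs, 3L)
  g <- c4
  for (tb in tbs) g <- apply_two_break(g, tb)
  expect_true(is_terminal(g))

  # the worked digon sorts with the single 2-break (y,z),(y,z) -> (y,y),(z,z)
  e1 <- example1()
  J <- build_junction_graph(e1$A, e1$B, e1$col)
  tb1 <- two_break_sort(J, mecp_exact(J))
  expect_length(tb1, 1L)
  after <- apply_two_break(J, tb1[[1]])
  expect_true(is_terminal(after))
  expect_setequal(c(after$edges$u, after$edges$v), c("y", "y", "z", "z"))

  # packing must cover the graph
  expect_error(two_break_sort(c4, cycle_packing(list(), host = c4)),
               "does not cover")
})

test_that("sorting length matches the BFS oracle on enumerated Eulerian graphs", {
  graphs <- enumerate_eulerian_multigraphs(3, 4)
  for (g in graphs) {
    c_ <- length(mecp_bruteforce(g))
    expect_identical(min_two_break_sort_length(g), n_edges(g) - c_)
    expect_length(two_break_sort(g, mecp_bruteforce(g)), n_edges(g) - c_)
  }
})

test_that("min_local_scenario replays to B with exactly e - c non-local moves", {
  e1 <- example1()
  res <- min_local_scenario(e1$A, e1$B, e1$col)
  rp <- replay(e1$A, e1$col, res$scenario)
  expect_true(genomes_equal(rp$genome, e1$B))
  expect_identical(rp$n_nonlocal, 1L)

  # A = B: zero-cost scenario
  res0 <- min_local_scenario(e1$A, e1$A, e1$col)
  expect_identical(res0$cost, 0L)
  expect_identical(replay(e1$A, e1$col, res0$scenario)$total_cost, 0L)

  tri <- triangle_instance()
  rest <- min_local_scenario(tri$A, tri$B, tri$col)
  expect_identical(rest$cost, 2L)
  rpt <- replay(tri$A, tri$col, rest$scenario)
  expect_true(genomes_equal(rpt$genome, tri$B))
  expect_identical(rpt$n_nonlocal, 2L)
})

test_that("scenario soundness and the lower-bound sandwich hold on random instances", {
  for (s in 1:40) {
    inst <- random_colored_instance(s)
    res <- min_local_scenario(inst$A, inst$B, inst$col)
    rp <- replay(inst$A, inst$col, res$scenario)
    expect_true(genomes_equal(rp$genome, inst$B))
    expect_identical(rp$n_nonlocal, res$cost)
    ap <- approx_scenario(inst$A, inst$B, inst$col)
    rpa <- replay(inst$A, inst$col, ap$scenario)
    expect_true(genomes_equal(rpa$genome, inst$B))
    expect_identical(rpa$n_nonlocal, ap$cost)
    # lower_bound <= cost <= approx <= 1.5 * cost
    expect_lte(res$lower_bound, res$cost + 1e-9)
    expect_lte(res$cost, ap$cost)
    expect_lte(ap$cost, 1.5 * res$cost + 1e-9)
    # a witness scenario of n_moves moves exists, so cost <= n_moves
    expect_lte(res$cost, inst$n_moves)
  }
})

test_that("the exhaustive search confirms optimality on tiny instances", {
  e1 <- example1()
  expect_identical(exhaustive_min_cost_search(e1$A, e1$B, e1$col), 1L)
  expect_identical(exhaustive_min_cost_search(e1$A, e1$A, e1$col), 0L)
  tri <- triangle_instance()
  expect_identical(exhaustive_min_cost_search(tri$A, tri$B, tri$col), 2L)
  for (s in 1:12) {
    inst <- random_colored_instance(s, max_blocks = 4, max_moves = 6,
                                    max_colors = 3)
    if (length(inst$A$universe) > 8) next
    expect_identical(exhaustive_min_cost_search(inst$A, inst$B, inst$col),
                     mls_cost(inst$A, inst$B, inst$col)$cost)
  }
})

test_that("approx_scenario achieves e - c1 - c2 and the triangle is ratio 3/2", {
  e1 <- example1()
  expect_identical(approx_scenario(e1$A, e1$B, e1$col)$cost, 1L) # optimal here
  tri <- triangle_instance()
  ap <- approx_scenario(tri$A, tri$B, tri$col)
  expect_identical(ap$cost, 3L)
  expect_identical(ap$cost / mls_cost(tri$A, tri$B, tri$col)$cost, 1.5)
  # all-loop junction graph: approximation is free
  inst <- random_colored_instance(6)
  mono <- coloring(inst$A, rep("m", length(inst$A$adjacencies)))
  expect_identical(approx_scenario(inst$A, inst$B, mono)$cost, 0L)
})

test_that("capping produces circular extensions non-loop equal to J'", {
  # circular-only instance: nothing to cap
  g <- random_eulerian_multigraph(3, 4, seed = 2, connected = TRUE)
  inst <- instance_from_eulerian_graph(g)
  cap0 <- cap_instance(inst$A, inst$B, inst$coloring)
  expect_true(genomes_equal(cap0$A_hat, inst$A))
  expect_true(genomes_equal(cap0$B_hat, inst$B))
  expect_length(cap0$telomeric_keys, 0L)

  # worked instance: the two telomere paths close with telomeric pairs and
  # the junction graph keeps its non-loop edges
  e1 <- example1()
  cap1 <- cap_instance(e1$A, e1$B, e1$col)
  expect_identical(cap1$A_hat$n_external, 0L)
  expect_identical(cap1$B_hat$n_external, 0L)
  expect_length(cap1$telomeric_keys, 2L)
  Jpp <- build_junction_graph(cap1$A_hat, cap1$B_hat, cap1$col_hat)
  nl <- function(g) {
    e <- g$edges[g$edges$u != g$edges$v, , drop = FALSE]
    sort(paste(pmin(e$u, e$v), pmax(e$u, e$v)))
  }
  expect_identical(nl(Jpp), nl(cap1$extension))

  # random instances: non-loop equality and valid circular genomes throughout
  for (s in c(2, 8, 15, 23)) {
    inst <- random_colored_instance(s)
    cap <- cap_instance(inst$A, inst$B, inst$col)
    expect_identical(cap$A_hat$n_external + cap$B_hat$n_external, 0L)
    Jpp <- build_junction_graph(cap$A_hat, cap$B_hat, cap$col_hat)
    expect_identical(nl(Jpp), nl(cap$extension))
    expect_true(is_eulerian(cap$extension))
    # non-telomeric pairs of A_hat map one-to-one onto adjacencies of A
    non_tel <- setdiff(names(cap$A_hat$adjacencies), cap$telomeric_keys)
    real <- lapply(cap$A_hat$adjacencies[non_tel], function(p)
      p[p <= max(inst$A$universe)])
    expect_setequal(vapply(real, adj_key, character(1)),
                    names(inst$A$adjacencies))
  }
})

test_that("capping accepts an arbitrary Eulerian extension (H-cycle case)", {
  e1 <- example1()
  J <- build_junction_graph(e1$A, e1$B, e1$col)
  # add a (y,z,x) triangle on top of J: J' - J then contains a cycle
  extra <- data.frame(id = max(J$edges$id) + 1:3,
                      u = c("y", "z", "x"), v = c("z", "x", "y"),
                      artificial = TRUE, b_key = NA_character_,
                      stringsAsFactors = FALSE)
  Jp <- multigraph(J$vertices, rbind(J$edges, extra))
  expect_true(is_eulerian(Jp))
  cap <- cap_instance(e1$A, e1$B, e1$col, extension = Jp)
  expect_identical(length(cap$h_cycles) + length(cap$f_paths), 1L)
  nl <- function(g) {
    e <- g$edges[g$edges$u != g$edges$v, , drop = FALSE]
    sort(paste(pmin(e$u, e$v), pmax(e$u, e$v)))
  }
  Jpp <- build_junction_graph(cap$A_hat, cap$B_hat, cap$col_hat)
  expect_identical(nl(Jpp), nl(Jp))
  # a non-Eulerian extension is rejected
  bad <- multigraph(J$vertices, rbind(J$edges, extra[1, ]))
  expect_error(cap_instance(e1$A, e1$B, e1$col, extension = bad),
               "not Eulerian")
})

test_that("mlps_gap_bound does its arithmetic and validation", {
  expect_identical(mlps_gap_bound(5, 5, 2), 0)
  expect_identical(mlps_gap_bound(7, 5, 1 / 2), 1)
  # grows linearly in the gap
  expect_identical(mlps_gap_bound(9, 5, 1 / 2), 2)
  expect_error(mlps_gap_bound(4, 5, 1), "d_mlps >= d_mls")
  expect_error(mlps_gap_bound(5, 4, 0), "positive")
})
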