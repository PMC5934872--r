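# Genome representation, block parsing, extremity renaming, colored DCJ
# moves and scenario replay.

test_that("GRIMM-style parsing handles signs, terminators and errors", {
  g <- parse_block_genome("1 2 3 $")
  expect_length(g, 1L)
  expect_identical(g[[1]]$blocks, c("1", "2", "3"))
  expect_false(g[[1]]$circular)

  inv <- parse_block_genome("1 -2 3 $")
  expect_identical(inv[[1]]$signs, c(1L, -1L, 1L))

  circ <- parse_block_genome("# comment\n> name\na b @")
  expect_true(circ[[1]]$circular)

  expect_error(parse_block_genome("1 2 $\n1 3 $"), "duplicate block")
  expect_error(parse_block_genome("$"), "empty chromosome")
  expect_error(parse_block_genome("1 2 3"), "must end with")
})

test_that("block extremities rename to tail 2i-1 / head 2i and adjacencies follow", {
  # single linear chromosome A B -C: {{A_t},{A_h,B_t},{B_h,C_h},{C_t}}
  # renames to {{1,2},{3,4},{5},{6}} after co-renaming
  ba <- block_to_adjacency(parse_block_genome("1 2 -3 $"))
  g <- ba$genome
  expect_identical(g$n_internal, 2L)
  expect_identical(g$n_external, 2L)
  # tail(1)=1, head(1)=2, tail(2)=3, head(2)=4, tail(3)=5, head(3)=6
  expect_true("2-3" %in% names(g$adjacencies))   # head(1)-tail(2)
  expect_true("4-6" %in% names(g$adjacencies))   # head(2)-head(3) (3 inverted)
  expect_true(all(c("1", "5") %in% names(g$adjacencies)))

  # smallest circular genome: one block, one adjacency, no telomeres
  circ <- block_to_adjacency(parse_block_genome("1 @"))$genome
  expect_identical(names(circ$adjacencies), "1-2")
  expect_identical(circ$n_external, 0L)

  # identical genomes give identical adjacency sets
  g1 <- block_to_adjacency(parse_block_genome("1 2 $\n3 4 $"))$genome
  g2 <- block_to_adjacency(parse_block_genome("1 2 $\n3 4 $"))$genome
  expect_identical(names(g1$adjacencies), names(g2$adjacencies))
})

test_that("round trip block -> adjacency -> block preserves chromosomes", {
  texts <- c("1 2 3 $", "1 -2 3 $\n4 5 $", "1 2 @\n3 $", "1 -2 -3 4 @")
  for (txt in texts) {
    bg <- parse_block_genome(txt)
    ba <- block_to_adjacency(bg)
    back <- adjacency_to_block(ba$genome, ba$map)
    # same multiset of blocks per chromosome type; same adjacency set again
    ba2 <- block_to_adjacency(back)
    expect_setequal(names(ba2$genome$adjacencies), names(ba$genome$adjacencies))
    expect_identical(sum(vapply(back, `[[`, logical(1), "circular")),
                     sum(vapply(bg, `[[`, logical(1), "circular")))
  }
})

test_that("co_rename produces the canonical pair coding", {
  # worked example: original A/B over extremities named after blocks
  fig1 <- block_to_adjacency(parse_block_genome("1 2 3 $"))$genome
  fig2 <- block_to_adjacency(parse_block_genome("1 -2 3 $"))$genome
  cr <- co_rename(fig1, fig2)
  expect_identical(names(cr$A$adjacencies), c("1-2", "3-4", "5", "6"))
  # the inversion recombines the two internal adjacencies of A and keeps the
  # telomeres (the deterministic co-renaming orders A's internals by their
  # smallest member, so B comes out as {{1,3},{2,4},{5},{6}})
  expect_setequal(names(cr$B$adjacencies), c("1-3", "2-4", "5", "6"))
  # identity: A = B stays equal
  cr2 <- co_rename(fig1, fig1)
  expect_identical(names(cr2$A$adjacencies), names(cr2$B$adjacencies))
  # mismatched universes raise
  expect_error(co_rename(fig1, genome(list(c(1, 2), 3, 4))),
               "different extremity universes")
})

test_that("genome invariants are enforced", {
  expect_error(genome(list(c(1, 2), c(2, 3))), "more than one adjacency")
  expect_error(genome(list(c(1, 1))), "distinct")
  expect_error(genome(list(c(1, 2, 3))), "1 or 2")
})

test_that("the four move templates apply with the stated costs", {
  e1 <- example1()
  # the worked non-local move transforming A into B
  mv <- dcj_move(list(c(1, 2), c(3, 4)), list(c(1, 4), c(3, 2)),
                 c("y", "z"), c("y", "z"))
  st <- apply_move(e1$A, e1$col, mv)
  expect_identical(st$cost, 1L)
  expect_true(genomes_equal(st$genome, e1$B))
  expect_identical(unname(st$coloring[["1-4"]]), "y")

  # same-colored pair-pair move costs 0
  A2 <- genome(list(c(1, 2), c(3, 4)))
  c2 <- coloring(A2, c("1-2" = "x", "3-4" = "x"))
  mv0 <- dcj_move(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                  c("x", "x"), c("x", "x"))
  expect_identical(apply_move(A2, c2, mv0)$cost, 0L)

  # split keeps the consumed color on one product; z free
  sp0 <- dcj_move(list(c(1, 2)), list(1, 2), "x", c("x", "x"))
  sp1 <- dcj_move(list(c(1, 2)), list(1, 2), "x", c("x", "q"))
  expect_identical(sp0$cost, 0L)
  expect_identical(sp1$cost, 1L)

  # join may take either consumed color
  jn <- dcj_move(list(1, 2), list(c(1, 2)), c("x", "y"), "y")
  expect_identical(jn$cost, 1L)

  # invalid rewrites are rejected
  expect_error(dcj_move(list(c(1, 2), c(3, 4)), list(c(1, 2), c(3, 4)),
                        c("x", "y"), c("x", "y")), "differ from consumed")
  expect_error(dcj_move(list(c(1, 2)), list(1, 3), "x", c("x", "x")),
               "conserve extremities")
  expect_error(dcj_move(list(c(1, 2)), list(1, 2), "x", c("q", "q")),
               "keep the consumed color")
})

test_that("apply_move validates against the current state", {
  e1 <- example1()
  mv <- dcj_move(list(c(1, 3), c(2, 4)), list(c(1, 2), c(3, 4)),
                 c("y", "z"), c("y", "z"))
  expect_error(apply_move(e1$A, e1$col, mv), "absent from genome")
  mv2 <- dcj_move(list(c(1, 2), c(3, 4)), list(c(1, 4), c(3, 2)),
                  c("y", "y"), c("y", "y"))
  expect_error(apply_move(e1$A, e1$col, mv2), "move expects")
})

test_that("replay accounts cost additively and conserves extremities", {
  e1 <- example1()
  # empty scenario: identity
  r0 <- replay(e1$A, e1$col, dcj_scenario())
  expect_identical(r0$total_cost, 0L)
  expect_true(genomes_equal(r0$genome, e1$A))

  # the single worked move reaches B at cost 1
  mv <- dcj_move(list(c(1, 2), c(3, 4)), list(c(1, 4), c(3, 2)),
                 c("y", "z"), c("y", "z"))
  r1 <- replay(e1$A, e1$col, dcj_scenario(list(mv)))
  expect_true(genomes_equal(r1$genome, e1$B))
  expect_identical(r1$total_cost, 1L)
  expect_identical(r1$n_nonlocal, 1L)

  # a same-color-only scenario costs 0, and replay cost is invariant under
  # re-chunking (sum of parts equals the whole)
  A <- genome(list(c(1, 2), c(3, 4)))
  cc <- coloring(A, c("1-2" = "x", "3-4" = "x"))
  m1 <- dcj_move(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                 c("x", "x"), c("x", "x"))
  m2 <- dcj_move(list(c(1, 3), c(2, 4)), list(c(1, 2), c(3, 4)),
                 c("x", "x"), c("x", "x"))
  whole <- replay(A, cc, dcj_scenario(list(m1, m2)))
  expect_identical(whole$total_cost, 0L)
  part1 <- replay(A, cc, dcj_scenario(list(m1)))
  part2 <- replay(part1$genome, part1$coloring, dcj_scenario(list(m2)))
  expect_identical(part1$total_cost + part2$total_cost, whole$total_cost)
  expect_true(genomes_equal(whole$genome, A))

  # extremity conservation along a random replayed scenario
  inst <- random_colored_instance(11)
  sc <- min_local_scenario(inst$A, inst$B, inst$col)$scenario
  g <- inst$A
  cc <- inst$col
  for (mv in sc$moves) {
    st <- apply_move(g, cc, mv)
    expect_identical(st$genome$universe, g$universe)
    g <- st$genome
    cc <- st$coloring
  }
})
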