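# The minimum local scenario (MLS) solver. The cost of an optimal scenario
# transforming A into B under a coloring of A is e(J) - c(J), the number of
# junction-graph edges minus the size of a maximum edge-disjoint cycle
# packing. Scenario construction realizes a packing-guided 2-break schedule
# directly on the genome: every 2-break becomes one extremity exchange (a
# pair-pair or pair-telomere DCJ), every uncovered junction edge is resolved
# by one split or telomere join, and zero-cost moves restructure telomeres
# and finish sorting inside monochromatic adjacency-graph components.

#' MLS result container
#' @keywords internal
new_mls_result <- function(cost, junction, packing, scenario = NULL,
                           method = "exact") {
  red <- reduce_loops_digons(junction)
  e <- n_edges(junction)
  structure(
    list(cost = as.integer(cost),
         junction_edges = e,
         packing = packing,
         lower_bound = (2 / 3) * e - (1 / 3) * red$c2 - (2 / 3) * red$c1,
         scenario = scenario,
         method = method,
         junction = junction),
    class = "mls_result"
  )
}

#' @export
print.mls_result <- function(x, ...) {
  cat("minimum local scenario (", x$method, "):\n", sep = "")
  cat("  cost (non-local moves): ", x$cost, "\n", sep = "")
  cat("  junction edges e(J):    ", x$junction_edges, "\n", sep = "")
  cat("  packing size c(J):      ", length(x$packing), "\n", sep = "")
  cat("  lower bound:            ", format(x$lower_bound, digits = 4), "\n",
      sep = "")
  if (!is.null(x$scenario)) {
    cat("  scenario length:        ", length(x$scenario$moves), " moves\n",
        sep = "")
  }
  invisible(x)
}

#' Cost of a minimum local scenario
#'
#' Computes `e(J) - c(J)` for the junction graph `J = J(A, B, col)`, with
#' `c(J)` from the exact cycle packing solver, together with the
#' loop/digon-based lower bound `(2/3) e(J) - (1/3) c2(J) - (2/3) c1(J)`.
#'
#' @param A,B co-renamed [genome()]s over the same universe.
#' @param col a [coloring()] of `A`.
#' @param config list passed to [mecp_exact()] (notably `cycle_cap`).
#' @return an object of class `"mls_result"` (without a scenario): fields
#'   `cost`, `junction_edges`, `packing`, `lower_bound`, `junction`.
#' @examples
#' A <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' B <- genome(list(c(1, 4), c(3, 2), 5, 6))
#' col <- coloring(A, c("1-2" = "y", "3-4" = "z", "5" = "t", "6" = "x"))
#' mls_cost(A, B, col)$cost
#' @export
mls_cost <- function(A, B, col, config = list()) {
  J <- build_junction_graph(A, B, col)
  packing <- mecp_exact(J, config)
  new_mls_result(n_edges(J) - length(packing), J, packing)
}

#' Sort an Eulerian multigraph into a terminal graph by 2-breaks
#'
#' Given a cycle packing covering all edges (an MECP of an Eulerian graph
#' does), each cycle of length *l* is sorted with `l - 1` 2-breaks by
#' repeatedly splitting off a loop, for `e(g) - |packing|` 2-breaks in total.
#'
#' @param g an Eulerian [multigraph()].
#' @param packing a [cycle_packing()] covering every edge of `g`.
#' @return a list of [two_break()]s; applying them in order to `g` yields a
#'   terminal graph.
#' @export
two_break_sort <- function(g, packing) {
  if (!is_eulerian(g)) abort("graph is not Eulerian")
  ids <- sort(unlist(packing$cycles, use.names = FALSE))
  if (!identical(ids, sort(g$edges$id))) {
    abort("packing does not cover the graph")
  }
  validate_packing(g, packing)
  ord <- order(vapply(packing$cycles, min, integer(1)))
  breaks <- list()
  cur <- g
  for (cyc in packing$cycles[ord]) {
    if (length(cyc) == 1L) next
    w <- cycle_walk(cur, cyc)
    V <- w$vertices
    E <- w$edges
    while (length(E) >= 2L) {
      v1 <- V[1]
      v2 <- V[2]
      v3 <- if (length(V) >= 3L) V[3] else V[1]
      tb <- two_break(c(E[1], E[2]), list(c(v2, v2), c(v1, v3)))
      cur <- apply_two_break(cur, tb)
      breaks[[length(breaks) + 1L]] <- tb
      V <- V[-2]
      E <- E[-1]
    }
  }
  if (!is_terminal(cur)) abort("internal error: sorting did not reach a terminal graph")
  breaks
}

# ---- genome-level scenario construction --------------------------------------

# Realize the packing-guided sorting schedule as DCJ moves on (A, col).
# Returns list(scenario, final_genome, final_coloring).
build_scenario_moves <- function(A, B, col, J, packing) {
  g <- A
  cc <- col
  cur_idx <- extremity_index(g)
  moves <- list()

  emit <- function(consumed, produced, ccols, pcols) {
    mv <- dcj_move(consumed, produced, ccols, pcols)
    st <- apply_move(g, cc, mv)
    g <<- st$genome
    cc <<- st$coloring
    cur_idx <<- extremity_index(g)
    moves[[length(moves) + 1L]] <<- mv
    invisible(mv)
  }
  key_of <- function(e) cur_idx[[as.character(e)]]
  adj_cur <- function(e) g$adjacencies[[key_of(e)]]
  col_cur <- function(e) unname(cc[[key_of(e)]])

  # zero-cost restructuring: make the adjacency holding extremity `e`
  # internal by joining it with another adjacency of the same color
  # (splitting an internal one first if needed)
  make_internal <- function(e) {
    k <- key_of(e)
    if (length(g$adjacencies[[k]]) == 2L) return(invisible(NULL))
    x <- unname(cc[[k]])
    others <- setdiff(names(cc)[unname(cc) == x], k)
    if (!length(others)) {
      abort("internal error: lone telomere of color ", x, " cannot be paired")
    }
    sizes <- lengths(g$adjacencies[others])
    others <- others[order(sizes, others)] # prefer an external partner
    ok <- others[1]
    oadj <- g$adjacencies[[ok]]
    if (length(oadj) == 2L) {
      emit(list(oadj), list(oadj[1], oadj[2]), x, c(x, x))
      partner <- oadj[1]
    } else {
      partner <- oadj
    }
    emit(list(e, partner), list(c(e, partner)), c(x, x), x)
    invisible(NULL)
  }

  # one non-local move exchanging extremities s1 and s2 between their
  # (distinct, not both external) adjacencies; each keeps its pair's color
  do_swap <- function(s1, s2) {
    a1 <- adj_cur(s1)
    a2 <- adj_cur(s2)
    x <- col_cur(s1)
    y <- col_cur(s2)
    if (length(a1) == 1L && length(a2) == 1L) {
      abort("internal error: telomere-telomere exchange is not a DCJ")
    }
    p1 <- c(setdiff(a1, s1), s2)
    p2 <- c(setdiff(a2, s2), s1)
    emit(list(a1, a2), list(p1, p2), c(x, y), c(x, y))
  }

  b_internals <- names(B$adjacencies)[lengths(B$adjacencies) == 2L]
  edge_bkey <- if (nrow(J$edges)) {
    stats::setNames(J$edges$b_key, J$edges$id)
  } else {
    character(0)
  }

  # current slot extremity of junction edge `eid` at color `colv`
  slot_of <- function(eid, colv) {
    bb <- adj_from_key(edge_bkey[[as.character(eid)]])
    hit <- bb[vapply(bb, function(e) col_cur(e) == colv, logical(1))]
    if (length(hit) != 1L) {
      abort("internal error: ambiguous junction slot for edge ", eid)
    }
    hit
  }

  # 1. uncovered junction edges: one split or telomere join each
  covered <- unlist(packing$cycles, use.names = FALSE)
  uncovered <- setdiff(J$edges$id, covered)
  for (eid in sort(uncovered)) {
    bb <- adj_from_key(edge_bkey[[as.character(eid)]])
    b1 <- bb[1]
    b2 <- bb[2]
    x <- col_cur(b1)
    y <- col_cur(b2)
    if (x == y) next
    a1 <- adj_cur(b1)
    a2 <- adj_cur(b2)
    if (length(a1) == 2L) {
      p <- setdiff(a1, b1)
      emit(list(a1), list(p, b1), x, c(x, y))
    } else if (length(a2) == 2L) {
      q <- setdiff(a2, b2)
      emit(list(a2), list(q, b2), y, c(y, x))
    } else {
      emit(list(b1, b2), list(c(b1, b2)), c(x, y), x)
    }
  }

  # 2. packing cycles: length-l cycle sorted with l - 1 extremity exchanges
  ord <- order(vapply(packing$cycles, min, integer(1)))
  for (cyc in packing$cycles[ord]) {
    if (length(cyc) < 2L) next
    rows <- match(cyc, J$edges$id)
    ends <- lapply(J$edges$b_key[rows], adj_from_key)
    colpairs <- lapply(ends, function(bb) c(col_cur(bb[1]), col_cur(bb[2])))
    mg <- multigraph(unique(unlist(colpairs)), data.frame(
      id = cyc,
      u = vapply(colpairs, `[`, character(1), 1L),
      v = vapply(colpairs, `[`, character(1), 2L),
      stringsAsFactors = FALSE
    ))
    w <- cycle_walk(mg, cyc)
    V <- w$vertices
    E <- w$edges
    while (length(E) >= 2L) {
      v1 <- V[1]
      v2 <- V[2]
      s1 <- slot_of(E[1], v1)
      s2 <- slot_of(E[2], v2)
      if (length(adj_cur(s1)) == 1L && length(adj_cur(s2)) == 1L) {
        make_internal(s2)
      }
      do_swap(s1, s2)
      V <- V[-2]
      E <- E[-1]
    }
  }

  # 3. zero-cost completion inside monochromatic components: create every
  # missing internal adjacency of B
  repeat {
    missing <- setdiff(b_internals, names(g$adjacencies))
    if (!length(missing)) break
    bb <- adj_from_key(sort(missing)[1])
    a <- bb[1]
    b <- bb[2]
    x <- col_cur(a)
    if (col_cur(b) != x) {
      abort("internal error: junction graph not terminal before completion")
    }
    a1 <- adj_cur(a)
    a2 <- adj_cur(b)
    rest <- c(setdiff(a1, a), setdiff(a2, b))
    if (length(rest) >= 1L) {
      emit(list(a1, a2), list(c(a, b), rest), c(x, x), c(x, x))
    } else {
      emit(list(a1, a2), list(c(a, b)), c(x, x), x)
    }
  }
  # split the surplus internal adjacencies (their extremities are telomeres
  # of B) -- zero cost, color kept on both products
  surplus <- setdiff(names(g$adjacencies)[lengths(g$adjacencies) == 2L],
                     b_internals)
  for (k in sort(surplus)) {
    a12 <- g$adjacencies[[k]]
    x <- unname(cc[[k]])
    emit(list(a12), list(a12[1], a12[2]), x, c(x, x))
  }
  if (!genomes_equal(g, B)) {
    abort("internal error: scenario does not reach the target genome")
  }
  list(scenario = dcj_scenario(moves), genome = g, coloring = cc)
}

#' Minimum local scenario with explicit move list
#'
#' End-to-end solver: builds the junction graph, finds a maximum cycle
#' packing, and realizes the packing-guided 2-break schedule as a DCJ
#' scenario on `(A, col)` that replays to `B` with exactly `e(J) - c(J)`
#' non-local moves. The returned scenario is replay-validated.
#'
#' @inheritParams mls_cost
#' @return an `"mls_result"` whose `scenario` is a [dcj_scenario()]; the
#'   field `final_coloring` carries the coloring after replay.
#' @examples
#' A <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' B <- genome(list(c(1, 4), c(3, 2), 5, 6))
#' col <- coloring(A, c("1-2" = "y", "3-4" = "z", "5" = "t", "6" = "x"))
#' res <- min_local_scenario(A, B, col)
#' res$cost
#' @export
min_local_scenario <- function(A, B, col, config = list()) {
  J <- build_junction_graph(A, B, col)
  packing <- mecp_exact(J, config)
  built <- build_scenario_moves(A, B, col, J, packing)
  expected <- n_edges(J) - length(packing)
  chk <- replay(A, col, built$scenario)
  if (!genomes_equal(chk$genome, B) || chk$n_nonlocal != expected) {
    abort("internal error: scenario replay does not match the predicted cost")
  }
  res <- new_mls_result(expected, J, packing, scenario = built$scenario)
  res$final_coloring <- built$coloring
  res
}

#' 3/2-approximate local scenario
#'
#' Same pipeline as [min_local_scenario()] but with the linear-time
#' loop/digon greedy packing, so no simple-cycle enumeration is needed. The
#' reported cost `w' = e(J) - c1(J) - c2(J)` satisfies
#' `w' / w_MLS <= 3/2`.
#'
#' @inheritParams mls_cost
#' @return an `"mls_result"` (method `"approx"`) with a replay-validated
#'   scenario of exactly `w'` non-local moves.
#' @export
approx_scenario <- function(A, B, col, config = list()) {
  J <- build_junction_graph(A, B, col)
  packing <- greedy_loops_digons_packing(J)
  built <- build_scenario_moves(A, B, col, J, packing)
  expected <- n_edges(J) - length(packing)
  chk <- replay(A, col, built$scenario)
  if (!genomes_equal(chk$genome, B) || chk$n_nonlocal != expected) {
    abort("internal error: scenario replay does not match the predicted cost")
  }
  res <- new_mls_result(expected, J, packing, scenario = built$scenario,
                        method = "approx")
  res$final_coloring <- built$coloring
  res
}

#' Upper bound on the length excess of a weighted-cost optimum
#'
#' For the normalized cost pair `(1, 1 + alpha)` (local moves cost 1,
#' non-local `1 + alpha`), the difference between the length of a scenario
#' minimizing that cost and the DCJ distance is bounded by
#' `(d_mlps - d_mls) * alpha`, where `d_mlps` and `d_mls` are the non-local
#' counts of a minimum local parsimonious scenario and of a minimum local
#' scenario. `d_mlps` must be supplied (its computation is outside this
#' package's scope).
#'
#' @param d_mlps,d_mls non-negative integers with `d_mlps >= d_mls`.
#' @param alpha positive number.
#' @return the numeric bound `(d_mlps - d_mls) * alpha`.
#' @examples
#' mlps_gap_bound(7, 5, 1 / 2)
#' @export
mlps_gap_bound <- function(d_mlps, d_mls, alpha) {
  if (d_mls < 0 || d_mlps < d_mls) {
    abort("need d_mlps >= d_mls >= 0")
  }
  if (alpha <= 0) abort("alpha must be positive")
  (d_mlps - d_mls) * alpha
}
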