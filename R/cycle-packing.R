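# Maximum edge-disjoint cycle packing (MECP). A cycle is a connected
# 2-regular edge subset of the multigraph: a loop (one edge), a digon (two
# parallel edges) or a longer vertex-simple cycle. c(G) -- the size of an
# MECP -- drives the minimum-local-scenario cost e(J) - c(J).
#
# The exact solver follows the standard route: strip loops and a maximum set
# of digons (some MECP always contains all of them), enumerate the simple
# cycles of the remaining simple graph, and solve maximum set packing on
# their edge sets by deterministic branch-and-bound. A subset-enumeration
# brute force serves as an independent oracle on small graphs.

#' Cycle packing container
#'
#' @param cycles list of integer vectors, each the edge-id set of one cycle.
#' @param host the [multigraph()] the packing lives in (its key is stored for
#'   validation).
#' @return an object of class `"cycle_packing"`.
#' @export
cycle_packing <- function(cycles, host = NULL) {
  cycles <- lapply(cycles, function(x) sort(as.integer(x)))
  ids <- unlist(cycles, use.names = FALSE)
  if (anyDuplicated(ids)) abort("cycles are not edge-disjoint")
  structure(list(cycles = cycles,
                 host_key = if (!is.null(host)) multigraph_key(host) else NA_character_),
            class = "cycle_packing")
}

#' @export
length.cycle_packing <- function(x) length(x$cycles)

#' @export
print.cycle_packing <- function(x, ...) {
  s <- packing_stats(x)
  cat("cycle packing: size", s$size, "(", s$n_loops, "loops,", s$n_digons,
      "digons,", s$n_longer, "longer )\n")
  invisible(x)
}

#' Loop / digon / longer-cycle counts of a packing
#'
#' @param packing a [cycle_packing()].
#' @return a list with `size`, `n_loops`, `n_digons`, `n_longer`.
#' @export
packing_stats <- function(packing) {
  len <- lengths(packing$cycles)
  list(size = length(len), n_loops = sum(len == 1L),
       n_digons = sum(len == 2L), n_longer = sum(len >= 3L))
}

# is `ids` (edge-id vector) a single cycle of g: connected and 2-regular
is_cycle_edge_set <- function(g, ids) {
  rows <- match(ids, g$edges$id)
  ends <- c(g$edges$u[rows], g$edges$v[rows])
  deg <- table(ends)
  if (any(deg %% 2L != 0L)) return(FALSE)
  # loops count twice at their vertex
  loops <- g$edges$u[rows] == g$edges$v[rows]
  if (length(ids) == 1L) return(loops[1])
  if (any(loops)) return(FALSE)
  if (any(deg != 2L)) return(FALSE)
  sub <- multigraph(unique(ends), g$edges[rows, c("id", "u", "v")])
  mg_is_connected(sub)
}

#' Validate a cycle packing against its host graph
#' @param g a [multigraph()]; @param packing a [cycle_packing()].
#' @return `TRUE` invisibly; aborts on an invalid packing.
#' @export
validate_packing <- function(g, packing) {
  ids <- unlist(packing$cycles, use.names = FALSE)
  if (anyDuplicated(ids)) abort("cycles are not edge-disjoint")
  if (!all(ids %in% g$edges$id)) abort("packing references unknown edge ids")
  for (cyc in packing$cycles) {
    if (!is_cycle_edge_set(g, cyc)) {
      abort("edge set {", paste(cyc, collapse = ","), "} is not a single cycle")
    }
  }
  invisible(TRUE)
}

#' Strip loops and a maximum digon set from a multigraph
#'
#' Removes every loop (each a length-1 cycle) and, for every vertex pair with
#' edge multiplicity *m*, `floor(m/2)` digons. Some maximum packing always
#' contains all of these, so the MECP size decomposes as
#' `c(g) = c1 + c2 + c(reduced)` with the reduced graph simple.
#'
#' @param g a [multigraph()].
#' @return a list with `reduced` (a simple [multigraph()]), counts `c1` and
#'   `c2`, and `removed` (the list of removed cycles as edge-id vectors).
#' @export
reduce_loops_digons <- function(g) {
  e <- g$edges
  removed <- list()
  is_loop <- e$u == e$v
  removed <- c(removed, as.list(e$id[is_loop]))
  c1 <- sum(is_loop)
  e <- e[!is_loop, , drop = FALSE]
  c2 <- 0L
  if (nrow(e)) {
    pair <- apply(cbind(e$u, e$v), 1, function(x) paste(sort(x), collapse = "~"))
    for (p in unique(pair)) {
      ids <- e$id[pair == p]
      k <- length(ids) %/% 2L
      if (k > 0L) {
        for (j in seq_len(k)) {
          removed <- c(removed, list(ids[c(2L * j - 1L, 2L * j)]))
        }
        drop <- ids[seq_len(2L * k)]
        keep <- !(e$id %in% drop)
        pair <- pair[keep]
        e <- e[keep, , drop = FALSE]
        c2 <- c2 + k
      }
    }
  }
  list(reduced = multigraph(g$vertices, e), c1 = c1, c2 = as.integer(c2),
       removed = removed)
}

#' Enumerate the simple cycles of a simple graph
#'
#' Depth-first enumeration rooted at the canonically smallest vertex of each
#' cycle; cycles have length at least 3 (the input must be loop- and
#' multi-edge-free, e.g. the output of [reduce_loops_digons()]).
#'
#' @param g a simple [multigraph()].
#' @param cap maximum number of cycles to enumerate; exceeding it is an
#'   error (the count may be exponential in the number of vertices), never a
#'   silent truncation.
#' @return a list of integer edge-id vectors.
#' @export
enumerate_simple_cycles <- function(g, cap = 1e6) {
  e <- g$edges
  if (any(e$u == e$v)) abort("graph has loops; reduce first")
  pair <- if (nrow(e)) apply(cbind(e$u, e$v), 1, function(x)
    paste(sort(x), collapse = "~")) else character(0)
  if (anyDuplicated(pair)) abort("graph has parallel edges; reduce first")
  verts <- sort(g$vertices)
  vid <- stats::setNames(seq_along(verts), verts)
  nbrs <- lapply(stats::setNames(verts, verts), function(v) {
    rows <- which(e$u == v | e$v == v)
    data.frame(to = ifelse(e$u[rows] == v, e$v[rows], e$u[rows]),
               id = e$id[rows], stringsAsFactors = FALSE)
  })
  cycles <- list()
  count <- 0L
  for (root in verts) {
    r <- vid[[root]]
    # DFS over paths root, v1, ..., vk with vid(vi) > r; close when back at root
    dfs <- function(cur, path_ids, visited, first_step) {
      nb <- nbrs[[cur]]
      o <- order(nb$to)
      for (i in o) {
        nxt <- nb$to[i]
        eid <- nb$id[i]
        if (nxt == root) {
          if (length(path_ids) >= 2L && !first_step) {
            # dedupe the two traversal directions: require that the first
            # vertex after the root is smaller than the last one
            if (vid[[second_vertex]] < vid[[cur]]) {
              count <<- count + 1L
              if (count > cap) {
                abort("simple-cycle enumeration budget exceeded (cap = ", cap,
                      "); raise `cycle_cap`")
              }
              cycles[[count]] <<- c(path_ids, eid)
            }
          }
        } else if (vid[[nxt]] > r && !(nxt %in% visited)) {
          if (first_step) second_vertex <<- nxt
          dfs(nxt, c(path_ids, eid), c(visited, nxt), FALSE)
        }
      }
    }
    second_vertex <- root
    nb0 <- nbrs[[root]]
    for (i in order(nb0$to)) {
      nxt <- nb0$to[i]
      if (vid[[nxt]] > r) {
        second_vertex <- nxt
        dfs(nxt, nb0$id[i], c(root, nxt), FALSE)
      }
    }
  }
  lapply(cycles, function(x) sort(as.integer(x)))
}

# deterministic exact maximum set packing over cycle edge sets.
# Tie-break: the lexicographically smallest index set among maximum packings
# (include-first depth-first search in ascending index order).
max_set_packing <- function(cycles) {
  n <- length(cycles)
  if (!n) return(integer(0))
  best <- integer(0)
  chosen <- integer(0)
  recurse <- function(i, used) {
    if (length(chosen) + (n - i + 1L) <= length(best)) return()
    if (i > n) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    cyc <- cycles[[i]]
    if (!any(cyc %in% used)) {
      chosen <<- c(chosen, i)
      recurse(i + 1L, c(used, cyc))
      chosen <<- chosen[-length(chosen)]
    }
    recurse(i + 1L, used)
  }
  recurse(1L, integer(0))
  best
}

#' Exact maximum edge-disjoint cycle packing
#'
#' Strips loops and digons ([reduce_loops_digons()]), enumerates the simple
#' cycles of the reduced simple graph, and solves maximum set packing on
#' their edge sets exactly by deterministic branch-and-bound.
#'
#' @param g a [multigraph()].
#' @param config list; `cycle_cap` bounds the simple-cycle enumeration
#'   (default `1e6`; exceeding it errors).
#' @return a [cycle_packing()] of maximum size.
#' @examples
#' tri <- multigraph(c("a", "b", "c"),
#'                   data.frame(u = c("a", "b", "c"), v = c("b", "c", "a")))
#' length(mecp_exact(tri))
#' @export
mecp_exact <- function(g, config = list()) {
  cap <- config$cycle_cap %||% 1e6
  red <- reduce_loops_digons(g)
  simple_cycles <- enumerate_simple_cycles(red$reduced, cap = cap)
  picked <- max_set_packing(simple_cycles)
  cycle_packing(c(red$removed, simple_cycles[picked]), host = g)
}

#' Brute-force maximum cycle packing (test oracle)
#'
#' Enumerates every edge subset that forms a single cycle (connected and
#' 2-regular), then exhaustively searches all edge-disjoint families.
#' Deliberately independent of [mecp_exact()]: no reduction, no cycle DFS.
#'
#' @param g a [multigraph()].
#' @param max_edges refuse graphs with more edges than this (default 10).
#' @return a maximum [cycle_packing()].
#' @export
mecp_bruteforce <- function(g, max_edges = 10L) {
  m <- nrow(g$edges)
  if (m > max_edges) {
    abort("brute-force oracle limited to ", max_edges, " edges (graph has ",
          m, ")")
  }
  ids <- g$edges$id
  cycles <- list()
  if (m > 0L) {
    for (mask in seq_len(2^m - 1L)) {
      sel <- ids[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]
      if (is_cycle_edge_set(g, sel)) cycles[[length(cycles) + 1L]] <- sort(sel)
    }
  }
  n <- length(cycles)
  best <- integer(0)
  recurse <- function(i, chosen, used) {
    if (length(chosen) + (n - i + 1L) <= length(best)) return()
    if (i > n) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    if (!any(cycles[[i]] %in% used)) {
      recurse(i + 1L, c(chosen, i), c(used, cycles[[i]]))
    }
    recurse(i + 1L, chosen, used)
  }
  if (n) recurse(1L, integer(0), integer(0))
  cycle_packing(cycles[best], host = g)
}

#' Greedy loop/digon packing
#'
#' The packing behind the 3/2-approximation: all `c1(g)` loops plus `c2(g)`
#' digons, where `c2(g)` is the sum over vertex pairs of
#' `floor(multiplicity / 2)`. Runs in time linear in the number of edges and
#' never enumerates longer cycles.
#'
#' @param g a [multigraph()].
#' @return a [cycle_packing()] of loops and digons only.
#' @export
greedy_loops_digons_packing <- function(g) {
  red <- reduce_loops_digons(g)
  cycle_packing(red$removed, host = g)
}

#' Size of a maximum cycle packing
#' @param g a [multigraph()]; @param config passed to [mecp_exact()].
#' @return integer `c(g)`.
#' @export
mecp_size <- function(g, config = list()) length(mecp_exact(g, config))

#' Text report of a cycle packing
#'
#' One cycle per line: the ordered vertex walk, a separator, and the edge
#' ids, e.g. `"a b c | 1 4 7"`. A machine-readable key-value header gives
#' the counts.
#'
#' @param g the host [multigraph()]; @param packing a [cycle_packing()].
#' @param path optional file to write to.
#' @return the report lines, invisibly when writing.
#' @export
packing_report <- function(g, packing, path = NULL) {
  s <- packing_stats(packing)
  lines <- c(paste("size", s$size), paste("loops", s$n_loops),
             paste("digons", s$n_digons), paste("longer", s$n_longer))
  for (cyc in packing$cycles) {
    w <- cycle_walk(g, cyc)
    lines <- c(lines, paste(paste(w$vertices, collapse = " "), "|",
                            paste(w$edges, collapse = " ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
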