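# Genome capping: extend two general genomes (with telomeres) into circular
# sets of pairs whose junction graph is non-loop equal to a prescribed
# Eulerian extension J' of J(A,B,col). Every external adjacency is completed
# by an artificial extremity, the paths of the adjacency graph are closed
# into cycles, and the edges of J' - J are realized by added cycles (an
# Eulerian subgraph H) and added paths (the remaining forest F), whose open
# ends are merged color by color.

# find the edge ids of one cycle in an edge table, or NULL if it is a forest
find_cycle_ids <- function(e) {
  if (!nrow(e)) return(NULL)
  lp <- which(e$u == e$v)
  if (length(lp)) return(e$id[lp[1]])
  pr <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
  d <- which(duplicated(pr))
  if (length(d)) return(e$id[pr == pr[d[1]]][1:2])
  repeat {
    deg <- table(c(e$u, e$v))
    leaves <- names(deg)[deg <= 1L]
    if (!nrow(e) || !length(leaves)) break
    keep <- !(e$u %in% leaves | e$v %in% leaves)
    if (all(keep)) break
    e <- e[keep, , drop = FALSE]
  }
  if (!nrow(e)) return(NULL)
  # min degree 2: walk without immediate backtracking until a vertex repeats
  path_v <- e$u[1]
  path_e <- integer(0)
  cur <- e$u[1]
  prev_edge <- NA_integer_
  repeat {
    inc <- which((e$u == cur | e$v == cur) & !(e$id %in% prev_edge))
    i <- inc[1]
    nxt <- if (e$u[i] == cur) e$v[i] else e$u[i]
    path_e <- c(path_e, e$id[i])
    if (nxt %in% path_v) {
      pos <- match(nxt, path_v)
      return(path_e[pos:length(path_e)])
    }
    path_v <- c(path_v, nxt)
    cur <- nxt
    prev_edge <- e$id[i]
  }
}

# partition a forest's edges into paths by repeatedly walking from a leaf;
# returns a list of vertex (color) sequences
peel_paths <- function(e) {
  paths <- list()
  while (nrow(e)) {
    deg <- table(c(e$u, e$v))
    leaves <- sort(names(deg)[deg == 1L])
    if (!length(leaves)) abort("internal error: forest expected")
    cur <- leaves[1]
    verts <- cur
    repeat {
      inc <- which(e$u == cur | e$v == cur)
      if (!length(inc)) break
      i <- inc[order(e$id[inc])][1]
      nxt <- if (e$u[i] == cur) e$v[i] else e$u[i]
      verts <- c(verts, nxt)
      e <- e[-i, , drop = FALSE]
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- verts
  }
  paths
}

#' Cap two genomes into circular sets of pairs
#'
#' Builds genome extensions `A_hat`, `B_hat` (no external adjacencies) and a
#' coloring `col_hat` such that `J(A_hat, B_hat, col_hat)` has exactly the
#' same non-loop edges as an Eulerian extension `J'` of `J(A, B, col)`. By
#' default `J'` duplicates every junction edge left uncovered by a maximum
#' cycle packing; an arbitrary Eulerian `extension` (containing the edges of
#' `J` with their ids) may be supplied instead.
#'
#' Construction: every external adjacency of `A` or `B` is completed with an
#' artificial extremity (closing the adjacency-graph paths with cap pairs
#' whose colors copy the path ends); an Eulerian subgraph `H` of `J' - J` is
#' realized as added cycles, the remaining forest `F` as added paths; the
#' open path ends, all on the `A_hat` side and colored, are merged pairwise
#' within each color in creation order.
#'
#' @inheritParams mls_cost
#' @param packing a [cycle_packing()] of the junction graph (computed when
#'   `NULL` and no `extension` is given).
#' @param extension optional Eulerian [multigraph()] extending the junction
#'   graph.
#' @return an object of class `"capped_instance"`: fields `A_hat`, `B_hat`,
#'   `col_hat`, `telomeric_keys` (pairs of two artificial extremities),
#'   `artificial_range`, `extension` (the `J'` used), and the realized
#'   `h_cycles` / `f_paths` color sequences.
#' @examples
#' A <- genome(list(c(1, 2), 3, 4))
#' B <- genome(list(c(1, 3), 2, 4))
#' col <- coloring(A, c("1-2" = "u", "3" = "u", "4" = "v"))
#' cap <- cap_instance(A, B, col)
#' cap$A_hat$n_external # capped genomes are circular
#' @export
cap_instance <- function(A, B, col, packing = NULL, extension = NULL,
                         config = list()) {
  J <- build_junction_graph(A, B, col)
  if (is.null(extension)) {
    if (is.null(packing)) packing <- mecp_exact(J, config)
    covered <- unlist(packing$cycles, use.names = FALSE)
    Jp <- eulerian_extension(J, setdiff(J$edges$id, covered))
  } else {
    Jp <- extension
    rows <- match(J$edges$id, Jp$edges$id)
    if (anyNA(rows)) abort("extension must contain every junction edge id")
    same <- paste(pmin(Jp$edges$u[rows], Jp$edges$v[rows]),
                  pmax(Jp$edges$u[rows], Jp$edges$v[rows])) ==
      paste(pmin(J$edges$u, J$edges$v), pmax(J$edges$u, J$edges$v))
    if (!all(same)) abort("extension changes the endpoints of a junction edge")
  }
  if (!is_eulerian(Jp)) abort("the junction-graph extension is not Eulerian")

  nxt_label <- max(A$universe) + 1L
  alloc <- function() {
    l <- nxt_label
    nxt_label <<- nxt_label + 1L
    l
  }
  idxA <- extremity_index(A)
  a_pairs <- list()  # list of list(ext =, color =, telomeric =)
  b_pairs <- unname(B$adjacencies[lengths(B$adjacencies) == 2L])
  halves <- list()   # open A_hat ends: list(ext =, color =)
  for (k in names(A$adjacencies)) {
    a <- A$adjacencies[[k]]
    if (length(a) == 2L) {
      a_pairs[[length(a_pairs) + 1L]] <-
        list(ext = a, color = unname(col[[k]]), telomeric = FALSE)
    }
  }

  # close the adjacency-graph paths: cap every external adjacency
  ag <- build_adjacency_graph(A, B)
  for (comp in ag$components) {
    if (comp$type != "path") next
    for (endpt in unique(c(comp$vertices[1], comp$vertices[length(comp$vertices)]))) {
      side <- substr(endpt, 1L, 1L)
      key <- substring(endpt, 3L)
      ext <- adj_from_key(key)
      if (length(ext) != 1L) abort("internal error: path end is not external")
      if (side == "A") {
        c0 <- unname(col[[key]])
        cap <- alloc()
        a_pairs[[length(a_pairs) + 1L]] <-
          list(ext = c(ext, cap), color = c0, telomeric = FALSE)
        bj <- alloc()
        b_pairs[[length(b_pairs) + 1L]] <- c(cap, bj)
        halves[[length(halves) + 1L]] <- list(ext = bj, color = c0)
      } else {
        c0 <- unname(col[[idxA[[as.character(ext)]]]])
        capb <- alloc()
        b_pairs[[length(b_pairs) + 1L]] <- c(ext, capb)
        halves[[length(halves) + 1L]] <- list(ext = capb, color = c0)
      }
    }
  }

  # realize J' - J: cycles first (H), then the leftover forest F as paths
  added <- Jp$edges[!(Jp$edges$id %in% J$edges$id), , drop = FALSE]
  h_cycles <- list()
  repeat {
    cyc <- find_cycle_ids(added)
    if (is.null(cyc)) break
    w <- cycle_walk(multigraph(unique(c(added$u, added$v)), added), cyc)
    h_cycles[[length(h_cycles) + 1L]] <- w$vertices
    added <- added[!(added$id %in% cyc), , drop = FALSE]
  }
  for (colseq in h_cycles) {
    m <- length(colseq)
    left <- right <- integer(m)
    for (i in seq_len(m)) {
      left[i] <- alloc()
      right[i] <- alloc()
      a_pairs[[length(a_pairs) + 1L]] <-
        list(ext = c(left[i], right[i]), color = colseq[i], telomeric = TRUE)
    }
    for (i in seq_len(m)) {
      b_pairs[[length(b_pairs) + 1L]] <- c(right[i], left[i %% m + 1L])
    }
  }
  f_paths <- peel_paths(added)
  for (colseq in f_paths) {
    k <- length(colseq) - 1L
    left <- right <- rep(NA_integer_, k + 1L)
    for (i in 0:k) {
      if (i > 0L) left[i + 1L] <- alloc()
      if (i < k) right[i + 1L] <- alloc()
    }
    for (i in seq_len(max(k - 1L, 0L))) {
      a_pairs[[length(a_pairs) + 1L]] <-
        list(ext = c(left[i + 1L], right[i + 1L]), color = colseq[i + 1L],
             telomeric = TRUE)
    }
    for (i in 0:(k - 1L)) {
      b_pairs[[length(b_pairs) + 1L]] <- c(right[i + 1L], left[i + 2L])
    }
    halves[[length(halves) + 1L]] <- list(ext = right[1L], color = colseq[1L])
    halves[[length(halves) + 1L]] <- list(ext = left[k + 1L],
                                          color = colseq[k + 1L])
  }

  # merge open ends pairwise within each color, in creation order
  half_cols <- vapply(halves, `[[`, character(1), "color")
  for (colr in sort(unique(half_cols))) {
    hs <- halves[half_cols == colr]
    if (length(hs) %% 2L != 0L) {
      abort("internal error: odd number of open ends of color ", colr)
    }
    for (j in seq_len(length(hs) / 2L)) {
      a_pairs[[length(a_pairs) + 1L]] <-
        list(ext = c(hs[[2L * j - 1L]]$ext, hs[[2L * j]]$ext), color = colr,
             telomeric = TRUE)
    }
  }

  A_hat <- genome(lapply(a_pairs, `[[`, "ext"))
  B_hat <- genome(b_pairs)
  if (A_hat$n_external || B_hat$n_external) {
    abort("internal error: capped genomes still have telomeres")
  }
  if (!setequal(A_hat$universe, B_hat$universe)) {
    abort("internal error: capped universes differ")
  }
  col_hat <- coloring(A_hat, stats::setNames(
    vapply(a_pairs, `[[`, character(1), "color"),
    vapply(a_pairs, function(p) adj_key(p$ext), character(1))
  ))
  telomeric_keys <- vapply(
    a_pairs[vapply(a_pairs, `[[`, logical(1), "telomeric")],
    function(p) adj_key(p$ext), character(1)
  )

  # contract: the capped junction graph is non-loop equal to J'
  Jpp <- build_junction_graph(A_hat, B_hat, col_hat)
  nonloop <- function(g) {
    e <- g$edges[g$edges$u != g$edges$v, , drop = FALSE]
    sort(paste(pmin(e$u, e$v), pmax(e$u, e$v)))
  }
  if (!identical(nonloop(Jpp), nonloop(Jp))) {
    abort("internal error: capped junction graph is not non-loop equal to J'")
  }

  structure(
    list(A_hat = A_hat, B_hat = B_hat, col_hat = col_hat,
         telomeric_keys = unname(telomeric_keys),
         artificial_range = if (nxt_label > max(A$universe) + 1L)
           c(max(A$universe) + 1L, nxt_label - 1L) else integer(0),
         extension = Jp, h_cycles = h_cycles, f_paths = f_paths),
    class = "capped_instance"
  )
}

#' @export
print.capped_instance <- function(x, ...) {
  cat("capped instance:", length(x$A_hat$adjacencies), "pairs per genome,",
      length(x$telomeric_keys), "telomeric pair(s),",
      if (length(x$artificial_range))
        paste0("artificial extremities ", x$artificial_range[1], "..",
               x$artificial_range[2]) else "no artificial extremities", "\n")
  invisible(x)
}
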