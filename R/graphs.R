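# The two graphs of the comparison: the classical adjacency graph AG(A,B)
# (bipartite on the adjacencies of the two genomes, one edge per shared
# extremity) and the junction graph J(A,B,col) obtained by contracting every
# A-adjacency to its color. The junction graph carries one edge per internal
# adjacency of B and is the object on which 2-break sorting happens.

#' Build the adjacency graph of two genomes
#'
#' Vertices are the adjacencies of *A* and *B* (keys prefixed `"A:"` and
#' `"B:"`); between adjacencies `p` of *A* and `q` of *B* there are exactly
#' `|p` \eqn{\cap} `q|` edges, one per shared extremity; the edge id *is* the
#' shared extremity. Every vertex has degree at most 2, so every connected
#' component is a path or a cycle.
#'
#' @param A,B [genome()]s over the same extremity universe.
#' @return a list of class `"adjacency_graph"` with elements `graph` (a
#'   [multigraph()]) and `components` (a list; each component has `type`
#'   (`"path"`/`"cycle"`), `vertices` (ordered walk of vertex labels) and
#'   `edges` (ordered extremity ids along the walk)).
#' @examples
#' A <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' B <- genome(list(c(1, 4), c(3, 2), 5, 6))
#' ag <- build_adjacency_graph(A, B)
#' vapply(ag$components, `[[`, character(1), "type")
#' @export
build_adjacency_graph <- function(A, B) {
  if (!setequal(A$universe, B$universe)) {
    abort("genomes are over different extremity universes")
  }
  idxA <- extremity_index(A)
  idxB <- extremity_index(B)
  verts <- c(paste0("A:", names(A$adjacencies)), paste0("B:", names(B$adjacencies)))
  ext <- A$universe
  edges <- data.frame(
    id = ext,
    u = paste0("A:", unname(idxA[as.character(ext)])),
    v = paste0("B:", unname(idxB[as.character(ext)])),
    stringsAsFactors = FALSE
  )
  g <- multigraph(verts, edges)
  structure(list(graph = g, components = ag_components(g)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  types <- vapply(x$components, `[[`, character(1), "type")
  cat("adjacency graph:", nrow(x$graph$edges), "edges;",
      sum(types == "cycle"), "cycle(s),", sum(types == "path"), "path(s)\n")
  invisible(x)
}

# ordered path/cycle decomposition of a graph with max degree 2
ag_components <- function(g) {
  deg <- degrees(g)
  if (any(deg > 2L)) abort("adjacency graph vertex of degree > 2")
  inc <- lapply(stats::setNames(g$vertices, g$vertices), function(v)
    which(g$edges$u == v | g$edges$v == v))
  used <- logical(nrow(g$edges))
  comps <- list()
  walk_from <- function(start) {
    verts <- start
    eids <- integer(0)
    cur <- start
    repeat {
      nxt_edge <- setdiff(inc[[cur]], which(used))
      if (!length(nxt_edge)) break
      e <- nxt_edge[1]
      used[e] <<- TRUE
      eids <- c(eids, g$edges$id[e])
      cur <- if (g$edges$u[e] == cur) g$edges$v[e] else g$edges$u[e]
      if (cur == start) return(list(type = "cycle", vertices = verts, edges = eids))
      verts <- c(verts, cur)
    }
    list(type = "path", vertices = verts, edges = eids)
  }
  # paths first: start from degree-1 (or isolated) vertices
  for (v in g$vertices[deg <= 1L]) {
    if (any(!used[inc[[v]]]) || (deg[[v]] == 0L)) {
      if (deg[[v]] == 0L) {
        comps <- c(comps, list(list(type = "path", vertices = v, edges = integer(0))))
      } else if (!all(used[inc[[v]]])) {
        comps <- c(comps, list(walk_from(v)))
      }
    }
  }
  # remaining edges belong to cycles
  for (v in g$vertices) {
    if (any(!used[inc[[v]]])) comps <- c(comps, list(walk_from(v)))
  }
  comps
}

#' Build the junction graph of two genomes under a coloring
#'
#' Vertices are the colors of the palette; every *internal* adjacency
#' `\{a,b\}` of *B* contributes one edge joining the colors of the two
#' *A*-adjacencies containing `a` and `b` (a loop when they share a color,
#' including when they are the same adjacency). External adjacencies of *B*
#' contribute nothing; colors with no incident edge stay as isolated
#' vertices, keeping the palette stable.
#'
#' @param A,B [genome()]s over the same universe.
#' @param col a [coloring()] of `A`.
#' @return a [multigraph()] whose edge table carries a `b_key` column naming
#'   the *B*-adjacency behind each edge.
#' @examples
#' A <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' B <- genome(list(c(1, 4), c(3, 2), 5, 6))
#' col <- coloring(A, c("1-2" = "y", "3-4" = "z", "5" = "t", "6" = "x"))
#' build_junction_graph(A, B, col)
#' @export
build_junction_graph <- function(A, B, col) {
  if (!setequal(A$universe, B$universe)) {
    abort("genomes are over different extremity universes")
  }
  stopifnot_colored(A, col)
  idxA <- extremity_index(A)
  internals <- B$adjacencies[lengths(B$adjacencies) == 2L]
  palette <- attr(col, "palette") %||% sort(unique(unname(col)))
  if (!length(internals)) return(multigraph(palette))
  u <- vapply(internals, function(q) unname(col[[idxA[[as.character(q[1])]]]]),
              character(1))
  v <- vapply(internals, function(q) unname(col[[idxA[[as.character(q[2])]]]]),
              character(1))
  multigraph(palette, data.frame(
    id = seq_along(internals), u = u, v = v,
    b_key = names(internals), stringsAsFactors = FALSE
  ))
}

#' Eulerian extension by duplicating uncovered edges
#'
#' Adds one parallel duplicate of each listed edge. When `uncovered` is the
#' set of edges left out of a maximum edge-disjoint cycle packing of a
#' junction graph, the result is Eulerian: packed edges contribute even
#' degree everywhere and each uncovered edge is doubled. Added edges are
#' flagged `artificial`.
#'
#' @param g a [multigraph()].
#' @param uncovered integer vector of edge ids of `g` to duplicate.
#' @return the extended [multigraph()].
#' @export
eulerian_extension <- function(g, uncovered) {
  uncovered <- as.integer(uncovered)
  if (!length(uncovered)) return(g)
  rows <- match(uncovered, g$edges$id)
  if (anyNA(rows)) abort("uncovered edge id ", uncovered[is.na(rows)][1],
                         " not in graph")
  dup <- g$edges[rows, , drop = FALSE]
  dup$id <- max(g$edges$id) + seq_len(nrow(dup))
  dup$artificial <- TRUE
  if ("b_key" %in% names(dup)) dup$b_key <- NA_character_
  g$edges <- rbind(g$edges, dup)
  rownames(g$edges) <- NULL
  g
}
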