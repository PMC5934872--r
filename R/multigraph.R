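# A small labeled-edge undirected multigraph: loops and parallel edges are
# allowed, every edge carries a persistent integer id so that cycle packings
# and 2-break scenarios can reference specific parallel edges. A loop
# contributes 2 to the degree of its vertex.

#' Construct a multigraph
#'
#' @param vertices character vector of vertex labels.
#' @param edges a data frame with columns `u` and `v` (vertex labels; `u == v`
#'   is a loop) and optionally `id` (unique integers; generated when absent).
#' @return an object of class `"multigraph"` with fields `vertices` and
#'   `edges` (data frame `id`, `u`, `v`, `artificial`).
#' @export
multigraph <- function(vertices, edges = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) abort("duplicate vertex labels")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(id = integer(0), u = character(0), v = character(0),
                        artificial = logical(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$id)) edges$id <- seq_len(nrow(edges))
    if (is.null(edges$artificial)) edges$artificial <- FALSE
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    edges$id <- as.integer(edges$id)
    if (anyDuplicated(edges$id)) abort("edge ids must be unique")
    bad <- !(edges$u %in% vertices) | !(edges$v %in% vertices)
    if (any(bad)) abort("edge endpoint not among the vertices: ",
                        edges$u[bad][1], "-", edges$v[bad][1])
    extra <- setdiff(names(edges), c("id", "u", "v", "artificial"))
    edges <- edges[, c("id", "u", "v", "artificial", extra)]
    rownames(edges) <- NULL
  }
  structure(list(vertices = vertices, edges = edges), class = "multigraph")
}

#' Number of edges of a multigraph
#' @param g a [multigraph()].
#' @return integer edge count, counting parallel edges and loops.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Vertex degrees of a multigraph
#'
#' A loop adds 2 to its vertex's degree.
#' @param g a [multigraph()].
#' @return a named integer vector over all vertices.
#' @export
degrees <- function(g) {
  d <- stats::setNames(integer(length(g$vertices)), g$vertices)
  for (i in seq_len(nrow(g$edges))) {
    d[[g$edges$u[i]]] <- d[[g$edges$u[i]]] + 1L
    d[[g$edges$v[i]]] <- d[[g$edges$v[i]]] + 1L
  }
  d
}

#' Eulerian and terminal predicates
#'
#' A graph is Eulerian when every vertex degree is even; a junction graph is
#' *terminal* when every edge is a self-loop (the sorting target: every
#' remaining adjacency difference is monochromatic).
#'
#' @param g a [multigraph()].
#' @return a logical scalar.
#' @export
is_eulerian <- function(g) all(degrees(g) %% 2L == 0L)

#' @rdname is_eulerian
#' @export
is_terminal <- function(g) all(g$edges$u == g$edges$v)

#' @export
print.multigraph <- function(x, ...) {
  cat("multigraph:", length(x$vertices), "vertices,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(paste0("  [", x$edges$id, "] ", x$edges$u, " -- ", x$edges$v,
               ifelse(x$edges$artificial, " (artificial)", ""),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

# canonical text key of a multigraph state: sorted endpoint pairs
multigraph_key <- function(g) {
  if (!nrow(g$edges)) return("")
  uv <- t(apply(cbind(g$edges$u, g$edges$v), 1, sort))
  paste(sort(paste(uv[, 1], uv[, 2], sep = "~")), collapse = "|")
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$edges)) g$edges[, c("u", "v")] else
      data.frame(u = character(0), v = character(0)),
    directed = FALSE,
    vertices = data.frame(name = g$vertices)
  )
}

# connected components as lists of vertex labels (isolated vertices are their
# own components)
mg_components <- function(g) {
  comp <- igraph::components(as_igraph(g))
  split(names(comp$membership), comp$membership)
}

mg_is_connected <- function(g) {
  non_isolated <- unique(c(g$edges$u, g$edges$v))
  if (length(non_isolated) <= 1L) return(TRUE)
  sub <- multigraph(non_isolated, g$edges)
  igraph::is_connected(as_igraph(sub))
}

#' Apply a 2-break to a multigraph
#'
#' Replaces two edges `(x,y)` and `(z,t)` by a re-matching of their four
#' endpoints: either `(x,z),(y,t)` or `(x,t),(y,z)`. Edge count and vertex
#' degrees are preserved. The two replaced edges keep their ids, the first
#' consumed id carrying the first produced pair.
#'
#' @param g a [multigraph()].
#' @param tb a list with `consumed` (two edge ids) and `produced` (a list of
#'   two character vectors of length 2, the new endpoint pairs).
#' @return the rewritten [multigraph()].
#' @export
apply_two_break <- function(g, tb) {
  ids <- as.integer(tb$consumed)
  if (length(ids) != 2L || anyDuplicated(ids)) abort("a 2-break consumes two distinct edges")
  rows <- match(ids, g$edges$id)
  if (anyNA(rows)) abort("edge id ", ids[is.na(rows)][1], " not in graph")
  old <- c(g$edges$u[rows], g$edges$v[rows])
  new <- unlist(tb$produced, use.names = FALSE)
  if (length(new) != 4L || !identical(sort(old), sort(as.character(new)))) {
    abort("produced pairs must re-match the four consumed endpoints")
  }
  g$edges$u[rows] <- c(tb$produced[[1]][1], tb$produced[[2]][1])
  g$edges$v[rows] <- c(tb$produced[[1]][2], tb$produced[[2]][2])
  g
}

#' Two-break constructor
#' @param consumed two edge ids.
#' @param produced list of two endpoint pairs (character vectors of length 2).
#' @return a list of class `"two_break"`.
#' @export
two_break <- function(consumed, produced) {
  structure(list(consumed = as.integer(consumed), produced = produced),
            class = "two_break")
}

#' @export
format.two_break <- function(x, ...) {
  paste0("(", paste(x$produced[[1]], collapse = ","), "),(",
         paste(x$produced[[2]], collapse = ","), ") from edges [",
         paste(x$consumed, collapse = ","), "]")
}

#' Write / read a multigraph as an edge-list text file
#'
#' One edge per line, `u v id`; loops appear as `u u id`. Isolated vertices
#' are written as a leading comment line so that round trips preserve them.
#'
#' @param g a [multigraph()].
#' @param path file path.
#' @export
write_multigraph <- function(g, path) {
  iso <- setdiff(g$vertices, c(g$edges$u, g$edges$v))
  header <- if (length(iso)) paste("# isolated:", paste(iso, collapse = " ")) else character(0)
  lines <- c(header, sprintf("%s %s %d", g$edges$u, g$edges$v, g$edges$id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_multigraph
#' @return `read_multigraph()` returns the parsed [multigraph()].
#' @export
read_multigraph <- function(path) {
  lines <- trimws(readLines(path))
  iso <- character(0)
  iso_lines <- grep("^# isolated:", lines, value = TRUE)
  if (length(iso_lines)) {
    iso <- strsplit(sub("^# isolated:\\s*", "", iso_lines[1]), "\\s+")[[1]]
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(multigraph(iso))
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) abort("line ", bad[1], ": expected 'u v id'")
  edges <- data.frame(
    u = vapply(parts, `[[`, character(1), 1L),
    v = vapply(parts, `[[`, character(1), 2L),
    id = as.integer(vapply(parts, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(edges$id)) abort("non-integer edge id")
  multigraph(union(iso, unique(c(edges$u, edges$v))), edges)
}

# Deterministic closed-walk order of a cycle given by edge ids: start at the
# smallest vertex label, prefer the smallest edge id. Returns the vertex
# sequence v1..vl and edge ids e1..el with ei joining vi and v(i mod l)+1.
cycle_walk <- function(g, ids) {
  rows <- match(as.integer(ids), g$edges$id)
  if (anyNA(rows)) abort("cycle references unknown edge ids")
  e <- g$edges[rows, , drop = FALSE]
  if (nrow(e) == 1L) {
    if (e$u[1] != e$v[1]) abort("single edge is not a loop")
    return(list(vertices = e$u[1], edges = e$id[1]))
  }
  start <- min(c(e$u, e$v))
  used <- logical(nrow(e))
  verts <- start
  eids <- integer(0)
  cur <- start
  repeat {
    cand <- which(!used & (e$u == cur | e$v == cur))
    if (!length(cand)) abort("edge set is not a single closed walk")
    i <- cand[order(e$id[cand])][1]
    used[i] <- TRUE
    eids <- c(eids, e$id[i])
    cur <- if (e$u[i] == cur) e$v[i] else e$u[i]
    if (cur == start && all(used)) break
    if (cur == start && !all(used)) abort("edge set revisits its start early")
    verts <- c(verts, cur)
  }
  list(vertices = verts, edges = eids)
}
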