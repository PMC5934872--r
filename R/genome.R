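#' @keywords internal
"_PACKAGE"

# ---- Adjacency and genome containers -----------------------------------------

#' Canonical text key of an adjacency
#'
#' Adjacencies are unordered sets of one or two extremity labels, so they are
#' keyed by their sorted content. Colorings and move validation key on these
#' strings, never on object identity.
#'
#' @param adj integer vector of length 1 (external adjacency, a telomere) or 2
#'   (internal adjacency).
#' @return a character scalar such as `"3-7"` or `"5"`.
#' @export
adj_key <- function(adj) paste(sort(as.integer(adj)), collapse = "-")

adj_from_key <- function(key) lapply(strsplit(key, "-", fixed = TRUE),
                                     function(x) as.integer(x))[[1]]

new_adjacency <- function(ext) {
  ext <- as.integer(ext)
  if (!length(ext) %in% c(1L, 2L) || anyNA(ext) || any(ext < 1L)) {
    abort("an adjacency is a set of 1 or 2 positive extremity labels")
  }
  if (length(ext) == 2L && ext[1] == ext[2]) {
    abort("adjacency extremities must be distinct: {", ext[1], ",", ext[2], "}")
  }
  sort(ext)
}

#' Construct a genome from a set of adjacencies
#'
#' A genome is a set of adjacencies covering every extremity of its universe
#' exactly once: internal adjacencies are unordered pairs of extremities
#' neighboring on a chromosome, external adjacencies are single extremities at
#' the two ends of a linear chromosome.
#'
#' @param adjacencies a list of integer vectors, each of length 1 or 2.
#' @return an object of class `"genome"`: a list with element `adjacencies`
#'   (a named list keyed by [adj_key()]), plus `universe`, `n_internal` and
#'   `n_external` fields.
#' @examples
#' # the three-block linear chromosome A B -C, extremities renamed 1..6
#' g <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' g$n_internal
#' @export
genome <- function(adjacencies) {
  adjacencies <- lapply(adjacencies, new_adjacency)
  ext <- unlist(adjacencies, use.names = FALSE)
  if (anyDuplicated(ext)) {
    dup <- ext[duplicated(ext)][1]
    abort("extremity ", dup, " occurs in more than one adjacency")
  }
  keys <- vapply(adjacencies, adj_key, character(1))
  names(adjacencies) <- keys
  sizes <- lengths(adjacencies)
  structure(
    list(
      adjacencies = adjacencies[order(vapply(adjacencies, min, integer(1)))],
      universe = sort(ext),
      n_internal = sum(sizes == 2L),
      n_external = sum(sizes == 1L)
    ),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", x$n_internal, "internal /", x$n_external,
      "external adjacencies over", length(x$universe), "extremities\n")
  cat(" {", paste(vapply(x$adjacencies, function(a)
    paste0("{", paste(a, collapse = ","), "}"), character(1)), collapse = ", "),
    "}\n")
  invisible(x)
}

#' @export
format.genome <- function(x, ...) {
  paste(vapply(x$adjacencies, function(a)
    paste0("{", paste(a, collapse = ","), "}"), character(1)), collapse = ", ")
}

genomes_equal <- function(a, b) {
  setequal(names(a$adjacencies), names(b$adjacencies))
}

# which adjacency of `g` contains extremity `e` (key)
adj_of <- function(g, e) {
  for (k in names(g$adjacencies)) if (e %in% g$adjacencies[[k]]) return(k)
  abort("extremity ", e, " not in genome")
}

# fast lookup table extremity -> adjacency key
extremity_index <- function(g) {
  keys <- rep(names(g$adjacencies), lengths(g$adjacencies))
  stats::setNames(keys, unlist(g$adjacencies, use.names = FALSE))
}

# ---- Colorings ---------------------------------------------------------------

#' Color the adjacencies of a genome
#'
#' A coloring is a total map from the adjacencies of one genome (genome *A* by
#' convention) to a set of color labels; a DCJ acting on same-colored
#' adjacencies is *local* (cost 0), otherwise *non-local* (cost 1).
#'
#' @param g a [genome()].
#' @param colors a character vector of color labels, either unnamed and in the
#'   order of `g$adjacencies`, or named by adjacency keys (see [adj_key()]).
#' @return a named character vector of class `"coloring"` keyed by adjacency
#'   key, with a `palette` attribute (the sorted set of colors in use).
#' @examples
#' A <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' col <- coloring(A, c("1-2" = "y", "3-4" = "z", "5" = "t", "6" = "x"))
#' @export
coloring <- function(g, colors) {
  nm <- names(colors)
  colors <- as.character(colors)
  names(colors) <- nm
  keys <- names(g$adjacencies)
  if (is.null(names(colors))) {
    if (length(colors) != length(keys)) {
      abort("unnamed color vector must have one color per adjacency")
    }
    names(colors) <- keys
  }
  missing <- setdiff(keys, names(colors))
  if (length(missing)) {
    abort("coloring is not total: no color for adjacency ", missing[1])
  }
  extra <- setdiff(names(colors), keys)
  if (length(extra)) {
    abort("coloring mentions adjacency ", extra[1], " absent from the genome")
  }
  colors <- colors[keys]
  structure(colors, palette = sort(unique(unname(colors))), class = "coloring")
}

#' @export
print.coloring <- function(x, ...) {
  cat("coloring over palette {", paste(attr(x, "palette"), collapse = ", "),
      "}\n")
  for (k in names(x)) cat(" ", k, "->", x[[k]], "\n")
  invisible(x)
}

# re-key a coloring after the genome changed (same keys assumed present)
stopifnot_colored <- function(g, col) {
  missing <- setdiff(names(g$adjacencies), names(col))
  if (length(missing)) {
    abort("adjacency ", missing[1], " has no color in the current coloring")
  }
  invisible(TRUE)
}
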