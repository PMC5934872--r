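# Block-level genome representation and the extremity renaming that turns it
# into a plain set of adjacencies.

#' Parse a GRIMM-style block genome
#'
#' One chromosome per line, blocks as signed integers or signed names
#' (`-B` reads block B right-to-left), terminated by `$` (linear) or `@`
#' (circular). Lines starting with `#` are comments; a `>` line names the
#' genome and is otherwise ignored.
#'
#' @param text a character scalar (possibly multi-line) or vector of lines.
#' @return an object of class `"block_genome"`: a list of chromosomes, each a
#'   list with `blocks` (character), `signs` (+1/-1) and `circular` (logical).
#' @examples
#' parse_block_genome("1 -2 3 $")
#' @export
parse_block_genome <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  if (!length(lines)) abort("no chromosome lines found")
  chroms <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tokens <- strsplit(lines[i], "[[:space:]]+")[[1]]
    term <- tokens[length(tokens)]
    if (!term %in% c("$", "@")) {
      abort("line ", i, ": chromosome must end with '$' (linear) or '@' (circular)")
    }
    tokens <- tokens[-length(tokens)]
    if (!length(tokens)) abort("line ", i, ": empty chromosome")
    if (any(tokens %in% c("$", "@"))) {
      abort("line ", i, ": unexpected terminator inside chromosome")
    }
    signs <- ifelse(startsWith(tokens, "-"), -1L, 1L)
    blocks <- sub("^[+-]", "", tokens)
    if (any(!nzchar(blocks))) abort("line ", i, ": unreadable block token")
    chroms[[i]] <- list(blocks = blocks, signs = signs, circular = term == "@")
  }
  all_blocks <- unlist(lapply(chroms, `[[`, "blocks"), use.names = FALSE)
  if (anyDuplicated(all_blocks)) {
    abort("duplicate block: ", all_blocks[duplicated(all_blocks)][1])
  }
  structure(chroms, class = "block_genome")
}

#' @export
print.block_genome <- function(x, ...) {
  cat("block genome,", length(x), "chromosome(s)\n")
  for (ch in x) {
    cat(" ", paste0(ifelse(ch$signs < 0, "-", ""), ch$blocks, collapse = " "),
        if (ch$circular) "@" else "$", "\n")
  }
  invisible(x)
}

# canonical block order shared by the two genomes being compared: numeric if
# every block name is numeric, lexicographic otherwise
block_order <- function(blocks) {
  num <- suppressWarnings(as.numeric(blocks))
  if (!anyNA(num)) blocks[order(num)] else sort(blocks)
}

#' Extremity labels of the blocks of a block genome
#'
#' Block number *i* (in canonical block order) gets tail extremity `2i-1` and
#' head extremity `2i`.
#'
#' @param g a [parse_block_genome()] result, or anything with the same shape.
#' @return a data frame with columns `block`, `end` (`"t"`/`"h"`) and
#'   `extremity`.
#' @export
extremity_map <- function(g) {
  blocks <- block_order(unlist(lapply(g, `[[`, "blocks"), use.names = FALSE))
  data.frame(
    block = rep(blocks, each = 2L),
    end = rep(c("t", "h"), length(blocks)),
    extremity = seq_len(2L * length(blocks)),
    stringsAsFactors = FALSE
  )
}

#' Convert a block genome to its adjacency set
#'
#' Renames block extremities to the integers `1..2n` (tail of block *i* is
#' `2i-1`, its head `2i`) and reads off the adjacency set: consecutive blocks
#' on a chromosome yield internal adjacencies, the two ends of a linear
#' chromosome yield external adjacencies, and a circular chromosome closes on
#' itself.
#'
#' @param g a `"block_genome"`.
#' @return a list with elements `genome` (a [genome()]) and `map` (the
#'   [extremity_map()] used, for reporting scenarios in block terms).
#' @examples
#' ab <- block_to_adjacency(parse_block_genome("1 2 -3 $"))
#' ab$genome
#' @export
block_to_adjacency <- function(g) {
  map <- extremity_map(g)
  lab <- stats::setNames(map$extremity, paste(map$block, map$end))
  adjacencies <- list()
  for (ch in g) {
    # oriented extremity sequence: forward block contributes (tail, head)
    seq_ext <- integer(0)
    for (j in seq_along(ch$blocks)) {
      ends <- if (ch$signs[j] > 0) c("t", "h") else c("h", "t")
      seq_ext <- c(seq_ext, lab[paste(ch$blocks[j], ends)])
    }
    k <- length(seq_ext)
    if (k >= 4L) {
      inner_left <- seq_ext[seq(2L, k - 1L, by = 2L)]
      inner_right <- seq_ext[seq(3L, k, by = 2L)]
      adjacencies <- c(adjacencies, Map(c, inner_left, inner_right))
    }
    if (ch$circular) {
      adjacencies <- c(adjacencies, list(c(seq_ext[k], seq_ext[1])))
    } else {
      adjacencies <- c(adjacencies, list(seq_ext[1]), list(seq_ext[k]))
    }
  }
  list(genome = genome(adjacencies), map = map)
}

#' Reconstruct chromosomes from an adjacency set
#'
#' Inverse of [block_to_adjacency()] up to chromosome order, reading
#' direction and circular rotation: walks the adjacency set block by block.
#'
#' @param g a [genome()] whose universe is `1..2n`.
#' @param map the extremity map of [block_to_adjacency()].
#' @return a `"block_genome"`.
#' @export
adjacency_to_block <- function(g, map) {
  if (!setequal(g$universe, map$extremity)) {
    abort("genome universe does not match the extremity map")
  }
  block_of <- stats::setNames(map$block, map$extremity)
  other_end <- stats::setNames(
    ifelse(map$extremity %% 2L == 1L, map$extremity + 1L, map$extremity - 1L),
    map$extremity
  )
  idx <- extremity_index(g)
  seen <- character(0)
  chroms <- list()
  walk <- function(start_ext) {
    blocks <- character(0)
    signs <- integer(0)
    e <- start_ext
    repeat {
      b <- block_of[[as.character(e)]]
      blocks <- c(blocks, b)
      signs <- c(signs, if (e %% 2L == 1L) 1L else -1L) # entered at tail => forward
      seen <<- c(seen, b)
      out <- other_end[[as.character(e)]]
      k <- idx[[as.character(out)]]
      adj <- g$adjacencies[[k]]
      if (length(adj) == 1L) return(list(blocks = blocks, signs = signs, circular = FALSE))
      nxt <- setdiff(adj, out)
      if (block_of[[as.character(nxt)]] %in% seen) {
        return(list(blocks = blocks, signs = signs, circular = TRUE))
      }
      e <- nxt
    }
  }
  # linear chromosomes first: start at each unused external adjacency
  externals <- unlist(g$adjacencies[lengths(g$adjacencies) == 1L], use.names = FALSE)
  for (e in externals) {
    if (block_of[[as.character(e)]] %in% seen) next
    chroms <- c(chroms, list(walk(e)))
  }
  # remaining blocks sit on circular chromosomes
  remaining <- setdiff(unique(map$block), seen)
  while (length(remaining)) {
    start <- map$extremity[map$block == remaining[1] & map$end == "t"]
    chroms <- c(chroms, list(walk(start)))
    remaining <- setdiff(remaining, seen)
  }
  structure(chroms, class = "block_genome")
}

#' Co-rename two genomes to canonical form
#'
#' Relabels the shared extremity universe so that genome *A* becomes
#' `{{1,2}, {3,4}, ..., {2n-1,2n}, {2n+1}, ..., {2n+2m}}` (internal
#' adjacencies ordered by their smallest original member, then the external
#' adjacencies in increasing order) and applies the same bijection to *B*.
#'
#' @param A,B two [genome()]s over the same extremity universe.
#' @return a list with the renamed `A` and `B`, the renaming `map`
#'   (old label -> new label) and its `inverse`.
#' @examples
#' A <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' B <- genome(list(c(1, 4), c(3, 2), 5, 6))
#' co_rename(A, B)$B
#' @export
co_rename <- function(A, B) {
  if (!setequal(A$universe, B$universe)) {
    abort("genomes are over different extremity universes")
  }
  internals <- A$adjacencies[lengths(A$adjacencies) == 2L]
  internals <- internals[order(vapply(internals, min, integer(1)))]
  externals <- sort(unlist(A$adjacencies[lengths(A$adjacencies) == 1L],
                           use.names = FALSE))
  old <- c(unlist(internals, use.names = FALSE), externals)
  map <- stats::setNames(seq_along(old), old)
  relab <- function(g) genome(lapply(g$adjacencies, function(a)
    unname(map[as.character(a)])))
  list(
    A = relab(A),
    B = relab(B),
    map = map,
    inverse = stats::setNames(as.integer(names(map)), map)
  )
}
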