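# Colored DCJ moves: the four rewrite templates, their costs, and scenario
# replay. A move is *local* (cost 0) when the colors it consumes agree -- for a
# split, when the freely chosen color of the second product equals the color
# of the consumed adjacency -- and *non-local* (cost 1) otherwise.

#' Construct a colored DCJ move
#'
#' The four templates, writing `(\{a,b\}|x)` for adjacency `\{a,b\}` of color
#' `x`, are:
#' \itemize{
#'   \item pair-pair: `({a,b}|x),({c,d}|y) -> ({a,c}|x),({b,d}|y)` (or the
#'     colors attributed the other way around),
#'   \item pair-telomere: `({a,b}|x),({c}|y) -> ({a,c}|x),({b}|y)` (or swapped),
#'   \item split: `({a,b}|x) -> ({a}|x),({b}|z)` with any color `z`,
#'   \item join: `({a}|x),({b}|y) -> ({a,b}|x)` (or color `y`).
#' }
#' The produced-color attribution is recorded explicitly in the move rather
#' than being left implicit.
#'
#' @param consumed list of 1 or 2 adjacencies (integer vectors) to consume.
#' @param produced list of 1 or 2 adjacencies produced.
#' @param consumed_colors character vector of colors of the consumed
#'   adjacencies, in the same order.
#' @param produced_colors character vector of colors attributed to the
#'   produced adjacencies, in the same order.
#' @return an object of class `"dcj_move"`.
#' @export
dcj_move <- function(consumed, produced, consumed_colors, produced_colors) {
  consumed <- lapply(consumed, new_adjacency)
  produced <- lapply(produced, new_adjacency)
  consumed_colors <- as.character(consumed_colors)
  produced_colors <- as.character(produced_colors)
  if (length(consumed) != length(consumed_colors) ||
      length(produced) != length(produced_colors)) {
    abort("each consumed/produced adjacency needs exactly one color")
  }
  mv <- structure(
    list(consumed = consumed, produced = produced,
         consumed_colors = consumed_colors,
         produced_colors = produced_colors),
    class = "dcj_move"
  )
  mv$kind <- move_kind(mv)
  mv$cost <- move_cost(mv)
  mv
}

# classify against the four rewrite templates; abort if none matches
move_kind <- function(mv) {
  cs <- lengths(mv$consumed)
  ps <- lengths(mv$produced)
  ext_in <- sort(unlist(mv$consumed, use.names = FALSE))
  ext_out <- sort(unlist(mv$produced, use.names = FALSE))
  if (!identical(ext_in, ext_out)) {
    abort("move does not conserve extremities: consumes {",
          paste(ext_in, collapse = ","), "} but produces {",
          paste(ext_out, collapse = ","), "}")
  }
  if (anyDuplicated(ext_in)) abort("move consumes an extremity twice")
  kind <- if (length(cs) == 2L && all(cs == 2L) && length(ps) == 2L && all(ps == 2L)) {
    "pair-pair"
  } else if (length(cs) == 2L && setequal(cs, c(1L, 2L)) &&
             length(ps) == 2L && setequal(ps, c(1L, 2L))) {
    "pair-telomere"
  } else if (length(cs) == 1L && cs == 2L && length(ps) == 2L && all(ps == 1L)) {
    "split"
  } else if (length(cs) == 2L && all(cs == 1L) && length(ps) == 1L && ps == 2L) {
    "join"
  } else {
    abort("consumed/produced adjacencies match none of the four DCJ templates")
  }
  # a rewrite must actually recombine: no produced adjacency may equal a
  # consumed one in the two-by-two templates (that would be the identity)
  if (kind %in% c("pair-pair", "pair-telomere")) {
    ck <- vapply(mv$consumed, adj_key, character(1))
    pk <- vapply(mv$produced, adj_key, character(1))
    if (any(pk %in% ck)) abort("produced adjacencies must differ from consumed ones")
  }
  # color attribution: every produced color must be traceable to a consumed
  # color, except for the free color z of a split
  if (kind == "split") {
    if (!mv$consumed_colors[1] %in% mv$produced_colors) {
      abort("a split must keep the consumed color on one product")
    }
  } else if (kind == "join") {
    if (!mv$produced_colors[1] %in% mv$consumed_colors) {
      abort("a join product takes one of the two consumed colors")
    }
  } else {
    if (!identical(sort(mv$produced_colors), sort(mv$consumed_colors))) {
      abort("produced colors must be the consumed colors, in either attribution")
    }
  }
  kind
}

move_cost <- function(mv) {
  if (mv$kind == "split") {
    x <- mv$consumed_colors[1]
    as.integer(!all(mv$produced_colors == x))
  } else {
    as.integer(mv$consumed_colors[1] != mv$consumed_colors[2])
  }
}

#' @export
format.dcj_move <- function(x, ...) {
  side <- function(adjs, cols) paste(mapply(function(a, co)
    paste0("(", paste(a, collapse = ","), "|", co, ")"), adjs, cols),
    collapse = ",")
  paste0(side(x$consumed, x$consumed_colors), " -> ",
         side(x$produced, x$produced_colors), " cost=", x$cost)
}

#' @export
print.dcj_move <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Apply a colored DCJ move to a genome
#'
#' Validates that the consumed adjacencies (with their colors) are present,
#' that the rewrite matches one of the four templates, and returns the new
#' genome, the new coloring, and the move's cost.
#'
#' @param g a [genome()].
#' @param col a [coloring()] of `g`.
#' @param mv a [dcj_move()].
#' @return a list with elements `genome`, `coloring` and `cost` (0 or 1).
#' @examples
#' A <- genome(list(c(1, 2), c(3, 4), 5, 6))
#' col <- coloring(A, c("1-2" = "y", "3-4" = "z", "5" = "t", "6" = "x"))
#' mv <- dcj_move(list(c(1, 2), c(3, 4)), list(c(1, 4), c(3, 2)),
#'                c("y", "z"), c("y", "z"))
#' apply_move(A, col, mv)$cost
#' @export
apply_move <- function(g, col, mv) {
  stopifnot_colored(g, col)
  ck <- vapply(mv$consumed, adj_key, character(1))
  for (i in seq_along(ck)) {
    if (!ck[i] %in% names(g$adjacencies)) {
      abort("consumed adjacency {", gsub("-", ",", ck[i]), "} absent from genome")
    }
    if (col[[ck[i]]] != mv$consumed_colors[i]) {
      abort("adjacency {", gsub("-", ",", ck[i]), "} has color ", col[[ck[i]]],
            ", move expects ", mv$consumed_colors[i])
    }
  }
  pk <- vapply(mv$produced, adj_key, character(1))
  adjs <- g$adjacencies
  adjs[ck] <- NULL
  new_cols <- col[setdiff(names(adjs), pk)]
  adjs[pk] <- mv$produced
  g2 <- genome(unname(adjs))
  cols2 <- c(stats::setNames(as.character(new_cols), names(new_cols)),
             stats::setNames(mv$produced_colors, pk))
  list(genome = g2, coloring = coloring(g2, cols2), cost = mv$cost)
}

#' Build a DCJ scenario from a list of moves
#' @param moves a list of [dcj_move()]s.
#' @return an object of class `"dcj_scenario"`.
#' @export
dcj_scenario <- function(moves = list()) {
  stopifnot(all(vapply(moves, inherits, logical(1), "dcj_move")))
  structure(list(moves = moves), class = "dcj_scenario")
}

#' @export
length.dcj_scenario <- function(x) length(x$moves)

#' @export
print.dcj_scenario <- function(x, ...) {
  cat("DCJ scenario,", length(x$moves), "move(s), cost",
      sum(vapply(x$moves, `[[`, integer(1), "cost")), "\n")
  for (m in x$moves) cat(" ", format(m), "\n")
  invisible(x)
}

#' Replay a DCJ scenario and account its cost
#'
#' Applies the moves of a scenario in order, validating each against the
#' current state; the total cost equals the number of non-local moves.
#'
#' @param g a [genome()]; @param col a [coloring()] of `g`;
#' @param scenario a [dcj_scenario()].
#' @return a list with `genome`, `coloring`, `total_cost`, `n_nonlocal`,
#'   `n_local`.
#' @export
replay <- function(g, col, scenario) {
  total <- 0L
  nonlocal <- 0L
  for (i in seq_along(scenario$moves)) {
    step <- tryCatch(
      apply_move(g, col, scenario$moves[[i]]),
      error = function(e) abort("move ", i, " is not applicable: ",
                                conditionMessage(e))
    )
    g <- step$genome
    col <- step$coloring
    total <- total + step$cost
    nonlocal <- nonlocal + (step$cost > 0L)
  }
  list(genome = g, coloring = col, total_cost = total,
       n_nonlocal = nonlocal, n_local = length(scenario$moves) - nonlocal)
}
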