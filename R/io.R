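# Plain-text readers and writers: the adjacency-set genome format (which
# doubles as a combined genome + coloring file), the scenario report, and
# the Hi-C inputs (bin table, dense matrix, 3-column contact list, BED
# breakpoint regions). GRIMM-style block genomes are parsed by
# parse_block_genome().

is_int_token <- function(x) grepl("^[0-9]+$", x)

#' Read an adjacency-set genome file
#'
#' One adjacency per line: `a b` (internal) or `a` (external), extremities
#' as positive integers, with an optional trailing color label (any
#' non-integer token, or the third token of an internal adjacency). Either
#' every adjacency carries a color or none does. `#` starts a comment.
#'
#' @param path file path.
#' @return a list with `genome` (a [genome()]) and `coloring` (a
#'   [coloring()], or `NULL` when the file carries no colors).
#' @export
read_genome_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(path, ": no adjacencies found")
  adjs <- vector("list", length(lines))
  cols <- rep(NA_character_, length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    ints <- is_int_token(tok)
    if (length(tok) == 1L && ints[1]) {
      adjs[[i]] <- as.integer(tok[1])
    } else if (length(tok) == 2L && all(ints)) {
      adjs[[i]] <- as.integer(tok)
    } else if (length(tok) == 2L && ints[1] && !ints[2]) {
      adjs[[i]] <- as.integer(tok[1])
      cols[i] <- tok[2]
    } else if (length(tok) == 3L && all(ints[1:2])) {
      adjs[[i]] <- as.integer(tok[1:2])
      cols[i] <- tok[3]
    } else {
      abort(path, ": line ", i, ": expected 'a', 'a b', 'a color' or 'a b color'")
    }
  }
  g <- genome(adjs)
  colored <- !is.na(cols)
  if (any(colored) && !all(colored)) {
    abort(path, ": line ", which(!colored)[1], ": missing color label")
  }
  col <- NULL
  if (all(colored)) {
    col <- coloring(g, stats::setNames(
      cols, vapply(adjs, adj_key, character(1))))
  }
  list(genome = g, coloring = col)
}

#' @rdname read_genome_file
#' @param g a [genome()]; @param col optional [coloring()] written as a
#'   trailing token.
#' @export
write_genome_file <- function(g, path, col = NULL) {
  lines <- vapply(names(g$adjacencies), function(k) {
    a <- paste(g$adjacencies[[k]], collapse = " ")
    if (is.null(col)) a else paste(a, col[[k]])
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a scenario report
#'
#' One move per line in the form
#' `({a,b}|x),({c,d}|y) -> ({a,c}|x),({b,d}|y) cost=1`, telomeres written as
#' `({a}|x)`.
#'
#' @param scenario a [dcj_scenario()]; @param path file path.
#' @export
write_scenario <- function(scenario, path) {
  writeLines(vapply(scenario$moves, format, character(1)), path)
  invisible(path)
}

#' Read Hi-C inputs
#'
#' `read_hic_dense()` reads a bin table TSV (columns `chrom`, `start`,
#' `end`, optional `bin`) plus a dense, headerless numeric matrix TSV.
#' `read_hic_contacts()` reads the bin table plus a 3-column contact list
#' (`bin_i`, `bin_j`, `count`); unlisted pairs are 0 and the matrix is
#' symmetrized.
#'
#' @param bins_path,matrix_path,contacts_path file paths.
#' @return a [hic_dataset()].
#' @export
read_hic_dense <- function(bins_path, matrix_path) {
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  H <- as.matrix(utils::read.table(matrix_path, header = FALSE, sep = "\t"))
  dimnames(H) <- NULL
  if (!is.numeric(H)) abort(matrix_path, ": matrix entries must be numeric")
  hic_dataset(bins, H)
}

#' @rdname read_hic_dense
#' @export
read_hic_contacts <- function(bins_path, contacts_path) {
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  cl <- utils::read.table(contacts_path, header = FALSE, sep = "\t")
  if (ncol(cl) != 3L) abort(contacts_path, ": expected 3 columns (i, j, count)")
  n <- nrow(bins)
  if (any(cl[[1]] < 1L | cl[[1]] > n | cl[[2]] < 1L | cl[[2]] > n)) {
    abort(contacts_path, ": bin index out of range 1..", n)
  }
  H <- matrix(0, n, n)
  for (r in seq_len(nrow(cl))) {
    i <- cl[[1]][r]
    j <- cl[[2]][r]
    H[i, j] <- H[i, j] + cl[[3]][r]
    if (i != j) H[j, i] <- H[j, i] + cl[[3]][r]
  }
  hic_dataset(bins, H)
}

#' Read breakpoint regions from a BED file
#'
#' Four columns, tab-separated, no header: `chrom`, `start`, `end`, `name`,
#' the name being the adjacency key (see [adj_key()]).
#'
#' @param path file path.
#' @return a data frame with columns `key`, `chrom`, `start`, `end` suitable
#'   for [adjacency_similarity()].
#' @export
read_breakpoints_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) abort(path, ": expected 4 BED columns (chrom, start, end, name)")
  data.frame(key = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
             start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]),
             stringsAsFactors = FALSE)
}
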