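# Hi-C contact maps: container, the two normalizations (expected-at-distance
# for intra-chromosomal contacts, coverage product for inter-chromosomal
# ones), and the adjacency-similarity lookup used to color breakpoint
# regions by spatial proximity.

#' Construct a binned Hi-C dataset
#'
#' @param bins a data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open genomic intervals, fixed width within a chromosome) and
#'   optionally `bin` (1-based row index into the matrix; defaults to row
#'   order).
#' @param H a symmetric nonnegative contact matrix, one row/column per bin.
#' @return an object of class `"hic_dataset"` with fields `bins`, `raw`, and
#'   after normalization `intra`, `inter` and `average_at_dist`.
#' @export
hic_dataset <- function(bins, H) {
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(bins))) {
    abort("bins need columns chrom, start, end")
  }
  if (is.null(bins$bin)) bins$bin <- seq_len(nrow(bins))
  bins <- bins[order(bins$bin), , drop = FALSE]
  if (!identical(as.integer(bins$bin), seq_len(nrow(bins)))) {
    abort("bin ids must be 1..n")
  }
  H <- as.matrix(H)
  if (nrow(H) != nrow(bins) || ncol(H) != nrow(bins)) {
    abort("contact matrix dimension does not match the bin table")
  }
  if (any(H < 0)) abort("contact counts must be nonnegative")
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H)))) {
    abort("contact matrix must be symmetric")
  }
  rownames(bins) <- NULL
  structure(list(bins = bins, raw = H, intra = NULL, inter = NULL,
                 average_at_dist = NULL),
            class = "hic_dataset")
}

#' @export
print.hic_dataset <- function(x, ...) {
  cat("Hi-C dataset:", nrow(x$bins), "bins over",
      length(unique(x$bins$chrom)), "chromosome(s);",
      "intra", if (is.null(x$intra)) "raw" else "normalized", "/",
      "inter", if (is.null(x$inter)) "raw" else "normalized", "\n")
  invisible(x)
}

# within-chromosome positional index of each bin (1, 2, ... along each chrom)
bin_offsets <- function(bins) {
  off <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    off[i[order(bins$start[i])]] <- seq_along(i)
  }
  off
}

#' Expected-at-distance normalization of intra-chromosomal contacts
#'
#' Divides every intra-chromosomal entry by the mean raw value over all
#' intra-chromosomal bin pairs at the same distance, pooled across all
#' chromosomes: `INTRA[i,j] = H[i,j] / averageAtDist(|i-j|)`. After
#' normalization the mean over all defined pairs at each distance is 1.
#' Distances whose pooled average is zero yield `NA` (recorded missing,
#' never a division by zero); inter-chromosomal entries stay `NA`.
#'
#' @param h a [hic_dataset()].
#' @return `h` with fields `intra` (matrix) and `average_at_dist` filled.
#' @export
normalize_intra <- function(h) {
  if (!nrow(h$bins)) abort("empty Hi-C dataset")
  off <- bin_offsets(h$bins)
  n <- nrow(h$bins)
  same <- outer(h$bins$chrom, h$bins$chrom, "==")
  dmat <- abs(outer(off, off, "-"))
  dmax <- max(dmat[same])
  avg <- rep(NA_real_, dmax + 1L)
  for (d in 0:dmax) {
    sel <- same & dmat == d
    if (any(sel)) avg[d + 1L] <- mean(h$raw[sel])
  }
  intra <- matrix(NA_real_, n, n)
  for (d in 0:dmax) {
    sel <- same & dmat == d
    if (!any(sel)) next
    a <- avg[d + 1L]
    intra[sel] <- if (!is.na(a) && a > 0) h$raw[sel] / a else NA_real_
  }
  h$intra <- intra
  h$average_at_dist <- stats::setNames(avg, 0:dmax)
  h
}

#' Coverage-product normalization of inter-chromosomal contacts
#'
#' `INTER[i,j] = H[i,j] / (interaction_i * interaction_j / interaction_all)`
#' where `interaction_x` sums all raw contacts (intra and inter) of bin *x*
#' and `interaction_all` sums the whole matrix. The result is invariant
#' under a global rescaling of the raw counts and accentuates contacts of
#' low-coverage loci. Bins with zero total interaction yield `NA`;
#' intra-chromosomal entries stay `NA`.
#'
#' @param h a [hic_dataset()].
#' @return `h` with the `inter` matrix filled.
#' @export
normalize_inter <- function(h) {
  if (!nrow(h$bins)) abort("empty Hi-C dataset")
  n <- nrow(h$bins)
  inter_pair <- !outer(h$bins$chrom, h$bins$chrom, "==")
  interaction <- rowSums(h$raw)
  interaction_all <- sum(h$raw)
  expected <- outer(interaction, interaction) / interaction_all
  inter <- matrix(NA_real_, n, n)
  ok <- inter_pair & expected > 0
  inter[ok] <- h$raw[ok] / expected[ok]
  h$inter <- inter
  h
}

# bin index containing the midpoint of (chrom, start, end), or abort
locate_bin <- function(h, chrom, start, end) {
  mid <- (start + end) / 2
  i <- which(h$bins$chrom == chrom & h$bins$start <= mid & mid < h$bins$end)
  if (length(i) != 1L) {
    abort("breakpoint region ", chrom, ":", start, "-", end,
          " does not fall in exactly one bin")
  }
  i
}

#' Hi-C similarity between pairs of adjacencies
#'
#' Each adjacency is located by the midpoint of its breakpoint region; the
#' similarity of two adjacencies is the corresponding contact-matrix entry:
#' intra-normalized for same-chromosome pairs and inter-normalized
#' otherwise in `"normalized"` mode, the raw matrix in `"raw"` mode. Two
#' adjacencies falling in the same bin read the diagonal entry of that bin.
#'
#' @param coords a data frame with columns `key` (adjacency key, see
#'   [adj_key()]), `chrom`, `start`, `end` -- the breakpoint region of each
#'   adjacency of genome *A*.
#' @param h a [hic_dataset()], normalized when `mode = "normalized"`.
#' @param mode `"normalized"` or `"raw"`.
#' @return a symmetric numeric matrix of class `"similarity_table"` with
#'   adjacency keys as dimnames and `NA` on the diagonal (self-pairs are
#'   excluded).
#' @export
adjacency_similarity <- function(coords, h, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  coords <- as.data.frame(coords, stringsAsFactors = FALSE)
  if (!all(c("key", "chrom", "start", "end") %in% names(coords))) {
    abort("coords need columns key, chrom, start, end")
  }
  if (mode == "normalized" && is.null(h$intra)) {
    abort("dataset is not intra-normalized; run normalize_intra()")
  }
  n <- nrow(coords)
  bin <- vapply(seq_len(n), function(i)
    locate_bin(h, coords$chrom[i], coords$start[i], coords$end[i]), integer(1))
  S <- matrix(NA_real_, n, n, dimnames = list(coords$key, coords$key))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same <- h$bins$chrom[bin[i]] == h$bins$chrom[bin[j]]
      S[i, j] <- if (mode == "raw") {
        h$raw[bin[i], bin[j]]
      } else if (same) {
        h$intra[bin[i], bin[j]]
      } else {
        if (is.null(h$inter)) {
          abort("cross-chromosome pair but no inter normalization; run normalize_inter()")
        }
        h$inter[bin[i], bin[j]]
      }
    }
  }
  structure(S, class = c("similarity_table", "matrix"))
}
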