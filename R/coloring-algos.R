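# The three coloring generators compared in the experiments -- k-medoids on
# a Hi-C similarity, the 1D-structure-preserving linear coloring, and the
# surjective random coloring -- plus the two quality measures: clustering
# weight and divergence from linearity.

as_coloring <- function(x) {
  structure(stats::setNames(as.character(x), names(x)),
            palette = sort(unique(as.character(x))), class = "coloring")
}

#' Clustering weight of a coloring under a similarity table
#'
#' Each cluster contributes the *medoid sum*: the maximum over its members
#' of the summed similarities to the other members (0 for singletons); the
#' clustering weight adds these over all clusters.
#'
#' @param col a [coloring()] (or named color vector) over the row names of
#'   `sim`.
#' @param sim a [adjacency_similarity()] table covering all colored elements.
#' @return a nonnegative number.
#' @export
clustering_weight <- function(col, sim) {
  keys <- names(col)
  missing <- setdiff(keys, rownames(sim))
  if (length(missing)) abort("no similarity entries for ", missing[1])
  total <- 0
  for (cl in unique(unname(col))) {
    members <- keys[unname(col) == cl]
    if (length(members) < 2L) next
    sums <- vapply(members, function(m)
      sum(sim[m, setdiff(members, m)]), numeric(1))
    total <- total + max(sums)
  }
  total
}

#' k-medoids coloring from a similarity table
#'
#' Starts from `k` randomly chosen centroids, assigns every element to the
#' most similar centroid, recomputes each cluster's medoid (the member
#' maximizing the summed similarity to the rest), and repeats until the
#' clustering weight stops increasing (or `max_iter` is hit). All ties break
#' towards the lowest element index, so runs are deterministic under a seed.
#'
#' @param sim a [adjacency_similarity()] table (symmetric, keys as dimnames).
#' @param k number of clusters, between 1 and the number of elements.
#' @param seed integer seed for the centroid initialization.
#' @param max_iter iteration cap (default 100).
#' @return a `"coloring"` over the elements with colors `"1" .. "k"`, every
#'   color used at least once; its `weight` attribute holds the final
#'   clustering weight.
#' @export
kmedoids_coloring <- function(sim, k, seed = NULL, max_iter = 100L) {
  keys <- rownames(sim)
  n <- length(keys)
  if (k < 1L || k > n) abort("k must be between 1 and ", n)
  centroids <- with_seed(seed, sort(sample.int(n, k)))
  assign_clusters <- function(centroids) {
    cl <- integer(n)
    cl[centroids] <- seq_len(k)
    for (i in seq_len(n)) {
      if (i %in% centroids) next
      s <- sim[i, centroids]
      s[is.na(s)] <- -Inf
      cl[i] <- which.max(s) # first maximum: lowest centroid index
    }
    cl
  }
  medoid_of <- function(members) {
    if (length(members) == 1L) return(members)
    sums <- vapply(members, function(m)
      sum(sim[m, setdiff(members, m)], na.rm = TRUE), numeric(1))
    members[which.max(sums)]
  }
  cl <- assign_clusters(centroids)
  best_cl <- cl
  best_w <- clustering_weight(stats::setNames(as.character(cl), keys), sim)
  for (iter in seq_len(max_iter)) {
    centroids <- vapply(seq_len(k), function(c_) medoid_of(which(cl == c_)),
                        integer(1))
    cl <- assign_clusters(centroids)
    w <- clustering_weight(stats::setNames(as.character(cl), keys), sim)
    if (w <= best_w) break
    best_w <- w
    best_cl <- cl
  }
  out <- as_coloring(stats::setNames(as.character(best_cl), keys))
  attr(out, "weight") <- best_w
  out
}

# per-chromosome left-to-right order of adjacency keys of a block genome
# (external, internal..., external for a linear chromosome)
chromosome_adjacency_order <- function(g) {
  ba <- block_to_adjacency(g)
  map <- ba$map
  lab <- stats::setNames(map$extremity, paste(map$block, map$end))
  out <- vector("list", length(g))
  for (ci in seq_along(g)) {
    ch <- g[[ci]]
    seq_ext <- integer(0)
    for (j in seq_along(ch$blocks)) {
      ends <- if (ch$signs[j] > 0) c("t", "h") else c("h", "t")
      seq_ext <- c(seq_ext, lab[paste(ch$blocks[j], ends)])
    }
    k <- length(seq_ext)
    keys <- character(0)
    if (!ch$circular) keys <- adj_key(seq_ext[1])
    if (k >= 4L) {
      for (j in seq(2L, k - 2L, by = 2L)) {
        keys <- c(keys, adj_key(c(seq_ext[j], seq_ext[j + 1L])))
      }
    }
    if (ch$circular) {
      keys <- c(keys, adj_key(c(seq_ext[k], seq_ext[1])))
    } else {
      keys <- c(keys, adj_key(seq_ext[k]))
    }
    out[[ci]] <- keys
  }
  out
}

#' Linear coloring of a block genome
#'
#' Respects the 1D structure of the chromosomes: chooses `k - C` cut blocks
#' uniformly at random (without replacement; `C` is the number of
#' chromosomes), cuts each chromosome between the two adjacencies flanking
#' each chosen block, and gives every resulting segment a distinct color.
#' Every segment holds at least one adjacency by construction. Only genomes
#' whose chromosomes are all linear are supported.
#'
#' @param g a `"block_genome"` with linear chromosomes.
#' @param k number of colors, from the chromosome count up to the total
#'   adjacency count.
#' @param seed integer seed for the cut draw.
#' @return a `"coloring"` over the adjacency keys of
#'   [block_to_adjacency()]`(g)$genome`.
#' @export
linear_coloring <- function(g, k, seed = NULL) {
  if (any(vapply(g, `[[`, logical(1), "circular"))) {
    abort("linear_coloring needs all-linear chromosomes")
  }
  C <- length(g)
  orders <- chromosome_adjacency_order(g)
  n_blocks_per <- vapply(g, function(ch) length(ch$blocks), integer(1))
  n_adj <- sum(lengths(orders))
  if (k < C || k > n_adj) {
    abort("k must be between the chromosome count (", C,
          ") and the adjacency count (", n_adj, ")")
  }
  # global gap index: chromosome ci contributes gaps 1..n_blocks (gap j cuts
  # between the two adjacencies flanking block j)
  gap_chrom <- rep(seq_len(C), n_blocks_per)
  gap_pos <- unlist(lapply(n_blocks_per, seq_len), use.names = FALSE)
  cuts <- with_seed(seed, sort(sample.int(length(gap_pos), k - C)))
  colors <- character(0)
  labels <- character(0)
  color_i <- 0L
  for (ci in seq_len(C)) {
    cut_here <- sort(gap_pos[cuts][gap_chrom[cuts] == ci])
    bounds <- c(0L, cut_here, length(orders[[ci]]))
    for (s in seq_len(length(bounds) - 1L)) {
      seg <- orders[[ci]][(bounds[s] + 1L):bounds[s + 1L]]
      color_i <- color_i + 1L
      labels <- c(labels, seg)
      colors <- c(colors, rep(as.character(color_i), length(seg)))
    }
  }
  as_coloring(stats::setNames(colors, labels))
}

#' Surjective uniform random coloring
#'
#' First gives one distinct adjacency to each of the `k` colors (a draw
#' without replacement), then colors the remaining adjacencies independently
#' and uniformly.
#'
#' @param g a [genome()].
#' @param k number of colors, at most the number of adjacencies.
#' @param seed integer seed.
#' @return a `"coloring"` with colors `"1" .. "k"`, each used at least once.
#' @export
random_coloring <- function(g, k, seed = NULL) {
  keys <- names(g$adjacencies)
  n <- length(keys)
  if (k < 1L || k > n) abort("k must be between 1 and ", n)
  cols <- with_seed(seed, {
    out <- character(n)
    first <- sample.int(n, k)
    out[first] <- as.character(seq_len(k))
    rest <- setdiff(seq_len(n), first)
    if (length(rest)) out[rest] <- as.character(sample.int(k, length(rest),
                                                           replace = TRUE))
    out
  })
  as_coloring(stats::setNames(cols, keys))
}

#' Divergence from linearity of a coloring
#'
#' For each color: partition its adjacencies by chromosome into `l` parts;
#' within each part, sorted along the chromosome, count one *gap* for every
#' consecutive pair separated by at least one differently colored adjacency;
#' the color contributes `gaps + l - 1`. The divergence of the coloring is
#' the sum over colors; it is 0 exactly when every color class is one
#' contiguous run on a single chromosome.
#'
#' @param col a `"coloring"` keyed by the adjacency keys of `g`.
#' @param g the `"block_genome"` giving the 1D order of the adjacencies.
#' @return a nonnegative integer.
#' @export
divergence_from_linearity <- function(col, g) {
  orders <- chromosome_adjacency_order(g)
  pos <- list() # key -> c(chrom, position)
  for (ci in seq_along(orders)) {
    for (j in seq_along(orders[[ci]])) {
      pos[[orders[[ci]][j]]] <- c(ci, j)
    }
  }
  missing <- setdiff(names(col), names(pos))
  if (length(missing)) {
    abort("adjacency ", missing[1], " has no position on the chromosomes")
  }
  total <- 0L
  for (cl in unique(unname(col))) {
    members <- names(col)[unname(col) == cl]
    chrom <- vapply(members, function(m) pos[[m]][1], numeric(1))
    l <- length(unique(chrom))
    gaps <- 0L
    for (ch in unique(chrom)) {
      p <- sort(vapply(members[chrom == ch], function(m) pos[[m]][2],
                       numeric(1)))
      if (length(p) > 1L) gaps <- gaps + sum(diff(p) > 1)
    }
    total <- total + gaps + l - 1L
  }
  as.integer(total)
}
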