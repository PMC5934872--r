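# Hi-C normalization, adjacency similarity, the three coloring generators,
# clustering weight and divergence from linearity.

toy_bins <- function(n_chroms = 1, bins_per = 3) {
  data.frame(chrom = rep(paste0("chr", seq_len(n_chroms)), each = bins_per),
             start = rep((seq_len(bins_per) - 1) * 1e4, n_chroms),
             end = rep(seq_len(bins_per) * 1e4, n_chroms),
             stringsAsFactors = FALSE)
}

test_that("intra normalization divides by the pooled distance average", {
  # 3-bin toy: off-diagonals (4, 2): averageAtDist(1) = 4, averageAtDist(2) = 2
  H <- matrix(c(9, 4, 2, 4, 9, 4, 2, 4, 9), 3, 3)
  h <- normalize_intra(hic_dataset(toy_bins(), H))
  expect_equal(unname(h$average_at_dist), c(9, 4, 2))
  expect_equal(h$intra[upper.tri(h$intra)], c(1, 1, 1))

  # constant matrix: INTRA is 1 at every defined distance
  hc <- normalize_intra(hic_dataset(toy_bins(), matrix(5, 3, 3)))
  expect_true(all(hc$intra == 1))

  # mean of INTRA at each distance is 1 by construction
  set.seed(8)
  M <- matrix(runif(64, 0, 10), 8)
  M <- (M + t(M)) / 2
  h2 <- normalize_intra(hic_dataset(toy_bins(2, 4), M))
  off <- rep(1:4, 2)
  same <- outer(h2$bins$chrom, h2$bins$chrom, "==")
  dm <- abs(outer(off, off, "-"))
  for (d in 0:3) {
    sel <- same & dm == d
    expect_equal(mean(h2$intra[sel]), 1, tolerance = 1e-9)
  }
  # inter-chromosomal entries are not intra-normalized
  expect_true(all(is.na(h2$intra[!same])))
})

test_that("inter normalization is symmetric and scale-invariant", {
  set.seed(9)
  M <- matrix(runif(36, 1, 10), 6)
  M <- (M + t(M)) / 2
  h <- normalize_inter(hic_dataset(toy_bins(2, 3), M))
  expect_equal(h$inter, t(h$inter))
  h2 <- normalize_inter(hic_dataset(toy_bins(2, 3), 2 * M))
  expect_equal(h$inter, h2$inter)

  # hand expansion on a 2-locus-per-chromosome toy
  H <- matrix(c(0, 1, 2, 3,
                1, 0, 4, 5,
                2, 4, 0, 6,
                3, 5, 6, 0), 4, 4)
  hh <- normalize_inter(hic_dataset(toy_bins(2, 2), H))
  inter_all <- sum(H)
  r <- rowSums(H)
  expect_equal(hh$inter[1, 3], H[1, 3] / (r[1] * r[3] / inter_all),
               ignore_attr = TRUE)
  expect_equal(hh$inter[2, 4], H[2, 4] / (r[2] * r[4] / inter_all),
               ignore_attr = TRUE)
  expect_true(all(is.na(hh$inter[1:2, 1:2])))
})

test_that("adjacency similarity reads the right matrix entries", {
  set.seed(10)
  M <- matrix(runif(36, 1, 10), 6)
  M <- (M + t(M)) / 2
  h <- normalize_inter(normalize_intra(hic_dataset(toy_bins(2, 3), M)))
  coords <- data.frame(key = c("k1", "k2", "k3", "k4"),
                       chrom = c("chr1", "chr1", "chr2", "chr1"),
                       start = c(0, 20000, 10000, 500),
                       end = c(10000, 30000, 20000, 900))
  S <- adjacency_similarity(coords, h)
  expect_equal(S["k1", "k2"], h$intra[1, 3])
  expect_equal(S["k1", "k3"], h$inter[1, 5])
  # same-bin pair reads that bin's diagonal entry
  expect_equal(S["k1", "k4"], h$intra[1, 1])
  expect_true(is.na(S["k1", "k1"]))
  expect_equal(S, t(S))
  Sr <- adjacency_similarity(coords, h, mode = "raw")
  expect_equal(Sr["k1", "k3"], M[1, 5])
  expect_error(adjacency_similarity(
    data.frame(key = "k", chrom = "chrX", start = 0, end = 10), h),
    "does not fall in exactly one bin")
})

test_that("clustering weight is the sum of medoid sums", {
  S <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  S["a", "b"] <- S["b", "a"] <- 2
  S["a", "c"] <- S["c", "a"] <- 1
  S["b", "c"] <- S["c", "b"] <- 4
  # singletons weigh nothing
  expect_identical(clustering_weight(as_coloring(
    stats::setNames(c("1", "2", "3"), c("a", "b", "c"))), S), 0)
  # a pair weighs its similarity (both members tie as medoid)
  expect_identical(clustering_weight(as_coloring(
    stats::setNames(c("1", "1", "2"), c("a", "b", "c"))), S), 2)
  # 3-element cluster: medoid is b or c with sum 6
  expect_identical(clustering_weight(as_coloring(
    stats::setNames(c("1", "1", "1"), c("a", "b", "c"))), S), 6)
})

test_that("k-medoids recovers planted clusters and never decreases its weight", {
  # k = n: all singletons, weight 0
  syn <- synthetic_hic(1, 8, planted_clusters = 2, noise = 0, seed = 3)
  h <- normalize_intra(syn$hic)
  coords <- data.frame(key = sprintf("a%02d", 1:8), chrom = h$bins$chrom,
                       start = h$bins$start + 100, end = h$bins$start + 300)
  S <- adjacency_similarity(coords, h)
  km_n <- kmedoids_coloring(S, 8, seed = 1)
  expect_identical(attr(km_n, "weight"), 0)
  expect_length(unique(unname(km_n)), 8L)

  # planted two-block structure is recovered (best of a few restarts)
  recovered <- 0L
  for (sd in 1:20) {
    syn <- synthetic_hic(1, 10, planted_clusters = 2, noise = 0, seed = sd)
    h <- normalize_intra(syn$hic)
    coords <- data.frame(key = sprintf("a%02d", 1:10), chrom = h$bins$chrom,
                         start = h$bins$start + 100, end = h$bins$start + 300)
    S <- adjacency_similarity(coords, h)
    best <- NULL
    for (s in 1:10) {
      km <- kmedoids_coloring(S, 2, seed = s)
      if (is.null(best) || attr(km, "weight") > attr(best, "weight")) best <- km
    }
    if (same_partition(unname(best), syn$truth)) recovered <- recovered + 1L
  }
  expect_identical(recovered, 20L)

  # surjectivity and determinism under a fixed seed
  km1 <- kmedoids_coloring(S, 3, seed = 5)
  km2 <- kmedoids_coloring(S, 3, seed = 5)
  expect_identical(km1, km2)
  expect_length(unique(unname(km1)), 3L)
  expect_error(kmedoids_coloring(S, 0, seed = 1), "between 1 and")
})

test_that("linear coloring respects 1D structure", {
  bg <- parse_block_genome("1 2 3 $\n4 5 6 $")
  adj <- block_to_adjacency(bg)$genome
  n_adj <- length(adj$adjacencies)

  # k = C: one color per chromosome
  lc <- linear_coloring(bg, 2, seed = 1)
  expect_length(unique(unname(lc)), 2L)
  ords <- chromosome_adjacency_order(bg)
  expect_length(unique(unname(lc[ords[[1]]])), 1L)
  expect_length(unique(unname(lc[ords[[2]]])), 1L)

  # k = adjacency count: every adjacency its own color
  lmax <- linear_coloring(bg, n_adj, seed = 2)
  expect_length(unique(unname(lmax)), n_adj)

  # any linear coloring has divergence 0 and exactly k colors
  for (k in 2:n_adj) {
    lck <- linear_coloring(bg, k, seed = k)
    expect_length(unique(unname(lck)), k)
    expect_identical(divergence_from_linearity(lck, bg), 0L)
  }
  expect_error(linear_coloring(bg, 1, seed = 1), "between the chromosome count")
  expect_error(linear_coloring(parse_block_genome("1 2 @"), 1), "all-linear")
})

test_that("random coloring is surjective and roughly uniform", {
  inst <- random_genome_pair(5, 2, 0, seed = 1)
  # k = 1: monochromatic
  expect_length(unique(unname(random_coloring(inst$A, 1, seed = 1))), 1L)
  # every color used in each of many seeded draws
  for (s in 1:50) {
    rc <- random_coloring(inst$A, 3, seed = s)
    expect_length(unique(unname(rc)), 3L)
  }
  # empirical frequencies uniform within chi-square tolerance
  counts <- integer(3)
  for (s in 1:400) {
    rc <- random_coloring(inst$A, 3, seed = 1000 + s)
    tab <- table(factor(unname(rc), levels = c("1", "2", "3")))
    counts <- counts + as.integer(tab)
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("divergence from linearity counts gaps plus extra chromosome parts", {
  bg <- parse_block_genome("1 2 3 $\n4 5 $")
  ords <- chromosome_adjacency_order(bg)
  keys1 <- ords[[1]] # 4 adjacencies
  keys2 <- ords[[2]] # 3 adjacencies

  # one color contiguous on each of two chromosomes: gaps 0, l = 2 -> 1
  col2 <- as_coloring(stats::setNames(
    c("a", "a", "b", "b", "a", "a", "a")[c(1:4, 5:7)], c(keys1, keys2)))
  # color a: chr1 positions 1,2 contiguous + all of chr2 -> l = 2, gaps 0
  expect_identical(divergence_from_linearity(col2, bg), 1L)

  # color at positions 1 and 3 of one chromosome (2 other-colored) -> 1 gap
  col3 <- as_coloring(stats::setNames(
    c("a", "b", "a", "c", "c", "c", "c"), c(keys1, keys2)))
  # a: one gap; b: 0; c: spans both chromosomes -> + 1
  expect_identical(divergence_from_linearity(col3, bg), 2L)

  # zero iff every color is one contiguous run on one chromosome
  col4 <- as_coloring(stats::setNames(
    c("a", "a", "b", "b", "c", "c", "c"), c(keys1, keys2)))
  expect_identical(divergence_from_linearity(col4, bg), 0L)
})
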