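cs <- c(chr1 = 50000)

# integer-valued random track from fragments (exact window sums)
random_track <- function(seed, n = 2000, sizes = cs) {
  compute_coverage(random_fragments(n, sizes, seed))
}

test_that("anchor conventions follow strand orientation", {
  csA <- c(chr1 = 20000)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 5001), c(3000, 7000)),
    strand = c("+", "-"), gene_id = c("gp", "gm"), seqlengths = csA
  )
  exons <- GenomicRanges::GRangesList(
    gp = GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000), strand = "+"),
    gm = GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 7000), strand = "-")
  )
  ann <- gene_annotation(genes, exons, csA)
  tss <- build_anchors(ann, "TSS", flank = 500)
  tes <- build_anchors(ann, "TES", flank = 500)
  # + gene [1000, 3000): TSS 1000, TES 2999
  expect_equal(tss$anchor[tss$label == "gp"], 1000)
  expect_equal(tes$anchor[tes$label == "gp"], 2999)
  # - gene [5000, 7000): TSS 6999, TES 5000
  expect_equal(tss$anchor[tss$label == "gm"], 6999)
  expect_equal(tes$anchor[tes$label == "gm"], 5000)

  # relative +100 on the - gene maps to genomic 6899: plant signal there
  fr <- make_fragments("chr1", 6899, 6900, "+", csA)
  tr <- compute_coverage(fr)
  m <- compute_window_matrix(tr, tss, window = 1, slide = 1)
  pos <- attr(m, "positions")
  expect_equal(unname(m["gm", pos == 100]), 1)
  expect_equal(sum(m["gm", ]), 1)

  # anchors of simulated genes fall inside their gene bounds
  ann2 <- small_sim_annotation(n_genes = 50, seed = 4,
                               chrom_sizes = c(chr1 = 600000))
  t2 <- build_anchors(ann2, "TSS", flank = 0)
  s <- BiocGenerics::start(ann2$genes) - 1
  e <- BiocGenerics::end(ann2$genes)
  idx <- match(t2$label, ann2$genes$gene_id)
  expect_true(all(t2$anchor >= s[idx] & t2$anchor < e[idx]))

  # near-edge regions are excluded with a logged count
  expect_message(
    near <- build_anchors(ann, "TSS", flank = 1500),
    "excluded"
  )
  expect_equal(attr(near, "n_excluded"), 1)
  expect_false("gp" %in% near$label)
})

test_that("window matrix matches brute-force per-base means and the column-count formula", {
  ann <- small_sim_annotation(n_genes = 10, seed = 31,
                              chrom_sizes = c(chr1 = 200000))
  regions <- build_anchors(ann, "TSS", flank = 3000)
  tr <- random_track(77, n = 5000, sizes = c(chr1 = 200000))
  m <- compute_window_matrix(tr, regions, window = 100, slide = 20)
  expect_equal(ncol(m), 296) # (6000 - 100) / 20 + 1
  orc <- oracle_window_matrix(tr, regions, 100, 20)
  expect_true(all(unclass(m) == orc))
  expect_equal(attr(m, "positions")[1], -3000)

  # constant track: every cell equals the constant
  const <- tr
  const$cov <- IRanges::RleList(chr1 = S4Vectors::Rle(3.5, 200000))
  mc <- compute_window_matrix(const, regions, 100, 20)
  expect_true(all(abs(unclass(mc) - 3.5) < 1e-12))
})

test_that("mirroring the genome mirrors profiles about the anchor", {
  sizes <- c(chr1 = 30000)
  fr <- random_fragments(800, sizes, seed = 55)
  L <- sizes[["chr1"]]
  mfr <- make_fragments("chr1", L - BiocGenerics::end(fr),
                        L - (BiocGenerics::start(fr) - 1),
                        ifelse(as.character(BiocGenerics::strand(fr)) == "+",
                               "-", "+"), sizes)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(12001, 18000), strand = "+",
    gene_id = "g1", seqlengths = sizes
  )
  ex <- GenomicRanges::GRangesList(
    g1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(12001, 18000),
                                strand = "+")
  )
  ann <- gene_annotation(genes, ex, sizes)
  mgenes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(L - 18000 + 1, L - 12000), strand = "-",
    gene_id = "g1", seqlengths = sizes
  )
  mex <- GenomicRanges::GRangesList(
    g1 = GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(L - 18000 + 1, L - 12000),
                                strand = "-")
  )
  mann <- gene_annotation(mgenes, mex, sizes)
  a1 <- build_anchors(ann, "TSS", flank = 2000)
  a2 <- build_anchors(mann, "TSS", flank = 2000)
  m1 <- compute_window_matrix(compute_coverage(fr), a1, 50, 50)
  m2 <- compute_window_matrix(compute_coverage(mfr), a2, 50, 50)
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
})

test_that("median profile equals the column-wise sorting oracle", {
  one <- matrix(runif(296), nrow = 1)
  wm <- structure(one, positions = seq(-3000, by = 20, length.out = 296),
                  window = 100, slide = 20, flank = 3000,
                  class = c("window_matrix", "matrix"))
  expect_equal(average_profile(wm)$value, as.numeric(one))

  rows <- matrix(c(0, 10, 20), nrow = 3, ncol = 5)
  wm2 <- structure(rows, positions = 1:5, class = c("window_matrix", "matrix"))
  expect_equal(average_profile(wm2)$value, rep(10, 5))

  set.seed(71)
  big <- matrix(rnorm(101 * 296), 101, 296)
  wmb <- structure(big, positions = seq_len(296),
                   class = c("window_matrix", "matrix"))
  sort_oracle <- apply(big, 2, function(x) sort(x)[51])
  expect_equal(average_profile(wmb)$value, sort_oracle)

  expect_error(average_profile(wmb[0, , drop = FALSE]), "empty")
})

test_that("region density equals the per-base oracle and scales linearly", {
  ann <- small_sim_annotation(n_genes = 8, seed = 12,
                              chrom_sizes = c(chr1 = 150000))
  regions <- build_anchors(ann, "TSS", flank = 1000)
  tr <- random_track(91, n = 3000, sizes = c(chr1 = 150000))
  d <- region_density(tr, regions)
  for (i in seq_len(nrow(regions))) {
    v <- track_vector(tr, regions$chrom[i])
    a <- regions$anchor[i]
    rel <- (-1000):(999)
    pos0 <- if (regions$orientation[i] == "-") a - rel else a + rel
    expect_equal(d$density[i], mean(v[pos0 + 1]))
  }
  # doubling the normalization factor doubles every density
  tr2 <- tr
  tr2$cov <- tr2$cov * 2
  expect_equal(region_density(tr2, regions)$density, d$density * 2)
  # constant track: density equals the constant
  trc <- tr
  trc$cov <- IRanges::RleList(chr1 = S4Vectors::Rle(2.5, 150000))
  expect_equal(region_density(trc, regions)$density, rep(2.5, nrow(regions)))
})

test_that("Wilcoxon comparison: exact enumeration, approximation agreement, errors", {
  # A = {1,2}, B = {3,4}: exact two-sided p = 1/3
  r <- compare_density_groups(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 1 / 3)
  expect_equal(r$method, "exact")

  # identical multisets under the approximation: p = 1
  same <- compare_density_groups(c(1, 2, 3, 1, 2, 3, 4, 5, 6),
                                 c(1, 2, 3, 1, 2, 3, 4, 5, 6))
  expect_equal(same$p.value, 1)

  # exact path matches full enumeration for all n, m <= 6 (no ties)
  set.seed(19)
  for (n in 1:6) {
    for (m in 1:6) {
      a <- sample(seq(1, 400), n)
      b <- sample(seq(401, 800), m) - 400.5 # interleaved, tie-free
      expect_equal(compare_density_groups(a, b)$p.value,
                   oracle_wilcox_p(a, b), tolerance = 1e-12)
    }
  }

  # approximation within 0.02 of enumeration at n = m = 8
  set.seed(23)
  for (rep_i in 1:5) {
    a <- rnorm(8)
    b <- rnorm(8, mean = 0.5)
    approx_p <- compare_density_groups(a, b, exact_max = 0)$p.value
    expect_lt(abs(approx_p - oracle_wilcox_p(a, b)), 0.02)
  }

  expect_error(compare_density_groups(numeric(0), 1:3), "non-empty")
})

test_that("k-means ordering recovers planted structure and is a deterministic permutation", {
  set.seed(3)
  n_hi <- 60
  n_lo <- 140
  mat <- rbind(
    matrix(rnorm(n_hi * 40, mean = 5), n_hi, 40),
    matrix(rnorm(n_lo * 40, mean = 0), n_lo, 40)
  )
  rownames(mat) <- sprintf("r%03d", seq_len(n_hi + n_lo))
  wm <- structure(mat, positions = seq_len(40),
                  class = c("window_matrix", "matrix"))
  ord <- cluster_and_order(wm, k = 2, seed = 9)
  planted <- rep(c(1, 2), c(n_hi, n_lo))
  tab <- table(ord$clusters, planted)
  err <- (sum(tab) - max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1])) /
    sum(tab)
  expect_lte(err, 0.02)
  # high-signal cluster ranked first and ordering is a permutation
  expect_true(all(sort(ord$order) == seq_len(n_hi + n_lo)))
  expect_true(mean(ord$order[1:n_hi] <= n_hi) > 0.97)
  expect_identical(ord$order, cluster_and_order(wm, k = 2, seed = 9)$order)

  # k = 1 degenerates to descending row-mean sort
  ord1 <- cluster_and_order(wm, k = 1)
  expect_identical(ord1$order, order(-rowMeans(mat), rownames(mat)))
  expect_error(cluster_and_order(wm, k = 300, seed = 1), "exceeds")

  # companion matrices are permuted, preserving every row exactly once
  comp <- apply_ordering(wm, ord)
  expect_identical(sort(rownames(comp)), sort(rownames(wm)))
  expect_equal(unclass(comp), unclass(wm)[ord$order, ], ignore_attr = TRUE)
})
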