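test_that("union-mode stranded counting follows the assignment rules", {
  ann <- fixture_annotation()
  frags <- c(
    make_fragments("chr1", 1100, 1300, "+"),   # inside geneA exon, sense
    make_fragments("chr1", 1100, 1300, "-"),   # antisense to geneA -> discarded
    make_fragments("chr1", 2850, 2950, "+"),   # overlaps exons of A and C -> ambiguous
    make_fragments("chr1", 6000, 6200, "-"),   # geneB sense
    make_fragments("chr1", 4300, 4500, "+"),   # intergenic -> no feature
    make_fragments("chr1", 1500, 2000, "+")    # intron of geneA only -> no feature
  )
  res <- count_union_stranded(frags, ann)
  expect_equal(unname(res$counts["geneA"]), 1)
  expect_equal(unname(res$counts["geneB"]), 1)
  expect_equal(unname(res$counts["geneC"]), 0)
  expect_equal(unname(res$tallies["ambiguous"]), 1)
  expect_equal(unname(res$tallies["wrong_strand"]), 1)
  expect_equal(unname(res$tallies["no_feature"]), 2)
  expect_equal(sum(res$tallies), length(frags))
})

test_that("counting matches the exhaustive per-fragment oracle on random input", {
  ann <- small_sim_annotation(n_genes = 20, seed = 77,
                              chrom_sizes = c(chr1 = 200000))
  frags <- random_fragments(1000, c(chr1 = 200000), seed = 88)
  res <- count_union_stranded(frags, ann)
  orc <- oracle_union_counts(frags, ann)
  expect_identical(res$counts, orc$counts)
  expect_identical(res$tallies, orc$tallies)
  expect_equal(sum(res$tallies), 1000)
  expect_equal(sum(res$counts), unname(res$tallies["assigned"]))
})

test_that("size factors implement median-of-ratios with its symmetries", {
  counts <- matrix(rpois(400, 100) + 1, ncol = 4)
  same <- cbind(counts[, 1], counts[, 1], counts[, 1])
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))

  double <- cbind(s1 = counts[, 1], s2 = 2L * counts[, 1])
  expect_equal(unname(estimate_size_factors(double)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  perm <- counts[sample(nrow(counts)), ]
  expect_equal(estimate_size_factors(perm), estimate_size_factors(counts))

  # scaling one sample by c scales its factor by c relative to the others
  # (size factors are defined up to a common rescaling)
  sf0 <- estimate_size_factors(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3L
  sf1 <- estimate_size_factors(scaled)
  expect_equal((sf1[2] / sf1[1]) / (sf0[2] / sf0[1]), 3, tolerance = 1e-9)

  expect_error(estimate_size_factors(matrix(0L, 3, 2)), "nonzero")
})

test_that("NB differential test: null identity, calibration, recovery", {
  # identical counts in both conditions: observed split is the modal one
  set.seed(40)
  row_vals <- rpois(100, 300) + 1L
  counts <- matrix(rep(row_vals, 4), ncol = 4) # every gene identical across samples
  counts[1, ] <- 500L
  de <- test_differential(counts, factor(c("a", "a", "b", "b")))
  expect_gte(de$p[1], 0.99)

  # type-I error on a 2000-gene null
  set.seed(41)
  null_counts <- matrix(rnbinom(2000 * 4, mu = 500, size = 1 / 0.1), ncol = 4)
  de0 <- test_differential(null_counts, factor(c("a", "a", "b", "b")))
  expect_gt(mean(de0$p < 0.05), 0.02)
  expect_lt(mean(de0$p < 0.05), 0.08)
  # BH adjustment: padj >= p and monotone in p-rank
  expect_true(all(de0$padj >= de0$p - 1e-15))
  o <- order(de0$p)
  expect_true(all(diff(de0$padj[o]) >= -1e-12))

  # planted fold change 4 at mean 500: median log2 FC within 0.3 of 2
  set.seed(42)
  mu <- rep(500, 1000)
  fc <- rep(1, 1000)
  fc[1:50] <- 4
  pl <- cbind(matrix(rnbinom(2000, mu = mu, size = 10), ncol = 2),
              matrix(rnbinom(2000, mu = mu * fc, size = 10), ncol = 2))
  dep <- test_differential(pl, factor(c("a", "a", "b", "b"),
                                      levels = c("a", "b")))
  expect_lt(abs(stats::median(dep$log2_fc[1:50]) - 2), 0.3)
})

test_that("DE classification applies the padj / fold-change / base-mean filters", {
  res <- data.frame(
    gene = sprintf("g%d", 1:6),
    base_mean = c(250, 250, 150, 250, 500, 199),
    fc = c(3.0, 2.0, 4.0, 1 / 3, 1 / 2, 5),
    padj = c(0.04, 0.04, 0.01, 0.01, 0.2, 0.001),
    p = c(0.01, 0.01, 0.001, 0.001, 0.1, 1e-4)
  )
  cls <- classify_de(res)$class
  expect_equal(cls, c("up", "unchanged", "low_expression", "down",
                      "unchanged", "low_expression"))
  # classification partitions the gene set
  expect_true(all(cls %in% c("up", "down", "unchanged", "low_expression")))
})

test_that("top-active ranking corrects counts for gene length with stable ties", {
  counts <- c(g_short = 1000, g_long = 1500)
  lens <- c(g_short = 1000, g_long = 2000)
  expect_equal(rank_top_active(counts, lens, n = 1), "g_short") # 1.0 > 0.75

  tied <- c(b_gene = 100, a_gene = 200)
  tlens <- c(b_gene = 100, a_gene = 200) # equal rates: identifier order
  expect_equal(rank_top_active(tied, tlens, n = 2), c("a_gene", "b_gene"))

  set.seed(8)
  cts <- stats::setNames(rpois(50, 500), sprintf("g%02d", 1:50))
  ls <- stats::setNames(sample(500:5000, 50), names(cts))
  top <- rank_top_active(cts, ls, n = 10)
  rate <- cts / ls
  orc <- names(sort(rate, decreasing = TRUE))[1:10]
  expect_equal(top, orc)
  expect_warning(all_g <- rank_top_active(cts, ls, n = 100), "returning all")
  expect_length(all_g, 50)
})

test_that("NB test agrees broadly with an established package on a planted dataset", {
  set.seed(77)
  mu <- rep(400, 600)
  fc <- rep(1, 600)
  fc[1:30] <- 5
  counts <- cbind(matrix(rnbinom(1200, mu = mu, size = 8), ncol = 2),
                  matrix(rnbinom(1200, mu = mu * fc, size = 8), ncol = 2))
  rownames(counts) <- sprintf("g%03d", 1:600)
  colnames(counts) <- sprintf("s%d", 1:4)
  cond <- factor(c("a", "a", "b", "b"))
  de <- test_differential(counts, cond)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, S4Vectors::DataFrame(condition = cond), ~condition
  )
  fitted <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- DESeq2::results(fitted)
  # size factors match the median-of-ratios reference
  expect_equal(unname(estimate_size_factors(counts)),
               unname(DESeq2::sizeFactors(fitted)), tolerance = 1e-6)
  # the two routes rank genes near-identically (the conditional-on-total
  # test is more conservative than the Wald test in absolute p, by design)
  ok <- !is.na(dres$pvalue)
  expect_gt(stats::cor(-log10(de$p[ok] + 1e-300),
                       -log10(dres$pvalue[ok] + 1e-300),
                       method = "spearman"), 0.95)
  expect_gt(stats::cor(de$log2_fc[ok], dres$log2FoldChange[ok]), 0.99)
  top_mine <- order(de$p)[1:30]
  top_theirs <- order(dres$pvalue)[1:30]
  expect_gte(length(intersect(top_mine, top_theirs)) / 30, 0.8)
  # calls made at padj < 0.05 are overwhelmingly the planted genes
  mine <- de$gene[de$padj < 0.05]
  expect_gt(length(mine), 5)
  expect_gte(mean(mine %in% sprintf("g%03d", 1:30)), 0.9)
})
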