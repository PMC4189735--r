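test_that("annotation simulation is deterministic, non-overlapping and handles edge cases", {
  cfg <- simulation_config(c(chr1 = 1e6), 50, intergenic_gap_range = c(1000, 3000),
                           seed = 7)
  ann <- simulate_annotation(cfg)
  expect_identical(simulate_annotation(cfg)$genes, ann$genes)
  expect_equal(n_genes(ann), 50)
  # brute-force interval sweep: no pair of genes overlaps
  s <- BiocGenerics::start(ann$genes)
  e <- BiocGenerics::end(ann$genes)
  for (i in seq_len(49)) {
    expect_true(all(s[-i] > e[i] | e[-i] < s[i]))
  }
  # exons stay inside their gene and have the gene's strand
  for (g in seq_len(50)) {
    ex <- ann$exons[[ann$genes$gene_id[g]]]
    expect_true(all(BiocGenerics::start(ex) >= s[g] &
                      BiocGenerics::end(ex) <= e[g]))
  }
  # empty annotation
  empty <- simulate_annotation(simulation_config(c(chr1 = 1e5), 0, seed = 1))
  expect_equal(n_genes(empty), 0)
  # capacity exceeded raises a placement error
  expect_error(
    simulate_annotation(simulation_config(
      c(chr1 = 20000), 10, gene_length_range = c(5000, 6000), seed = 1
    )),
    "placement"
  )
})

test_that("ChIP simulation: background uniformity, anchored enrichment, count conservation", {
  ann <- small_sim_annotation()
  flat <- chip_enrichment_spec(peak_amplitude = 0)
  fr <- simulate_chip_fragments(ann, flat, 30000, seed = 5)
  expect_length(fr, 30000)
  # amplitude 0: per-window midpoint counts within 3 Poisson sd of uniform
  mids <- floor((BiocGenerics::start(fr) - 1 + BiocGenerics::end(fr)) / 2)
  on1 <- mids[as.character(GenomeInfoDb::seqnames(fr)) == "chr1"]
  win <- table(cut(on1, seq(0, 400000, by = 20000)))
  lambda <- length(on1) / 20
  expect_true(all(abs(win - lambda) < 3.5 * sqrt(lambda)))

  # one strong peak: fragments near that TSS exceed an intergenic window
  amp <- rep(0, n_genes(ann))
  amp[1] <- 10
  peaked <- chip_enrichment_spec(peak_amplitude = amp, peak_shape = 500)
  fr2 <- simulate_chip_fragments(ann, peaked, 100000, seed = 6)
  tss <- build_anchors(ann, "TSS", flank = 0)
  a <- tss$anchor[tss$label == ann$genes$gene_id[1]]
  chrom1 <- tss$chrom[tss$label == ann$genes$gene_id[1]]
  mids2 <- floor((BiocGenerics::start(fr2) - 1 + BiocGenerics::end(fr2)) / 2)
  ch2 <- as.character(GenomeInfoDb::seqnames(fr2))
  n_peak <- sum(ch2 == chrom1 & abs(mids2 - a) <= 500)
  # same-width window in the chr2 gene desert tail
  n_bg <- sum(ch2 == "chr2" & abs(mids2 - 190000) <= 500)
  expect_gt(n_peak, n_bg)
  expect_lt(stats::binom.test(c(n_peak, n_bg))$p.value, 1e-6)

  expect_length(simulate_chip_fragments(ann, flat, 1, seed = 1), 1)
  expect_identical(
    GenomicRanges::granges(simulate_chip_fragments(ann, flat, 100, seed = 3)),
    GenomicRanges::granges(simulate_chip_fragments(ann, flat, 100, seed = 3))
  )
})

test_that("background ChIP coverage passes chi-square uniformity across seeds", {
  ann <- small_sim_annotation(n_genes = 5, chrom_sizes = c(chr1 = 100000))
  flat <- chip_enrichment_spec(peak_amplitude = 0)
  pvals <- vapply(1:100, function(s) {
    fr <- simulate_chip_fragments(ann, flat, 2000, seed = s)
    mids <- floor((BiocGenerics::start(fr) - 1 + BiocGenerics::end(fr)) / 2)
    obs <- table(cut(mids, seq(0, 100000, by = 5000)))
    stats::chisq.test(obs)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("RNA simulation: strand placement, conservation, condition fold changes", {
  ann <- small_sim_annotation()
  ng <- n_genes(ann)
  # degenerate antisense fractions: all fragments on the source gene strand
  pure <- rna_expression_spec(expression_level = 100,
                              antisense_fraction_tss = 0,
                              antisense_fraction_tes = 0)
  fr <- simulate_rna_fragments(ann, pure, "c", 5000, seed = 2)
  expect_length(fr, 5000)
  gstr <- stats::setNames(as.character(BiocGenerics::strand(ann$genes)),
                          ann$genes$gene_id)
  expect_identical(as.character(BiocGenerics::strand(fr)),
                   unname(gstr[fr$origin]))
  expect_true(all(fr$category == "sense"))

  # antisense fragments land on the opposite strand near TSS/TES
  mix <- rna_expression_spec(expression_level = 100,
                             antisense_fraction_tss = 0.2,
                             antisense_fraction_tes = 0.1)
  fr2 <- simulate_rna_fragments(ann, mix, "c", 20000, seed = 3)
  expect_length(fr2, 20000) # conservation over all categories
  anti <- fr2[fr2$category != "sense"]
  expect_identical(as.character(BiocGenerics::strand(anti)),
                   unname(ifelse(gstr[anti$origin] == "+", "-", "+")))
  frac_tss <- mean(fr2$category == "antisense_tss")
  expect_lt(abs(frac_tss - 0.2), 0.02)

  # fold change 4 recovered within 10% over 20 seeds at expected count 500
  fcv <- rep(1, ng)
  fcv[1] <- 4
  lev <- rep(500, ng)
  spec <- rna_expression_spec(expression_level = lev,
                              antisense_fraction_tss = 0,
                              antisense_fraction_tes = 0,
                              fold_changes = list(treated = fcv))
  gid1 <- ann$genes$gene_id[1]
  # the multinomial renormalizes masses within each sample, so correct the
  # raw count ratio by the total-mass ratio to recover the fold change
  mass_corr <- (sum(lev) + 3 * 500) / sum(lev)
  ratio <- vapply(1:20, function(s) {
    n_t <- sum(simulate_rna_fragments(ann, spec, "treated",
                                      20000, seed = s)$origin == gid1)
    n_u <- sum(simulate_rna_fragments(ann, spec, "untreated",
                                      20000, seed = 100 + s)$origin == gid1)
    n_t / n_u * mass_corr
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 4) / 4, 0.1)
})

test_that("sense fragments start within the exon union of their source gene", {
  ann <- small_sim_annotation(n_genes = 20, seed = 9)
  spec <- rna_expression_spec(expression_level = 50,
                              antisense_fraction_tss = 0,
                              antisense_fraction_tes = 0)
  fr <- simulate_rna_fragments(ann, spec, "c", 3000, seed = 11)
  red <- IRanges::reduce(ann$exons)
  for (gid in unique(fr$origin)) {
    sub <- fr[fr$origin == gid]
    ex <- red[[gid]]
    starts <- BiocGenerics::start(sub)
    inside <- vapply(starts, function(p) {
      any(p >= BiocGenerics::start(ex) & p <= BiocGenerics::end(ex))
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("qPCR panel simulation: zero-noise identity, constant spike-ins, mean-preserving noise", {
  truth <- data.frame(
    target = rep(c("g1", "g2"), each = 2),
    sample = rep(c("a", "b"), 2),
    abundance = c(10, 40, 5, 5)
  )
  exact <- simulate_qpcr_panel(truth, c("ERCC-00074" = 1000),
                               noise_cv = 0, seed = 1)
  expect_equal(exact$abundance[exact$role == "target"], truth$abundance)
  sp <- exact[exact$role == "spikein", ]
  expect_true(all(sp$abundance == 1000)) # constant across conditions
  # lognormal noise preserves the mean: 100 wells within 3% of truth
  noisy <- simulate_qpcr_panel(truth[1, ], noise_cv = 0.1, seed = 4,
                               n_replicates = 100)
  expect_lt(abs(mean(noisy$abundance) - 10) / 10, 0.03)
  expect_identical(simulate_qpcr_panel(truth, noise_cv = 0.2, seed = 9),
                   simulate_qpcr_panel(truth, noise_cv = 0.2, seed = 9))
})
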