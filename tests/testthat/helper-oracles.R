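# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-base loops, full enumeration) so they check the
# vectorized implementations from an independent route.

# per-base fragment pile-up by looping over fragments
oracle_coverage <- function(records, chrom_sizes) {
  out <- lapply(chrom_sizes, function(L) numeric(L))
  ch <- as.character(GenomeInfoDb::seqnames(records))
  s <- BiocGenerics::start(records)
  e <- BiocGenerics::end(records)
  for (i in seq_along(records)) {
    out[[ch[i]]][s[i]:e[i]] <- out[[ch[i]]][s[i]:e[i]] + 1
  }
  out
}

# decoded per-base vector of a coverage track for one chromosome
track_vector <- function(track, chrom) {
  as.numeric(track$cov[[chrom]])
}

# brute-force window matrix: per-base extraction + mean per window
oracle_window_matrix <- function(track, regions, window, slide) {
  flank <- attr(regions, "flank")
  n_win <- (2 * flank - window) %/% slide + 1
  out <- matrix(NA_real_, nrow(regions), n_win)
  for (i in seq_len(nrow(regions))) {
    v <- track_vector(track, regions$chrom[i])
    a <- regions$anchor[i]
    rel <- (-flank):(flank - 1)
    pos0 <- if (regions$orientation[i] == "-") a - rel else a + rel
    base <- v[pos0 + 1]
    for (j in seq_len(n_win)) {
      lo <- (j - 1) * slide + 1
      out[i, j] <- mean(base[lo:(lo + window - 1)])
    }
  }
  out
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_wilcox_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(a)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(vals), n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive per-fragment union-mode assignment
oracle_union_counts <- function(records, annotation) {
  gid <- annotation$genes$gene_id
  red <- IRanges::reduce(annotation$exons)[gid]
  counts <- stats::setNames(integer(length(gid)), gid)
  tallies <- c(assigned = 0L, ambiguous = 0L, wrong_strand = 0L,
               no_feature = 0L)
  fch <- as.character(GenomeInfoDb::seqnames(records))
  fst <- as.character(BiocGenerics::strand(records))
  fs <- BiocGenerics::start(records)
  fe <- BiocGenerics::end(records)
  for (i in seq_along(records)) {
    hit_same <- character(0)
    hit_any <- FALSE
    for (g in seq_along(gid)) {
      ex <- red[[g]]
      gch <- as.character(GenomeInfoDb::seqnames(annotation$genes[g]))
      if (gch != fch[i]) next
      ov <- any(fs[i] <= BiocGenerics::end(ex) &
                  fe[i] >= BiocGenerics::start(ex))
      if (!ov) next
      hit_any <- TRUE
      gstr <- as.character(BiocGenerics::strand(annotation$genes[g]))
      if (gstr == fst[i]) hit_same <- c(hit_same, gid[g])
    }
    if (!hit_any) {
      tallies["no_feature"] <- tallies["no_feature"] + 1L
    } else if (length(hit_same) == 0) {
      tallies["wrong_strand"] <- tallies["wrong_strand"] + 1L
    } else if (length(hit_same) == 1) {
      tallies["assigned"] <- tallies["assigned"] + 1L
      counts[hit_same] <- counts[hit_same] + 1L
    } else {
      tallies["ambiguous"] <- tallies["ambiguous"] + 1L
    }
  }
  list(counts = counts, tallies = tallies)
}

# hand-built two-gene annotation on one 10 kb chromosome:
#   geneA: + strand, [1000, 3000), exons [1000,1400) and [2500,3000)
#   geneB: - strand, [5000, 7000), single exon
#   geneC: + strand, [2800, 4000), single exon (overlaps geneA exon 2)
fixture_annotation <- function() {
  cs <- c(chr1 = 10000)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 5001, 2801), c(3000, 7000, 4000)),
    strand = c("+", "-", "+"),
    gene_id = c("geneA", "geneB", "geneC"), seqlengths = cs
  )
  exons <- GenomicRanges::GRangesList(
    geneA = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(1001, 2501), c(1400, 3000)), strand = "+"
    ),
    geneB = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(5001, 7000), strand = "-"
    ),
    geneC = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(2801, 4000), strand = "+"
    )
  )
  gene_annotation(genes, exons, cs)
}

# stranded fragment GRanges from 0-based half-open intervals
make_fragments <- function(chrom, start0, end0, strand,
                           chrom_sizes = c(chr1 = 10000),
                           sample_id = "s") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start0 + 1, end0), strand = strand,
    seqlengths = chrom_sizes
  )
  gr$duplicate <- FALSE
  gr$unique <- TRUE
  gr$sample <- sample_id
  gr
}

# random fragments within bounds
random_fragments <- function(n, chrom_sizes, seed, max_len = 300) {
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_sizes), n, replace = TRUE)
    len <- sample(50:max_len, n, replace = TRUE)
    start0 <- floor(stats::runif(n) * (chrom_sizes[chrom] - len))
    make_fragments(chrom, start0, start0 + len,
                   sample(c("+", "-"), n, TRUE), chrom_sizes)
  })
}

# small simulated annotation reused across tests
small_sim_annotation <- function(n_genes = 30, seed = 42,
                                 chrom_sizes = c(chr1 = 400000,
                                                 chr2 = 200000)) {
  simulate_annotation(simulation_config(
    chrom_sizes = chrom_sizes, n_genes = n_genes,
    gene_length_range = c(2000, 5000),
    intergenic_gap_range = c(1500, 4000), seed = seed
  ))
}
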