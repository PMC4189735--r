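#' Strand-aware union-mode gene counting
#'
#' Assigns each fragment to a gene when its interval overlaps that gene's
#' exon union on the matching strand; fragments overlapping exons of two
#' or more same-strand genes are ambiguous and discarded, fragments
#' overlapping exons only on the opposite strand are discarded as
#' wrong-strand, and fragments touching no exon are no-feature. One count
#' per fragment (paired-end data counted once). The four category tallies
#' always sum to the input fragment count.
#'
#' @param records stranded fragment `GRanges`.
#' @param annotation a `gene_annotation` with exons.
#' @return list with `counts` (named integer vector per gene) and
#'   `tallies` (assigned / ambiguous / wrong_strand / no_feature).
#' @export
count_union_stranded <- function(records, annotation) {
  if (sum(lengths(annotation$exons)) == 0) {
    stop("annotation has no exons to count against")
  }
  gid <- annotation$genes$gene_id
  red <- IRanges::reduce(annotation$exons)[gid]
  ex <- unlist(red)
  ex_gene <- rep(gid, lengths(red))
  hits <- GenomicRanges::findOverlaps(records, ex, ignore.strand = TRUE)
  fs <- as.character(BiocGenerics::strand(records))[S4Vectors::queryHits(hits)]
  gs <- as.character(BiocGenerics::strand(ex))[S4Vectors::subjectHits(hits)]
  same <- fs == gs
  # genes hit on the matching strand, deduplicated per fragment
  key <- paste(S4Vectors::queryHits(hits), ex_gene[S4Vectors::subjectHits(hits)])
  keep <- same & !duplicated(key)
  q <- S4Vectors::queryHits(hits)[keep]
  g <- ex_gene[S4Vectors::subjectHits(hits)][keep]
  n_genes_hit <- tabulate(q, nbins = length(records))
  assigned <- n_genes_hit == 1L
  counts <- table(factor(g[assigned[q]], levels = gid))
  any_overlap <- tabulate(S4Vectors::queryHits(hits),
                          nbins = length(records)) > 0L
  tallies <- c(
    assigned = sum(assigned),
    ambiguous = sum(n_genes_hit >= 2L),
    wrong_strand = sum(any_overlap & n_genes_hit == 0L),
    no_feature = sum(!any_overlap)
  )
  list(counts = stats::setNames(as.integer(counts), gid), tallies = tallies)
}

#' Build a count table from fragment sets
#'
#' Runs [count_union_stranded()] per sample and binds the results into a
#' genes x samples matrix with sample metadata.
#'
#' @param fragment_sets named list of fragment `GRanges`.
#' @param annotation a `gene_annotation`.
#' @param metadata optional data.frame (one row per sample) with columns
#'   such as `genotype`, `treatment`, `replicate`.
#' @return a `count_table`: list with `counts` (integer matrix),
#'   `metadata`, `tallies` (per-sample category counts).
#' @export
build_count_table <- function(fragment_sets, annotation, metadata = NULL) {
  stopifnot(is.list(fragment_sets), length(fragment_sets) >= 1)
  if (is.null(names(fragment_sets))) {
    names(fragment_sets) <- sprintf("sample%d", seq_along(fragment_sets))
  }
  per <- lapply(fragment_sets, count_union_stranded, annotation = annotation)
  counts <- vapply(per, `[[`, numeric(n_genes(annotation)), "counts")
  tallies <- vapply(per, `[[`, numeric(4), "tallies")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, metadata = metadata, tallies = t(tallies)),
    class = "count_table"
  )
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted
#' to genes with a finite log geometric mean, i.e. nonzero in every
#' sample) of the ratio of that sample's count to the gene's across-sample
#' geometric mean.
#'
#' @param counts integer matrix (genes x samples) or a `count_table`.
#' @return named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    stop("no gene has nonzero counts in every sample; cannot size-normalize")
  }
  apply(logc, 2, function(x) exp(stats::median((x - loggeo)[ok])))
}

# Dispersion trend: local regression of the raw method-of-moments
# dispersion on log mean. Fitting on the raw scale keeps the trend
# mean-unbiased (per-gene estimates at 2 residual df are heavily skewed,
# so log- or median-based fits are biased low); negative estimates stay
# in the fit for the same reason. Degenerate mean ranges (or loess
# failure) fall back to the global mean dispersion.
.dispersion_trend <- function(base_mean, disp_mom) {
  use <- base_mean > 0 & is.finite(disp_mom)
  fallback <- mean(disp_mom[use])
  if (!is.finite(fallback) || fallback <= 0) fallback <- 1e-8
  trend <- rep(fallback, length(base_mean))
  lx <- log(base_mean[use])
  if (sum(use) >= 50 && stats::sd(lx) > 0.1) {
    fit <- tryCatch(
      stats::loess(disp_mom[use] ~ lx, span = 0.75, degree = 1,
                   family = "gaussian"),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      px <- pmin(max(lx), pmax(min(lx), log(pmax(base_mean, 1e-8))))
      pr <- tryCatch(stats::predict(fit, data.frame(lx = px)),
                     error = function(e) rep(NA_real_, length(px)))
      good <- is.finite(pr)
      trend[good] <- pr[good]
    }
  }
  pmax(trend, 1e-8)
}

#' Negative-binomial differential expression test
#'
#' Two-condition, two-sided differential test on size-factor-normalized
#' counts with a negative-binomial error model:
#'
#' 1. size factors by median-of-ratios; normalized counts
#'    `q = K / s`; base mean = across-sample mean of `q`;
#' 2. per-gene method-of-moments dispersion from the pooled
#'    within-condition variance `w` of normalized counts, shot-noise
#'    corrected (`alpha = (w - q_bar * mean(1/s)) / q_bar^2`), floored at
#'    `1e-8`;
#' 3. small-sample shrinkage of `alpha` toward a mean-dispersion trend
#'    (local regression of dispersion on log mean) with prior weight
#'    `prior_df` against the residual df `n - 2`;
#' 4. a conditional exact-style test: given the total count of a gene,
#'    the per-condition sums are modelled as negative binomials with
#'    matched mean and variance under the null of equal concentration,
#'    and the two-sided p-value sums the probabilities of all splits no
#'    more likely than the observed one;
#' 5. Benjamini-Hochberg adjustment across genes.
#'
#' Fold change is `(mean_B + pseudo) / (mean_A + pseudo)` on normalized
#' means with a pseudo-count of 1 to stabilize zeros.
#'
#' @param counts integer matrix (genes x samples) or a `count_table`.
#' @param condition_labels factor/character of length `ncol` with exactly
#'   two levels; the first level is the reference (untreated) condition.
#' @param prior_df prior degrees of freedom for dispersion shrinkage.
#' @param pseudo_count pseudo-count used in the fold-change ratio.
#' @return a `de_result` data.frame: `gene`, `base_mean`, `fc`,
#'   `log2_fc`, `dispersion`, `p`, `padj`.
#' @export
test_differential <- function(counts, condition_labels, prior_df = 10,
                              pseudo_count = 1) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  cond <- factor(condition_labels)
  if (nlevels(cond) != 2) stop("exactly two conditions are required")
  if (any(table(cond) < 2)) {
    stop("each condition needs >= 2 replicates for dispersion estimation; ",
         "pool replicates or supply a pooled-dispersion design")
  }
  sf <- estimate_size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(q)
  ia <- which(cond == levels(cond)[1])
  ib <- which(cond == levels(cond)[2])
  mean_a <- rowMeans(q[, ia, drop = FALSE])
  mean_b <- rowMeans(q[, ib, drop = FALSE])
  n <- ncol(counts)
  # pooled within-condition variance of normalized counts (df = n - 2)
  ss <- rowSums((q[, ia, drop = FALSE] - mean_a)^2) +
    rowSums((q[, ib, drop = FALSE] - mean_b)^2)
  w <- ss / (n - 2)
  z <- base_mean * mean(1 / sf)
  disp_mom <- (w - z) / base_mean^2
  disp_mom[!is.finite(disp_mom)] <- 0
  trend <- .dispersion_trend(base_mean, disp_mom)
  d_res <- n - 2
  # linear shrinkage toward the trend, weighted by residual vs prior df;
  # raw scale keeps the combination mean-unbiased at tiny df
  disp <- (prior_df * trend + d_res * pmax(disp_mom, 0)) /
    (prior_df + d_res)
  disp <- pmax(disp, 1e-8)
  ka <- rowSums(counts[, ia, drop = FALSE])
  kb <- rowSums(counts[, ib, drop = FALSE])
  sa <- sum(sf[ia])
  sb <- sum(sf[ib])
  sa2 <- sum(sf[ia]^2)
  sb2 <- sum(sf[ib]^2)
  p <- vapply(seq_len(nrow(counts)), function(g) {
    .nb_conditional_p(ka[g], kb[g], sa, sb, sa2, sb2, disp[g])
  }, numeric(1))
  fc <- (mean_b + pseudo_count) / (mean_a + pseudo_count)
  res <- data.frame(
    gene = if (!is.null(rownames(counts))) rownames(counts) else
      sprintf("gene%05d", seq_len(nrow(counts))),
    base_mean = base_mean,
    fc = fc,
    log2_fc = log2(fc),
    dispersion = disp,
    p = p,
    padj = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  class(res) <- c("de_result", "data.frame")
  res
}

# Conditional two-sided NB test: given kt = ka + kb, enumerate splits
# (a, kt - a), score each by the product of NB probabilities of the two
# condition sums under the pooled concentration estimate, and sum the
# probabilities of splits no more likely than the observed one. The
# enumeration window covers +/- 20 combined standard deviations around
# the expected split (plus the observed value); mass outside is
# negligible at double precision.
.nb_conditional_p <- function(ka, kb, sa, sb, sa2, sb2, alpha) {
  kt <- ka + kb
  if (kt == 0) return(1)
  q0 <- kt / (sa + sb)
  mu_a <- q0 * sa
  mu_b <- q0 * sb
  var_a <- mu_a + alpha * q0^2 * sa2
  var_b <- mu_b + alpha * q0^2 * sb2
  size_a <- if (var_a > mu_a) mu_a^2 / (var_a - mu_a) else 1e12
  size_b <- if (var_b > mu_b) mu_b^2 / (var_b - mu_b) else 1e12
  center <- round(kt * sa / (sa + sb))
  hw <- ceiling(20 * sqrt(var_a + var_b)) + 10
  ks <- max(0, center - hw):min(kt, center + hw)
  if (!(ka %in% ks)) ks <- sort(unique(c(ks, max(0, ka - 2):min(kt, ka + 2))))
  lp <- stats::dnbinom(ks, mu = mu_a, size = size_a, log = TRUE) +
    stats::dnbinom(kt - ks, mu = mu_b, size = size_b, log = TRUE)
  lp_obs <- lp[match(ka, ks)]
  pp <- exp(lp - max(lp))
  min(1, sum(pp[lp <= lp_obs + 1e-7]) / sum(pp))
}

#' Classify differential expression results
#'
#' Applies the expression filters: a gene is `up` when
#' `padj < alpha`, fold change `>= min_fc` and base mean `>= min_base_mean`;
#' `down` when `padj < alpha`, fold change `<= 1 / min_fc` and base mean
#' `>= min_base_mean`; `low_expression` whenever base mean
#' `< min_base_mean` (weakly expressed in both conditions, removed from
#' the DE list); otherwise `unchanged`.
#'
#' @param results a `de_result` from [test_differential()].
#' @param alpha adjusted p-value cutoff.
#' @param min_fc fold-change cutoff (applied to `fc` and `1 / fc`).
#' @param min_base_mean base-mean floor below which genes are removed.
#' @return the input with a `class` column added.
#' @export
classify_de <- function(results, alpha = 0.05, min_fc = 2.5,
                        min_base_mean = 200) {
  stopifnot(all(c("padj", "fc", "base_mean") %in% names(results)))
  cls <- rep("unchanged", nrow(results))
  sig <- results$padj < alpha & results$base_mean >= min_base_mean
  cls[sig & results$fc >= min_fc] <- "up"
  cls[sig & results$fc <= 1 / min_fc] <- "down"
  cls[results$base_mean < min_base_mean] <- "low_expression"
  results$class <- cls
  results
}

#' Rank the most active genes by length-corrected counts
#'
#' Sorts genes by raw count divided by exon-union gene length
#' (descending) and returns the top `n`; rate ties break by gene
#' identifier so the ranking is deterministic.
#'
#' @param counts named numeric vector of per-gene raw counts (e.g. the
#'   wild-type sample sums), or a `count_table` whose row sums are used.
#' @param gene_lengths named numeric vector of exon-union lengths (> 0).
#' @param n number of genes to return.
#' @return character vector of the `n` most active gene ids.
#' @export
rank_top_active <- function(counts, gene_lengths, n = 2500) {
  if (inherits(counts, "count_table")) counts <- rowSums(counts$counts)
  gene_lengths <- gene_lengths[names(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("every counted gene needs a positive length")
  }
  if (n > length(counts)) {
    warning(sprintf("requested top %d of %d genes; returning all",
                    n, length(counts)))
    n <- length(counts)
  }
  rate <- counts / gene_lengths
  names(counts)[order(-rate, names(counts))][seq_len(n)]
}
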