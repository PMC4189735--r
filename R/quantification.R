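#' qPCR abundance table helpers
#'
#' The quantification operations consume long-format tables of
#' linear-scale relative abundances with columns `target`, `sample`,
#' `role`, `abundance` (and optionally `replicate`). Cycle-threshold
#' values can be converted with [ct_to_abundance()].
#'
#' @param ct numeric Ct values.
#' @param efficiency amplification efficiency per cycle (2 = perfect
#'   doubling; no standard-curve calibration is modelled).
#' @return linear-scale abundances `efficiency^(-ct)`.
#' @export
ct_to_abundance <- function(ct, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  efficiency^(-ct)
}

# Mean abundance for (target, sample, role); errors with the missing
# row's name, as every reference lookup must.
.qpcr_lookup <- function(table, target, sample, role = NULL) {
  sel <- table$target == target & table$sample == sample
  if (!is.null(role) && !is.null(table$role)) sel <- sel & table$role == role
  if (!any(sel)) {
    stop(sprintf("missing qPCR row: target '%s', sample '%s'%s", target,
                 sample, if (is.null(role)) "" else sprintf(" (%s)", role)))
  }
  mean(table$abundance[sel])
}

#' ChIP-qPCR fold enrichment
#'
#' Double-ratio enrichment relative to input DNA and a control region:
#' `(IP_target / Input_target) / (IP_control / Input_control)` per
#' sample. Invariant to any per-sample global scaling of abundances,
#' which is what the double normalization exists to provide.
#'
#' @param table qPCR table with columns `target`, `sample`, `role`
#'   (`"ip"` rows are immunoprecipitated DNA, `"input"` rows input DNA),
#'   `abundance`. Replicate rows sharing those keys are averaged.
#' @param target amplicon of interest.
#' @param control_region control (e.g. intergenic) amplicon.
#' @param samples samples to evaluate; defaults to all in the table.
#' @return named numeric vector of fold enrichments per sample.
#' @export
chip_fold_enrichment <- function(table, target, control_region,
                                 samples = unique(table$sample)) {
  vapply(stats::setNames(samples, samples), function(s) {
    ip_t <- .qpcr_lookup(table, target, s, "ip")
    in_t <- .qpcr_lookup(table, target, s, "input")
    ip_c <- .qpcr_lookup(table, control_region, s, "ip")
    in_c <- .qpcr_lookup(table, control_region, s, "input")
    (ip_t / in_t) / (ip_c / in_c)
  }, numeric(1))
}

#' Spike-in-normalized fold induction
#'
#' Absolute-quantification arithmetic: per sample, transcript abundance
#' is normalized to an exogenous spike-in standard (default ERCC-00074,
#' constant copies added per sample), then expressed as fold induction
#' over the baseline (untreated) sample:
#' `(abundance(g, s) / abundance(ref, s)) /
#'  (abundance(g, baseline) / abundance(ref, baseline))`.
#'
#' @param table qPCR table (`target`, `sample`, `abundance`, optional
#'   `role`).
#' @param gene transcript of interest.
#' @param reference spike-in target name.
#' @param baseline_sample sample defining fold induction 1.
#' @param samples samples to evaluate; defaults to all in the table.
#' @return named numeric vector of fold inductions per sample.
#' @export
spikein_fold_induction <- function(table, gene, reference = "ERCC-00074",
                                   baseline_sample,
                                   samples = unique(table$sample)) {
  norm <- vapply(stats::setNames(samples, samples), function(s) {
    ref <- .qpcr_lookup(table, reference, s)
    if (ref <= 0) stop(sprintf("spike-in '%s' non-positive in sample '%s'",
                               reference, s))
    .qpcr_lookup(table, gene, s) / ref
  }, numeric(1))
  ref0 <- .qpcr_lookup(table, reference, baseline_sample)
  base <- .qpcr_lookup(table, gene, baseline_sample) / ref0
  norm / base
}

#' Splicing-product fraction
#'
#' Fraction of total transcript represented by one splicing product,
#' with total RNA detected by 3' UTR primers:
#' `abundance(product) / abundance(total)` per sample. Per-sample global
#' scalings cancel.
#'
#' @param table qPCR table (`target`, `sample`, `abundance`).
#' @param product splicing-product amplicon.
#' @param total total-RNA (3' UTR) amplicon name.
#' @param samples samples to evaluate; defaults to all in the table.
#' @return named numeric vector of fractions per sample.
#' @export
splice_product_fraction <- function(table, product, total = "total_3utr",
                                    samples = unique(table$sample)) {
  vapply(stats::setNames(samples, samples), function(s) {
    tot <- .qpcr_lookup(table, total, s)
    if (tot <= 0) stop(sprintf("total abundance non-positive in sample '%s'", s))
    .qpcr_lookup(table, product, s) / tot
  }, numeric(1))
}

#' Summarize replicate qPCR measurements
#'
#' Mean and standard deviation of abundance over replicate rows sharing
#' `(target, sample, role)`.
#'
#' @param table qPCR table with a `replicate` column.
#' @return data.frame with `target`, `sample`, `role`, `mean_abundance`,
#'   `sd_abundance`, `n`.
#' @export
summarize_qpcr_replicates <- function(table) {
  if (is.null(table$role)) table$role <- "target"
  key <- interaction(table$target, table$sample, table$role, drop = TRUE)
  agg <- do.call(rbind, lapply(split(table, key), function(d) {
    data.frame(
      target = d$target[1], sample = d$sample[1], role = d$role[1],
      mean_abundance = mean(d$abundance),
      sd_abundance = if (nrow(d) > 1) stats::sd(d$abundance) else NA_real_,
      n = nrow(d), stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  agg
}
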