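#' Default pipeline configuration
#'
#' Builds the configuration for an end-to-end synthetic run emulating a
#' two-genotype (wild-type vs Cfp1-null) by two-treatment (untreated vs
#' doxorubicin) design with two biological replicates per condition:
#' promoter-mark ChIP samples with matched input controls, stranded
#' paired-end RNA-seq with low-abundance divergent antisense
#' transcription at TSS and TES, and qPCR validation panels. Every field
#' can be overridden; seeds are explicit so reruns are byte-identical.
#'
#' The condition effects encode the study's qualitative structure: the
#' treatment induces one gene subset and represses another (identically
#' in both genotypes), the null genotype has strongly reduced promoter
#' ChIP enrichment, and its antisense fractions at TSS/TES are elevated.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master integer seed; stage seeds derive from it.
#' @param ... named overrides of any top-level config field.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(out_dir = "results/pipeline",
                                    seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    genome = list(
      chrom_sizes = c(chr1 = 1200000, chr2 = 800000),
      n_genes = 200,
      gene_length_range = c(2000, 6000),
      intergenic_gap_range = c(1500, 4000)
    ),
    design = list(
      genotypes = c("WT", "cfp1_null"),
      treatments = c("untreated", "doxo"),
      n_replicates = 2,
      frac_up = 0.15, frac_down = 0.10,
      fc_up = 6, fc_down = 1 / 6
    ),
    chip = list(
      total_fragments = 100000,
      background_rate = 0.001,
      peak_shape = 500,
      fragment_length = 200,
      # apex fold enrichment over background by genotype and treatment
      amplitude = list(
        WT = list(untreated = 8, doxo = 14),
        cfp1_null = list(untreated = 2, doxo = 3)
      )
    ),
    rna = list(
      total_fragments = 150000,
      fragment_length = 200,
      antisense_span = 1000,
      antisense_fraction = list(WT = 0.02, cfp1_null = 0.06),
      expression_meanlog = log(100), expression_sdlog = 1
    ),
    analysis = list(
      window = 100, slide = 20, flank = 3000,
      k = 5, alpha = 0.05, min_fc = 2.5, min_base_mean = 200,
      n_top = 50
    ),
    qpcr = list(noise_cv = 0.05, n_replicates = 3, spikein_copies = c(
      "ERCC-00074" = 5000, "ERCC-00096" = 800, "ERCC-00130" = 12000
    )),
    include_chip = TRUE,
    include_rna = TRUE,
    include_qpcr = TRUE
  )
  utils::modifyList(cfg, list(...))
}

#' Read / write a pipeline configuration
#'
#' Plain YAML round-trip of the configuration list, with seeds explicit.
#'
#' @param path YAML file.
#' @param config a `pipeline_config` list.
#' @return `read_pipeline_config` returns the config list;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$genome$chrom_sizes <- unlist(cfg$genome$chrom_sizes)
  cfg$qpcr$spikein_copies <- unlist(cfg$qpcr$spikein_copies)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  # named atomic vectors must become maps, not bare sequences, in YAML
  config$genome$chrom_sizes <- as.list(config$genome$chrom_sizes)
  config$qpcr$spikein_copies <- as.list(config$qpcr$spikein_copies)
  yaml::write_yaml(config, path)
  invisible(path)
}

# Stable hash of the configuration for output provenance.
.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

# TSV writer stamping provenance (config hash + master seed) as a leading
# comment so every output records how it was produced.
.write_tsv <- function(df, path, provenance) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(mat, path, provenance) {
  df <- data.frame(region = rownames(mat), unclass(mat)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path, provenance)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: annotation simulation; ChIP fragment simulation
#' per genotype x treatment (two replicates plus an input control),
#' uniqueness/duplicate filtering, replicate merging, coverage and
#' reads-per-million normalization with bedGraph output; RNA fragment
#' simulation, strand splitting, union-mode stranded counting, size
#' factors, negative-binomial differential testing and classification,
#' top-active ranking; sliding-window matrices, median profiles, k-means
#' heatmap ordering, and per-region density Wilcoxon comparisons at the
#' TSSs of upregulated genes (ChIP) and sense/antisense densities at
#' TSS/TES (RNA); and the qPCR fold-enrichment / spike-in fold-induction
#' / splice-fraction arithmetic. Outputs are TSV/bedGraph/GTF files under
#' `out_dir/{tracks,matrices,profiles,stats,de,report}`, each stamped
#' with the config hash and seed; identical configs produce byte-identical
#' outputs. Stages whose `include_*` flag is off are reported as skipped.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @return invisibly, a list with the main in-memory results (annotation,
#'   DE tables, density tests, report data.frame).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dirs <- file.path(config$out_dir,
                    c("tracks", "matrices", "profiles", "stats", "de",
                      "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("# metachip pipeline config_hash=%s seed=%d",
                  .config_hash(config), config$seed)
  report <- list()
  note <- function(stage, key, value) {
    report[[length(report) + 1]] <<- data.frame(
      stage = stage, key = key, value = as.character(value),
      stringsAsFactors = FALSE
    )
  }
  stage_log <- function(stage) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
  }

  # --- annotation -----------------------------------------------------
  stage_log("simulate: annotation")
  sim_cfg <- simulation_config(
    chrom_sizes = config$genome$chrom_sizes,
    n_genes = config$genome$n_genes,
    gene_length_range = config$genome$gene_length_range,
    intergenic_gap_range = config$genome$intergenic_gap_range,
    seed = config$seed
  )
  annotation <- simulate_annotation(sim_cfg)
  write_annotation_gtf(annotation, file.path(config$out_dir, "report",
                                             "annotation.gtf"))
  ng <- n_genes(annotation)
  note("simulate", "n_genes", ng)

  # condition effects: deterministic assignment of regulated gene subsets
  des <- config$design
  n_up <- round(des$frac_up * ng)
  n_down <- round(des$frac_down * ng)
  truth <- rep("null", ng)
  truth[seq_len(n_up)] <- "up"
  truth[n_up + seq_len(n_down)] <- "down"
  truth <- withr::with_seed(config$seed + 17L, sample(truth))
  names(truth) <- annotation$genes$gene_id
  fc_doxo <- ifelse(truth == "up", des$fc_up,
                    ifelse(truth == "down", des$fc_down, 1))
  note("simulate", "n_true_up", n_up)
  note("simulate", "n_true_down", n_down)

  anchors_tss <- build_anchors(annotation, "TSS",
                               flank = config$analysis$flank)
  anchors_tes <- build_anchors(annotation, "TES",
                               flank = config$analysis$flank)

  results <- list(annotation = annotation, truth = truth)

  # --- RNA stages: counting, DE, classification, top-active ----------
  de_by_genotype <- list()
  if (isTRUE(config$include_rna)) {
    stage_log("simulate: RNA fragments")
    level <- withr::with_seed(config$seed + 23L, stats::rlnorm(
      ng, meanlog = config$rna$expression_meanlog,
      sdlog = config$rna$expression_sdlog
    ))
    rna_sets <- list()
    meta <- list()
    si <- 0L
    for (gt in des$genotypes) {
      af <- config$rna$antisense_fraction[[gt]]
      spec <- rna_expression_spec(
        expression_level = level,
        antisense_fraction_tss = af, antisense_fraction_tes = af,
        antisense_span = config$rna$antisense_span,
        fold_changes = list(doxo = fc_doxo),
        fragment_length = config$rna$fragment_length
      )
      for (tr in des$treatments) {
        for (rep_i in seq_len(des$n_replicates)) {
          si <- si + 1L
          id <- sprintf("rna_%s_%s_rep%d", gt, tr, rep_i)
          rna_sets[[id]] <- simulate_rna_fragments(
            annotation, spec, condition = tr,
            total_fragments = config$rna$total_fragments,
            seed = config$seed + 100L + si, sample_id = id
          )
          meta[[id]] <- data.frame(sample = id, genotype = gt,
                                   treatment = tr, replicate = rep_i,
                                   stringsAsFactors = FALSE)
        }
      }
    }
    meta <- do.call(rbind, meta)

    stage_log("expression: counting and differential testing")
    tab <- build_count_table(rna_sets, annotation, metadata = meta)
    counts_df <- data.frame(gene = rownames(tab$counts), tab$counts,
                            check.names = FALSE)
    .write_tsv(counts_df, file.path(config$out_dir, "de", "counts.tsv"),
               prov)
    .write_tsv(data.frame(sample = rownames(tab$tallies), tab$tallies),
               file.path(config$out_dir, "de", "count_tallies.tsv"), prov)

    for (gt in des$genotypes) {
      sel <- meta$genotype == gt
      cond <- factor(meta$treatment[sel], levels = des$treatments)
      de <- test_differential(tab$counts[, meta$sample[sel], drop = FALSE],
                              cond)
      de <- classify_de(de, alpha = config$analysis$alpha,
                        min_fc = config$analysis$min_fc,
                        min_base_mean = config$analysis$min_base_mean)
      de_by_genotype[[gt]] <- de
      .write_tsv(de, file.path(config$out_dir, "de",
                               sprintf("de_%s.tsv", gt)), prov)
      note("de", sprintf("%s_up", gt), sum(de$class == "up"))
      note("de", sprintf("%s_down", gt), sum(de$class == "down"))
    }
    top <- rank_top_active(
      rowSums(tab$counts[, meta$sample[meta$genotype == "WT"], drop = FALSE]),
      gene_exon_lengths(annotation), n = config$analysis$n_top
    )
    writeLines(c(prov, top),
               file.path(config$out_dir, "de", "top_active_genes.txt"))
    note("de", "n_top_active", length(top))
    results$count_table <- tab
    results$de <- de_by_genotype
    results$top_active <- top
  } else {
    note("de", "status", "skipped (include_rna = FALSE)")
  }

  up_genes <- if (length(de_by_genotype) > 0) {
    de_by_genotype$WT$gene[de_by_genotype$WT$class == "up"]
  } else {
    names(truth)[truth == "up"]
  }
  if (length(up_genes) == 0) up_genes <- anchors_tss$label
  up_tss <- anchors_tss[anchors_tss$label %in% up_genes, ]
  attr(up_tss, "flank") <- config$analysis$flank
  up_tes <- anchors_tes[anchors_tes$label %in% up_genes, ]
  attr(up_tes, "flank") <- config$analysis$flank

  # --- ChIP stages ----------------------------------------------------
  if (isTRUE(config$include_chip)) {
    stage_log("chip: simulate, filter, merge, coverage")
    chip_tracks <- list()
    si <- 0L
    for (gt in des$genotypes) {
      for (tr in des$treatments) {
        amp_base <- config$chip$amplitude[[gt]][[tr]]
        # enrichment concentrates at regulated promoters upon treatment
        amp <- ifelse(truth == "up" & tr == des$treatments[2],
                      amp_base * 1.5, amp_base)
        spec <- chip_enrichment_spec(
          background_rate = config$chip$background_rate,
          peak_amplitude = amp, peak_shape = config$chip$peak_shape,
          fragment_length = config$chip$fragment_length
        )
        reps <- lapply(seq_len(des$n_replicates), function(rep_i) {
          si <<- si + 1L
          filter_fragments(simulate_chip_fragments(
            annotation, spec,
            total_fragments = config$chip$total_fragments,
            seed = config$seed + 500L + si,
            sample_id = sprintf("chip_%s_%s_rep%d", gt, tr, rep_i)
          ))
        })
        merged <- merge_replicates(reps)
        track <- normalize_track(compute_coverage(merged))
        id <- sprintf("chip_%s_%s", gt, tr)
        chip_tracks[[id]] <- track
        write_track_bedgraph(track, file.path(config$out_dir, "tracks",
                                              paste0(id, ".bedGraph")))
        note("chip", paste0(id, "_library_size"), track$library_size)
      }
      si <- si + 10L
      input_spec <- chip_enrichment_spec(
        background_rate = config$chip$background_rate,
        peak_amplitude = 0, peak_shape = config$chip$peak_shape,
        fragment_length = config$chip$fragment_length
      )
      input <- filter_fragments(simulate_chip_fragments(
        annotation, input_spec,
        total_fragments = config$chip$total_fragments,
        seed = config$seed + 900L + si,
        sample_id = sprintf("input_%s", gt)
      ))
      chip_tracks[[sprintf("input_%s", gt)]] <-
        normalize_track(compute_coverage(input))
    }

    stage_log("chip: window matrices, profiles, heatmap ordering")
    mats <- lapply(chip_tracks, compute_window_matrix, regions = up_tss,
                   window = config$analysis$window,
                   slide = config$analysis$slide)
    ref_id <- sprintf("chip_WT_%s", des$treatments[2])
    k_use <- min(config$analysis$k, nrow(mats[[ref_id]]))
    ordering <- cluster_and_order(mats[[ref_id]], k = k_use,
                                  seed = config$seed + 41L)
    for (id in names(mats)) {
      .write_matrix_tsv(apply_ordering(mats[[id]], ordering),
                        file.path(config$out_dir, "matrices",
                                  paste0(id, "_tss.tsv")), prov)
      .write_tsv(average_profile(mats[[id]]),
                 file.path(config$out_dir, "profiles",
                           paste0(id, "_tss_profile.tsv")), prov)
    }
    note("chip", "heatmap_k", k_use)
    note("chip", "n_profiled_regions", nrow(mats[[ref_id]]))

    stage_log("chip: densities and Wilcoxon comparisons")
    dens <- lapply(names(chip_tracks), function(id) {
      region_density(chip_tracks[[id]], up_tss, group = id)
    })
    names(dens) <- names(chip_tracks)
    dens_df <- do.call(rbind, dens)
    .write_tsv(dens_df, file.path(config$out_dir, "stats",
                                  "chip_tss_density.tsv"), prov)
    cmp <- list()
    for (tr in des$treatments) {
      a <- dens[[sprintf("chip_%s_%s", des$genotypes[1], tr)]]
      b <- dens[[sprintf("chip_%s_%s", des$genotypes[2], tr)]]
      ht <- compare_density_groups(a, b)
      cmp[[tr]] <- data.frame(
        comparison = sprintf("%s_vs_%s_%s", des$genotypes[1],
                             des$genotypes[2], tr),
        n = ht$n, m = ht$m, statistic = ht$statistic, p = ht$p.value,
        method = ht$method, stringsAsFactors = FALSE
      )
    }
    chip_tests <- do.call(rbind, cmp)
    .write_tsv(chip_tests, file.path(config$out_dir, "stats",
                                     "chip_density_tests.tsv"), prov)
    results$chip_tracks <- chip_tracks
    results$chip_density_tests <- chip_tests
  } else {
    note("chip", "status", "skipped (include_chip = FALSE)")
  }

  # --- RNA strand-split profiles and antisense contrast --------------
  if (isTRUE(config$include_rna)) {
    stage_log("rna: strand-split sense/antisense densities")
    sense_dens <- list()
    anti_dens <- list()
    for (gt in des$genotypes) {
      tr <- des$treatments[2]
      ids <- sprintf("rna_%s_%s_rep%d", gt, tr, seq_len(des$n_replicates))
      merged <- merge_replicates(rna_sets[ids])
      halves <- split_by_strand(merged)
      for (h in names(halves)) halves[[h]] <- normalize_track(halves[[h]])
      write_track_bedgraph(halves$plus,
                           file.path(config$out_dir, "tracks",
                                     sprintf("rna_%s_%s_plus.bedGraph",
                                             gt, tr)))
      write_track_bedgraph(halves$minus,
                           file.path(config$out_dir, "tracks",
                                     sprintf("rna_%s_%s_minus.bedGraph",
                                             gt, tr)))
      sd_list <- strand_densities(halves, up_tss)
      sense_dens[[gt]] <- sd_list$sense
      anti_dens[[gt]] <- sd_list$antisense
      for (kind in c("sense", "antisense")) {
        mat <- compute_window_matrix(
          strand_track(halves, up_tss, kind), up_tss,
          window = config$analysis$window, slide = config$analysis$slide
        )
        .write_tsv(average_profile(mat),
                   file.path(config$out_dir, "profiles",
                             sprintf("rna_%s_%s_%s_tss_profile.tsv",
                                     gt, tr, kind)), prov)
      }
    }
    ht_anti <- compare_density_groups(anti_dens[[des$genotypes[1]]],
                                      anti_dens[[des$genotypes[2]]])
    ht_sense <- compare_density_groups(sense_dens[[des$genotypes[1]]],
                                       sense_dens[[des$genotypes[2]]])
    rna_tests <- data.frame(
      comparison = c("antisense_tss", "sense_tss"),
      n = c(ht_anti$n, ht_sense$n), m = c(ht_anti$m, ht_sense$m),
      statistic = c(ht_anti$statistic, ht_sense$statistic),
      p = c(ht_anti$p.value, ht_sense$p.value),
      method = c(ht_anti$method, ht_sense$method),
      stringsAsFactors = FALSE
    )
    .write_tsv(rna_tests, file.path(config$out_dir, "stats",
                                    "rna_density_tests.tsv"), prov)
    note("rna", "antisense_tss_p", format(ht_anti$p.value, digits = 4))
    note("rna", "sense_tss_p", format(ht_sense$p.value, digits = 4))
    results$rna_density_tests <- rna_tests
  }

  # --- qPCR arithmetic ------------------------------------------------
  if (isTRUE(config$include_qpcr)) {
    stage_log("qpcr: enrichment, fold induction, splice fractions")
    qp <- .simulate_qpcr_stage(config)
    .write_tsv(qp$tables$rt, file.path(config$out_dir, "stats",
                                       "qpcr_rt_panel.tsv"), prov)
    .write_tsv(qp$tables$chip, file.path(config$out_dir, "stats",
                                         "qpcr_chip_panel.tsv"), prov)
    .write_tsv(qp$results, file.path(config$out_dir, "stats",
                                     "qpcr_results.tsv"), prov)
    results$qpcr <- qp$results
    note("qpcr", "n_measurements", nrow(qp$results))
  } else {
    note("qpcr", "status", "skipped (include_qpcr = FALSE)")
  }

  report_df <- do.call(rbind, report)
  .write_tsv(report_df, file.path(config$out_dir, "report", "summary.tsv"),
             prov)
  stage_log(sprintf("done in %.1f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  results$report <- report_df
  invisible(results)
}

# qPCR validation stage: truth tables mirroring the validation assays —
# an induced transcript quantified absolutely against spike-ins, a ChIP
# enrichment panel, and splicing products against a 3' UTR total.
.simulate_qpcr_stage <- function(config) {
  samples <- c("WT_untreated", "WT_doxo", "null_untreated", "null_doxo")
  rt_truth <- data.frame(
    target = rep("induced_gene", 4),
    sample = samples,
    abundance = c(50, 600, 55, 480), # copies; induction in both genotypes
    role = "target", stringsAsFactors = FALSE
  )
  rt <- simulate_qpcr_panel(rt_truth,
                            spikein_copies = config$qpcr$spikein_copies,
                            noise_cv = config$qpcr$noise_cv,
                            seed = config$seed + 71L,
                            n_replicates = config$qpcr$n_replicates)
  fi <- lapply(c(WT = "WT", null = "null"), function(gt) {
    spikein_fold_induction(rt, "induced_gene",
                           baseline_sample = paste0(gt, "_untreated"),
                           samples = paste0(gt, c("_untreated", "_doxo")))
  })
  chip_truth <- do.call(rbind, lapply(seq_along(samples), function(i) {
    enr <- c(8, 14, 2, 2.5)[i] # promoter IP/input over control ratio 1
    data.frame(
      target = rep(c("promoter", "intergenic_ctrl"), each = 2),
      sample = samples[i],
      role = rep(c("ip", "input"), 2),
      abundance = c(enr * 0.02, 0.02, 0.015, 0.015),
      stringsAsFactors = FALSE
    )
  }))
  chip_panel <- simulate_qpcr_panel(chip_truth, noise_cv = config$qpcr$noise_cv,
                                    seed = config$seed + 72L,
                                    n_replicates = config$qpcr$n_replicates)
  enr <- chip_fold_enrichment(chip_panel, "promoter", "intergenic_ctrl")
  splice_truth <- data.frame(
    target = rep(c("spliced_e2e3", "unspliced_i2", "total_3utr"), 4),
    sample = rep(samples, each = 3),
    abundance = rep(c(40, 4, 50), 4) * rep(c(1, 8, 1, 7.5), each = 3),
    role = rep(c("target", "target", "total_3utr"), 4),
    stringsAsFactors = FALSE
  )
  splice_panel <- simulate_qpcr_panel(splice_truth,
                                      noise_cv = config$qpcr$noise_cv,
                                      seed = config$seed + 73L,
                                      n_replicates = config$qpcr$n_replicates)
  frac <- splice_product_fraction(splice_panel, "spliced_e2e3")
  res <- rbind(
    data.frame(assay = "spikein_fold_induction",
               sample = c(names(fi$WT), names(fi$null)),
               value = c(fi$WT, fi$null), stringsAsFactors = FALSE),
    data.frame(assay = "chip_fold_enrichment", sample = names(enr),
               value = enr, stringsAsFactors = FALSE),
    data.frame(assay = "splice_fraction_e2e3", sample = names(frac),
               value = frac, stringsAsFactors = FALSE)
  )
  rownames(res) <- NULL
  list(tables = list(rt = rt, chip = chip_panel, splice = splice_panel),
       results = res)
}

#' Sense/antisense densities around oriented anchors
#'
#' Given strand-split tracks and an oriented anchor set, computes the
#' per-region density of the sense signal (the strand matching each
#' region's orientation) and the antisense signal (the opposite strand).
#'
#' @param halves list with `plus` and `minus` `coverage_track`s.
#' @param regions an `anchor_set`.
#' @return list of two `density_summary` objects, `sense` and
#'   `antisense`.
#' @export
strand_densities <- function(halves, regions) {
  plus_d <- region_density(halves$plus, regions)
  minus_d <- region_density(halves$minus, regions)
  is_plus <- regions$orientation == "+"
  sense <- plus_d
  sense$density <- ifelse(is_plus, plus_d$density, minus_d$density)
  antis <- plus_d
  antis$density <- ifelse(is_plus, minus_d$density, plus_d$density)
  list(sense = sense, antisense = antis)
}

# A pseudo-track holding, per chromosome, the strand-matched ("sense") or
# strand-opposed ("antisense") signal for profiling: regions on + read the
# corresponding strand's track directly. Used only for profile output; the
# per-region selection happens row-wise.
strand_track <- function(halves, regions, kind = c("sense", "antisense")) {
  kind <- match.arg(kind)
  # Build a combined track whose values at each region's bases come from
  # the appropriate strand. Regions are disjoint in practice (anchors 3 kb
  # apart); overlapping regions would take the last write.
  base <- halves$plus
  out <- base$cov
  flank <- attr(regions, "flank")
  for (i in seq_len(nrow(regions))) {
    want_plus <- (regions$orientation[i] == "+") == (kind == "sense")
    src <- if (want_plus) halves$plus$cov else halves$minus$cov
    chrom <- regions$chrom[i]
    a <- regions$anchor[i]
    lo <- max(1, a - flank + 1)
    hi <- min(length(out[[chrom]]), a + flank + 1)
    v <- as.numeric(S4Vectors::window(src[[chrom]], lo, hi))
    out[[chrom]][lo:hi] <- v
  }
  base$cov <- out
  base
}
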