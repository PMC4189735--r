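#!/usr/bin/env Rscript
# Stage 2 — promoter occupancy profiling: per-condition ChIP coverage
# (replicates merged, reads-per-million normalized), 100 bp / 20 bp
# sliding-window matrices in a 3 kb flank around the TSSs of the
# treatment-induced genes, median average profiles, a k-means-ordered
# heatmap ordering from the WT treated sample, and per-region density
# comparisons between genotypes (two-tailed unpaired Wilcoxon).

source("analysis/00_common.R")

up_tss <- build_anchors(ANNOTATION, "TSS", flank = CONFIG$analysis$flank)
up_tss <- up_tss[up_tss$label %in% names(TRUTH)[TRUTH == "up"], ]
attr(up_tss, "flank") <- CONFIG$analysis$flank
message(sprintf("profiling %d induced-gene TSS regions", nrow(up_tss)))

tracks <- list()
si <- 0L
for (gt in CONFIG$design$genotypes) {
  for (tr in CONFIG$design$treatments) {
    amp_base <- CONFIG$chip$amplitude[[gt]][[tr]]
    amp <- ifelse(TRUTH == "up" & tr == "doxo", amp_base * 1.5, amp_base)
    spec <- chip_enrichment_spec(
      background_rate = CONFIG$chip$background_rate, peak_amplitude = amp,
      peak_shape = CONFIG$chip$peak_shape,
      fragment_length = CONFIG$chip$fragment_length
    )
    reps <- lapply(1:2, function(r) {
      si <<- si + 1L
      filter_fragments(simulate_chip_fragments(
        ANNOTATION, spec, CONFIG$chip$total_fragments,
        seed = SEED + 500L + si
      ))
    })
    tracks[[paste(gt, tr, sep = "_")]] <-
      normalize_track(compute_coverage(merge_replicates(reps)))
  }
}

mats <- lapply(tracks, compute_window_matrix, regions = up_tss,
               window = CONFIG$analysis$window,
               slide = CONFIG$analysis$slide)
ordering <- cluster_and_order(mats$WT_doxo,
                              k = min(CONFIG$analysis$k, nrow(mats$WT_doxo)),
                              seed = SEED + 41L)

profiles <- do.call(rbind, lapply(names(mats), function(id) {
  p <- average_profile(mats[[id]])
  p$sample <- id
  p
}))
write_summary(profiles, "02_chip_tss_profiles.tsv")

peaks <- do.call(rbind, lapply(names(mats), function(id) {
  p <- average_profile(mats[[id]])
  data.frame(sample = id, peak_position = p$position[which.max(p$value)],
             peak_median_rpm = round(max(p$value), 3))
}))
message("median-profile maxima (position relative to TSS):")
print(peaks, row.names = FALSE)

tests <- do.call(rbind, lapply(CONFIG$design$treatments, function(tr) {
  ht <- compare_density_groups(
    region_density(tracks[[paste0("WT_", tr)]], up_tss),
    region_density(tracks[[paste0("cfp1_null_", tr)]], up_tss)
  )
  data.frame(treatment = tr, n = ht$n, m = ht$m,
             statistic = ht$statistic, p = signif(ht$p.value, 4))
}))
message("WT vs Cfp1-null H3K4me3 density at induced TSSs:")
print(tests, row.names = FALSE)
write_summary(tests, "02_chip_density_wilcoxon.tsv")
write_summary(data.frame(rank = seq_along(ordering$order),
                         region = rownames(mats$WT_doxo)[ordering$order],
                         cluster = ordering$clusters[ordering$order]),
              "02_heatmap_row_order.tsv")
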