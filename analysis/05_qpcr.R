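#!/usr/bin/env Rscript
# Stage 5 — validation-assay arithmetic on simulated qPCR panels:
# ChIP-qPCR fold enrichment (double ratio over input DNA and a control
# intergenic region), spike-in-normalized absolute quantification
# expressed as fold induction over the untreated sample, and splicing-
# product fractions against a 3' UTR total.

source("analysis/00_common.R")

samples <- c("WT_untreated", "WT_doxo", "null_untreated", "null_doxo")

rt_truth <- data.frame(
  target = "induced_gene", sample = samples,
  abundance = c(50, 600, 55, 480), role = "target"
)
rt <- simulate_qpcr_panel(rt_truth,
                          spikein_copies = CONFIG$qpcr$spikein_copies,
                          noise_cv = CONFIG$qpcr$noise_cv, seed = SEED + 71L,
                          n_replicates = CONFIG$qpcr$n_replicates)
fi <- c(
  spikein_fold_induction(rt, "induced_gene", baseline_sample = "WT_untreated",
                         samples = samples[1:2]),
  spikein_fold_induction(rt, "induced_gene",
                         baseline_sample = "null_untreated",
                         samples = samples[3:4])
)

chip_truth <- do.call(rbind, lapply(seq_along(samples), function(i) {
  enr <- c(8, 14, 2, 2.5)[i]
  data.frame(target = rep(c("promoter", "intergenic_ctrl"), each = 2),
             sample = samples[i], role = rep(c("ip", "input"), 2),
             abundance = c(enr * 0.02, 0.02, 0.015, 0.015))
}))
chip_panel <- simulate_qpcr_panel(chip_truth, noise_cv = CONFIG$qpcr$noise_cv,
                                  seed = SEED + 72L,
                                  n_replicates = CONFIG$qpcr$n_replicates)
enr <- chip_fold_enrichment(chip_panel, "promoter", "intergenic_ctrl")

splice_truth <- data.frame(
  target = rep(c("spliced_e2e3", "unspliced_i2", "total_3utr"), 4),
  sample = rep(samples, each = 3),
  abundance = rep(c(40, 4, 50), 4) * rep(c(1, 8, 1, 7.5), each = 3),
  role = rep(c("target", "target", "total_3utr"), 4)
)
splice_panel <- simulate_qpcr_panel(splice_truth,
                                    noise_cv = CONFIG$qpcr$noise_cv,
                                    seed = SEED + 73L,
                                    n_replicates = CONFIG$qpcr$n_replicates)
frac <- splice_product_fraction(splice_panel, "spliced_e2e3")

res <- rbind(
  data.frame(assay = "spikein_fold_induction", sample = names(fi),
             value = round(unname(fi), 3)),
  data.frame(assay = "chip_fold_enrichment", sample = names(enr),
             value = round(unname(enr), 3)),
  data.frame(assay = "splice_fraction_e2e3", sample = names(frac),
             value = round(unname(frac), 3))
)
message("validation-assay results (noise CV ",
        CONFIG$qpcr$noise_cv, ", ", CONFIG$qpcr$n_replicates,
        " replicate wells):")
print(res, row.names = FALSE)
write_summary(res, "05_qpcr_results.tsv")
message("fold induction tracks the simulated truth (12x / ~8.7x); ",
        "splice fractions are stable across induction")
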