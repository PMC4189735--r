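#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study: genome annotation, one ChIP
# sample with its input control, and one stranded RNA sample, written in
# their standard formats (GTF / 6-column BED) so later stages can be run
# from files as well as in memory.

source("analysis/00_common.R")

message(sprintf("annotation: %d genes on %d chromosomes", NG,
                length(ANNOTATION$chrom_sizes)))
write_annotation_gtf(ANNOTATION, file.path(SCRATCH, "annotation.gtf"))

chip_spec <- chip_enrichment_spec(
  background_rate = CONFIG$chip$background_rate,
  peak_amplitude = CONFIG$chip$amplitude$WT$untreated,
  peak_shape = CONFIG$chip$peak_shape,
  fragment_length = CONFIG$chip$fragment_length
)
chip <- simulate_chip_fragments(ANNOTATION, chip_spec,
                                CONFIG$chip$total_fragments, seed = SEED + 1L,
                                sample_id = "chip_WT_untreated_rep1")
write_fragments_bed(chip, file.path(SCRATCH, "chip_WT_untreated_rep1.bed"))

input_spec <- chip_enrichment_spec(
  background_rate = CONFIG$chip$background_rate, peak_amplitude = 0,
  peak_shape = CONFIG$chip$peak_shape,
  fragment_length = CONFIG$chip$fragment_length
)
input <- simulate_chip_fragments(ANNOTATION, input_spec,
                                 CONFIG$chip$total_fragments, seed = SEED + 2L,
                                 sample_id = "input_WT")
write_fragments_bed(input, file.path(SCRATCH, "input_WT.bed"))

rna <- simulate_rna_sample("WT", "doxo", 1, offset = 1L)
write_fragments_bed(rna, file.path(SCRATCH, "rna_WT_doxo_rep1.bed"))

summary_df <- data.frame(
  quantity = c("n_genes", "n_true_up", "n_true_down",
               "chip_fragments", "rna_fragments",
               "rna_sense_fraction", "rna_antisense_tss_fraction"),
  value = c(NG, sum(TRUTH == "up"), sum(TRUTH == "down"),
            length(chip), length(rna),
            round(mean(rna$category == "sense"), 4),
            round(mean(rna$category == "antisense_tss"), 4))
)
print(summary_df, row.names = FALSE)
write_summary(summary_df, "01_simulation_summary.tsv")
message("Simulated inputs written; fragment files live under ", SCRATCH)
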