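# Shared study design for the numbered analysis scripts: a two-genotype
# (WT vs Cfp1-null) x two-treatment (untreated vs doxorubicin) synthetic
# dataset, two replicates per condition. Each script sources this file,
# runs one analysis stage with the metachip package, and writes small
# summary tables under results/analysis/ (bulky intermediates go to
# scratch/).

suppressMessages(library(metachip))

SEED <- 1L
RESULTS <- "results/analysis"
SCRATCH <- "scratch/analysis"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)

CONFIG <- default_pipeline_config(out_dir = SCRATCH, seed = SEED)

ANNOTATION <- simulate_annotation(simulation_config(
  chrom_sizes = CONFIG$genome$chrom_sizes,
  n_genes = CONFIG$genome$n_genes,
  gene_length_range = CONFIG$genome$gene_length_range,
  intergenic_gap_range = CONFIG$genome$intergenic_gap_range,
  seed = SEED
))

# per-gene regulation truth, matching run_pipeline()'s assignment
NG <- n_genes(ANNOTATION)
n_up <- round(CONFIG$design$frac_up * NG)
n_down <- round(CONFIG$design$frac_down * NG)
TRUTH <- rep("null", NG)
TRUTH[seq_len(n_up)] <- "up"
TRUTH[n_up + seq_len(n_down)] <- "down"
TRUTH <- withr::with_seed(SEED + 17L, sample(TRUTH))
names(TRUTH) <- ANNOTATION$genes$gene_id
FC_DOXO <- ifelse(TRUTH == "up", CONFIG$design$fc_up,
                  ifelse(TRUTH == "down", CONFIG$design$fc_down, 1))

EXPRESSION_LEVEL <- withr::with_seed(SEED + 23L, stats::rlnorm(
  NG, meanlog = CONFIG$rna$expression_meanlog,
  sdlog = CONFIG$rna$expression_sdlog
))

rna_spec_for <- function(genotype) {
  af <- CONFIG$rna$antisense_fraction[[genotype]]
  rna_expression_spec(
    expression_level = EXPRESSION_LEVEL,
    antisense_fraction_tss = af, antisense_fraction_tes = af,
    antisense_span = CONFIG$rna$antisense_span,
    fold_changes = list(doxo = FC_DOXO),
    fragment_length = CONFIG$rna$fragment_length
  )
}

simulate_rna_sample <- function(genotype, treatment, replicate, offset) {
  simulate_rna_fragments(
    ANNOTATION, rna_spec_for(genotype), condition = treatment,
    total_fragments = CONFIG$rna$total_fragments,
    seed = SEED + 100L + offset,
    sample_id = sprintf("rna_%s_%s_rep%d", genotype, treatment, replicate)
  )
}

write_summary <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
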