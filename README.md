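# metachip

Quantitative analysis of promoter chromatin marks and divergent antisense
transcription, built as a reusable R package plus a set of numbered
analysis scripts. The workflow reproduces, on synthetic data emulating a
two-genotype (wild-type vs Cfp1-null) × two-treatment (untreated vs
doxorubicin) mouse ES cell study design, the standard computational
pipeline behind promoter ChIP-seq / stranded RNA-seq papers:

- **Coverage**: fragment filtering (uniquely aligned, duplicates removed),
  replicate merging, per-base pile-up, normalization to reads per million
  mapped fragments, strand splitting by paired-end fragment strand.
- **Metagene profiling**: sliding-window occupancy matrices (mean signal
  per base in 100 bp windows every 20 bp across ±3 kb of TSS/TES/region
  centres, oriented 5'→3'), median average profiles, k-means-ordered
  heatmaps where the ordering of a reference sample is applied verbatim to
  all companions, and per-region densities compared with two-tailed
  unpaired Wilcoxon rank-sum tests (exact when `min(n, m) ≤ 8` and
  tie-free).
- **Expression**: strand-aware union-mode counting over exon unions,
  median-of-ratios size factors
  `s_j = median_g (K_gj / (∏_j K_gj)^{1/m})`, a negative-binomial
  differential test (method-of-moments dispersion shrunk toward a
  mean–dispersion trend; two-sided conditional test on per-condition count
  sums given the gene total), Benjamini–Hochberg adjustment, and the
  classification filters padj < 0.05, fold change ≥ 2.5, base mean ≥ 200,
  plus ranking of the most active genes by length-corrected counts.
- **Quantification arithmetic**: ChIP-qPCR fold enrichment
  `(IP_t/Input_t)/(IP_c/Input_c)`, ERCC spike-in absolute normalization
  with fold induction relative to the untreated sample, and
  splicing-product fractions over a 3' UTR total — all invariant to
  per-sample global scalings.
- **Synthetic data**: a first-class generator for gene annotations,
  ChIP fragment sets with triangular TSS-anchored enrichment over uniform
  background, stranded RNA fragment sets with tunable divergent antisense
  fractions at TSS/TES, and noisy qPCR panels with spike-ins — so every
  stage is testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the study end to end and print
their findings; `Rscript analysis/04_antisense.R` contrasts sense and
antisense read densities at induced genes in the treated samples:

```
WT vs Cfp1-null read density at induced genes (treated samples):
 anchor    signal  n  m median_wt median_null         p
    TSS     sense 30 30     316.0       297.0 0.6520000
    TSS antisense 30 30      16.5        36.4 0.0055700
    TES     sense 30 30     332.0       307.0 0.5692000
    TES antisense 30 30      14.0        37.3 0.0002531
```

Antisense density at both TSSs and TESs of the 30 induced genes is two- to
three-fold higher in the Cfp1-null genotype and separates clearly by
Wilcoxon, while sense output (matched by construction) does not — the
signature the strand-split density machinery exists to detect. The other
scripts report promoter occupancy profiles (stage 2; median profile maxima
near the TSS, reduced ~2.4-fold in the null genotype), DE classification
against simulation truth (stage 3; sensitivity 0.84 at zero observed FDR
under the padj/fold-change/base-mean filters), and the validation-assay
arithmetic (stage 5; fold inductions of 11.7 and 8.0 versus simulated
truths of 12 and ~8.7).

The same end-to-end run is available as one call:

```r
library(metachip)
res <- run_pipeline(default_pipeline_config(out_dir = "out", seed = 1))
res$report
```

Outputs (bedGraph tracks, window matrices, profiles, density tests, DE
tables, qPCR results) land under `out/{tracks,matrices,profiles,stats,de,report}`,
each stamped with the config hash and seed; identical configs reproduce
byte-identical files.

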