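Package: metachip
Title: Metagene Occupancy Profiling, Strand-Aware Expression and qPCR
    Arithmetic for Promoter Chromatin Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for promoter chromatin mark and
    antisense transcription analysis: normalized ChIP-seq coverage tracks,
    sliding-window occupancy matrices around TSS/TES anchors, median
    average profiles and k-means-ordered heatmaps, per-region density
    statistics with Wilcoxon comparisons, strand-aware union-mode gene
    counting with negative-binomial differential expression
    classification, ChIP-qPCR fold enrichment and ERCC spike-in
    normalization arithmetic, and a synthetic-data generator emulating a
    two-genotype by two-treatment stranded paired-end study design so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    withr,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
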