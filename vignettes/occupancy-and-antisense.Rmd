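---
title: "Methods: promoter occupancy profiling and antisense transcription analysis"
author: "metachip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter occupancy profiling and antisense transcription analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metachip)
```

# Scope and model

metachip implements the quantitative core of a promoter-chromatin study:
how much of a histone mark (H3K4me3, H3K9ac) sits around transcription
start sites under different genotypes and treatments, whether that
occupancy differs between groups of regions, how treatment changes gene
expression, and how much low-abundance divergent antisense RNA is made at
the starts and ends of genes. All computation operates on *fragments* —
deduplicated, uniquely aligned paired-end fragment intervals — not raw
reads; mapping artifacts, base qualities and alignment itself are out of
scope. Internal coordinates are 0-based half-open everywhere; conversion
to 1-based inclusive happens only at the GTF boundary.

## Coverage and normalization

Coverage at base $b$ is the number of fragment intervals containing $b$
(`compute_coverage()`, piled up with `IRanges` run-length encodings). The
source convention "normalized to the total number of uniquely mapped
reads" fixes normalization only up to a constant, so the package uses
reads per million: every value is scaled by $10^6 / \text{library size}$
and the factor is recorded on the track. Because every downstream
statistic (window means, densities, profiles) is linear in the track,
any alternative constant yields identical comparative results; tests
assert this linearity. Strand-split tracks share the merged library size
so sense and antisense signal remain on one scale, and they sum to the
unsplit track exactly at every base.

Duplicate removal operates at fragment level on the key
(chromosome, start, end, strand) — no sequence access is needed — and
uniqueness is a per-record flag set by the aligner or simulator.
Replicate merging is concatenation; library sizes add.

## Window matrices, profiles, densities

Occupancy around anchors uses mean signal per base in 100 bp windows
advanced every 20 bp across a ±3 kb flank (the defaults; all three are
config-surfaced). Windows start at $-\text{flank}$ and advance while they
fit, giving $(2 \cdot 3000 - 100)/20 + 1 = 296$ columns with no partial
windows. For minus-strand anchors the per-base signal is read 3'→5'
genomically, so relative coordinate $+x$ always means $x$ bases
downstream of the anchor in transcription direction; TSS of a minus gene
$[s, e)$ is $e - 1$, its TES is $s$. Anchors whose full interval leaves
the chromosome are dropped (not zero-padded, which would dilute signal
artificially) and the count is logged.

Average profiles are per-window **medians** across regions — robust to
the handful of extreme promoters that dominate means. Box-plot-style
per-region densities are the mean per-base signal over the full interval;
on the full window grid this differs from a mean of windows only at the
grid edges, and the per-base definition was chosen as the more elementary
one. Group comparisons are two-tailed unpaired Wilcoxon rank-sum tests
through `stats::wilcox.test`: the exact null distribution when
$\min(n, m) \le 8$ with no ties, otherwise the normal approximation with
tie and continuity corrections. The test suite validates the exact path
against full enumeration of assignments for all $n, m \le 6$ and bounds
the approximation against enumeration at $n = m = 8$.

Heatmap ordering mimics the classic Cluster-3.0-then-apply-everywhere
recipe: Euclidean k-means (fixed seed, 10 restarts) on a reference
matrix, clusters displayed by descending mean signal, rows within a
cluster by descending row mean with label tie-breaks, and the resulting
permutation applied verbatim to companion matrices. Neither $k$ nor the
display order is canonical in the field; $k$ defaults to 5 and both are
config-surfaced rather than inferred.

## Expression analysis

Counting is union-mode and stranded: a fragment counts for a gene iff it
overlaps the gene's exon union on the gene's strand; overlaps with two or
more same-strand genes are ambiguous and discarded; exon-free or
wrong-strand fragments are tallied separately, and the four tallies sum
to the input count by construction. Fragments count once (paired-end
data at fragment resolution).

Size factors are median-of-ratios: $s_j = \mathrm{median}_g\,
K_{gj} / (\prod_j K_{gj})^{1/m}$ over genes with nonzero counts in every
sample. The differential test is a self-contained negative-binomial
procedure in the spirit of the classic count-based DE tools:

1. per-gene method-of-moments dispersion
   $\hat\alpha_g = (w_g - \bar q_g \overline{1/s}) / \bar q_g^2$, where
   $w_g$ is the pooled within-condition variance of normalized counts
   (shot noise subtracted), floored at $10^{-8}$;
2. a mean–dispersion trend fitted by local regression of the **raw**
   $\hat\alpha_g$ on $\log \bar q_g$. At two residual degrees of freedom
   the per-gene estimates are extremely skewed, so any log- or
   median-based fit is biased low — fitting on the raw scale keeps the
   trend mean-unbiased, and negative moment estimates stay in the fit for
   the same reason. Degenerate mean ranges fall back to the global mean;
3. linear shrinkage $\alpha_g = (d_0 \alpha_{trend} + d\,
   \max(\hat\alpha_g, 0)) / (d_0 + d)$ with prior weight $d_0 = 10$
   against the residual df $d = n - 2$; again raw-scale so the
   combination stays mean-unbiased at tiny $d$. The suite verifies the
   resulting type-I error (0.03–0.07 at nominal 0.05 on 5,000-gene null
   simulations with dispersion 0.1 and two replicates per condition);
4. a conditional two-sided test: given a gene's total count, the
   per-condition sums are negative binomials with matched mean and
   variance under the null of equal concentration, and the p-value sums
   the probabilities of all splits no likelier than the observed one
   (enumeration windowed to ±20 combined standard deviations; omitted
   mass is negligible at double precision). This test is deliberately
   conditional on the pooled mean, which makes it conservative under
   strong alternatives; a cross-check test shows its gene *ranking*
   agrees with DESeq2's Wald test at Spearman > 0.95 on planted data
   while absolute p-values are smaller in magnitude.

Fold change is the ratio of size-factor-normalized condition means with a
pseudo-count of 1 (zero handling is not specified by the upstream
convention; raw normalized ratios are used, not shrunken ones).
Classification applies padj < 0.05 (Benjamini–Hochberg), fold change
≥ 2.5 (or ≤ 1/2.5), and removes genes with base mean < 200 as weakly
expressed; the classes partition the gene set. The most active genes are
ranked by raw count divided by exon-union length, ties broken by gene
identifier for determinism.

## qPCR and spike-in arithmetic

Three small-number operations, all invariant to per-sample global
scalings (the property their normalization exists to provide, asserted
under 100 random scalings in the tests): double-ratio ChIP enrichment
$(\mathrm{IP}_t/\mathrm{Input}_t)/(\mathrm{IP}_c/\mathrm{Input}_c)$;
spike-in-normalized abundance $(g,s) \mapsto a_{gs}/a_{\mathrm{ref},s}$
(reference ERCC-00074) expressed as fold induction over the untreated
baseline; and splicing-product fractions over a 3' UTR total. Inputs are
linear-scale relative abundances; `ct_to_abundance()` converts cycle
thresholds assuming perfect doubling (efficiency 2), since no
standard-curve calibration is modelled. The exact arithmetic behind
"fold enrichment relative to input DNA and a control region" is not
written down as a formula anywhere authoritative; the double ratio is the
standard reading and is documented as such.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: two
genotypes × two treatments × two biological replicates; promoter-mark
ChIP samples with matched input controls; stranded paired-end RNA with
divergent antisense at TSS/TES; qPCR panels with constant-copy
spike-ins.

**ChIP fragments** are drawn from a mixture of a genome-wide uniform
background (`background_rate` fragments/bp, default 0.001) and per-gene
peaks whose fragment-midpoint density decays as a symmetric triangle over
±`peak_shape` (default 500 bp) around the anchor. No peak shape is
canonical — only TSS-proximal enrichment is — and the triangle is the
simplest shape with finite, analytic mass (`amplitude × rate ×
half-width` fragments per gene), which the tests exploit. Enrichment
magnitudes are nowhere stated in the source material, so the defaults
(apex fold enrichment 8–14 in wild type, 2–3 in the null genotype, 1.5×
extra at treatment-induced promoters) are calibration choices surfaced in
the config, chosen to produce clearly visible but not saturated signal.

**RNA fragments**: each gene has an expected sense mass (default
log-normal across genes, meanlog $\log 100$, sdlog 1 — a realistic
breadth of expression); fractions `antisense_fraction_tss` / `_tes` of
its mass are emitted on the opposite strand, starting within
`antisense_span` (1 kb) upstream of the TSS / downstream of the TES,
matching divergent initiation. Realized per-category counts are one
multinomial draw, so totals are conserved exactly. Condition effects are
multiplicative per-gene fold changes (default: 15% of genes up 6-fold,
10% down 6-fold upon treatment, identical in both genotypes; antisense
fractions 2% in wild type vs 6% in the null genotype). Fragment length
is fixed at 200 bp.

**qPCR panels** apply mean-preserving multiplicative log-normal noise
(`meanlog` offset by $-\sigma^2/2$) so the expected measured abundance
equals the truth — which the spike-in normalization then cancels.

What the generator does **not** emulate: sequence content, mappability,
GC bias, fragment-length variation, duplicate and multi-mapping
structure, splice-junction reads, intron signal, batch effects, or
dispersion trends with expression. Passing tests therefore demonstrate
the *arithmetic and statistical machinery* is correct under the stated
generative model, not that the pipeline is robust to every artifact of
real sequencing data.

# Determinism and numerical choices

Every stochastic operation takes an explicit seed and draws through
`withr::with_seed`, so identical configs yield byte-identical outputs —
the end-to-end pipeline run is tested for byte equality across reruns,
and each output file carries the config MD5 and seed in a comment header.
Window means are computed by row cumulative sums (exact for the
integer-valued unnormalized tracks, and matching a per-base brute-force
oracle exactly in the tests). K-means ties and rank ties break by row
label; top-active ties break by gene identifier. Degenerate inputs are
errors, not guesses: empty density groups, zero library sizes,
out-of-bounds fragments (named in the message), annotations without
exons, `k` exceeding the row count, and single-replicate DE designs all
fail loudly.

# Problem sizes

The default synthetic study uses a 2 Mb two-chromosome genome with 200
genes, 100k ChIP fragments and 150k RNA fragments per sample — enough for
~30 detected induced genes, clear promoter profiles, and a decisive
antisense contrast, while a full pipeline run takes well under a minute.
Statistical calibration checks use 5,000-gene null count tables over five
seeds and 2,000-gene planted-change tables over three seeds; the
antisense contrast check uses 500 genes. These sizes were chosen so the
whole suite exercises every claim at comfortable statistical resolution.

# Known limitations

- The DE test requires two replicates per condition and exactly two
  conditions; single-replicate designs need a pooled-dispersion mode that
  is intentionally not provided.
- The conditional NB test is conservative for strongly changed genes;
  rankings are robust but absolute p-values undercall relative to Wald
  tests.
- Coverage uses whole fragment intervals; read extension to a fixed
  length is available upstream of `compute_coverage()` only by adjusting
  fragment intervals, not as a dedicated option.
- Peak calling is out of scope: non-promoter region sets are inputs, as
  they are in the studies this workflow mirrors.
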