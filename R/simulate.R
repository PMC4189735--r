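#' ChIP enrichment specification
#'
#' Parameters of the fragment mixture a ChIP sample is drawn from: a
#' genome-wide uniform background plus, for each gene, a symmetric
#' triangular peak of fragment-midpoint density centred on the anchor
#' (TSS by default). `peak_amplitude` is the fold enrichment of the peak
#' apex over background, so a gene's peak mass is
#' `background_rate * peak_amplitude * peak_shape` fragments (triangle
#' area with base `2 * peak_shape`).
#'
#' @param background_rate expected background fragments per bp.
#' @param peak_amplitude scalar or per-gene vector of apex fold
#'   enrichments over background; 0 yields a pure background (input) sample.
#' @param peak_shape half-width of the triangular peak in bp.
#' @param anchor `"TSS"` or a `GRanges` whose midpoints anchor the peaks.
#' @param fragment_length emitted fragment length in bp.
#' @return object of class `chip_enrichment_spec`.
#' @export
chip_enrichment_spec <- function(background_rate = 0.001,
                                 peak_amplitude = 10,
                                 peak_shape = 500,
                                 anchor = "TSS",
                                 fragment_length = 200) {
  if (any(peak_amplitude < 0)) stop("peak_amplitude must be >= 0")
  if (peak_shape <= 0) stop("peak_shape (half-width) must be positive")
  if (background_rate <= 0) stop("background_rate must be positive")
  if (fragment_length <= 0) stop("fragment_length must be positive")
  structure(
    list(
      background_rate = background_rate, peak_amplitude = peak_amplitude,
      peak_shape = peak_shape, anchor = anchor,
      fragment_length = as.integer(fragment_length)
    ),
    class = "chip_enrichment_spec"
  )
}

#' RNA expression specification
#'
#' Expected per-gene sense fragment masses plus the fractions of each
#' gene's mass emitted as short divergent antisense fragments just
#' upstream of the TSS and just downstream of the TES (on the strand
#' opposite the gene), emulating the low-abundance divergent
#' transcription seen at active mammalian promoters and terminators.
#'
#' @param expression_level per-gene expected sense fragment mass
#'   (recycled if scalar).
#' @param antisense_fraction_tss,antisense_fraction_tes fraction of a
#'   gene's fragment mass emitted antisense at the TSS / TES, in `[0, 1]`.
#' @param antisense_span bp window the antisense fragments start in
#'   (upstream of TSS, downstream of TES).
#' @param fold_changes named list: condition label -> scalar or per-gene
#'   multiplicative fold change (> 0) applied to that condition's masses.
#'   Conditions absent from the list get fold change 1.
#' @param fragment_length emitted fragment length in bp.
#' @return object of class `rna_expression_spec`.
#' @export
rna_expression_spec <- function(expression_level = 100,
                                antisense_fraction_tss = 0.02,
                                antisense_fraction_tes = 0.02,
                                antisense_span = 1000,
                                fold_changes = list(),
                                fragment_length = 200) {
  fr <- c(antisense_fraction_tss, antisense_fraction_tes)
  if (any(fr < 0) || any(fr > 1) || sum(fr[1] + fr[2]) > 1) {
    stop("antisense fractions must lie in [0, 1] and sum to at most 1")
  }
  if (any(expression_level < 0)) stop("expression levels must be >= 0")
  if (any(unlist(fold_changes) <= 0)) stop("fold changes must be positive")
  if (antisense_span <= 0) stop("antisense_span must be positive")
  structure(
    list(
      expression_level = expression_level,
      antisense_fraction_tss = antisense_fraction_tss,
      antisense_fraction_tes = antisense_fraction_tes,
      antisense_span = as.integer(antisense_span),
      fold_changes = fold_changes,
      fragment_length = as.integer(fragment_length)
    ),
    class = "rna_expression_spec"
  )
}

# Build a fragment GRanges from 0-based midpoints, clipping to chromosome.
.fragments_from_midpoints <- function(chrom, mid, strand, chrom_sizes,
                                      fragment_length, sample_id) {
  half <- fragment_length / 2
  start0 <- pmax(0, round(mid - half))
  end0 <- pmin(chrom_sizes[chrom], start0 + fragment_length)
  start0 <- pmin(start0, end0 - 1)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start0 + 1, end0), strand = strand,
    seqlengths = chrom_sizes
  )
  gr$duplicate <- FALSE
  gr$unique <- TRUE
  gr$sample <- sample_id
  gr
}

#' Simulate ChIP-seq fragments
#'
#' Draws `total_fragments` fragment intervals from the background +
#' per-anchor triangular enrichment mixture of `spec`. Component masses
#' are background `rate * genome_length` and, per gene,
#' `rate * amplitude * half_width`; each fragment picks its component
#' multinomially, then its midpoint uniformly (background) or
#' triangularly around the anchor (peak). Fragment strand is assigned at
#' random, as in an unstranded ChIP library. An input-control sample is
#' the same call with `peak_amplitude = 0`.
#'
#' @param annotation a `gene_annotation`.
#' @param spec a [chip_enrichment_spec()].
#' @param total_fragments number of fragments to emit (> 0).
#' @param seed integer seed.
#' @param sample_id label stored on each fragment.
#' @return `GRanges` of fragments with `duplicate`, `unique`, `sample`
#'   metadata columns.
#' @export
simulate_chip_fragments <- function(annotation, spec, total_fragments,
                                    seed = 1L, sample_id = "chip") {
  stopifnot(inherits(spec, "chip_enrichment_spec"))
  if (total_fragments <= 0) stop("total_fragments must be positive")
  withr::with_seed(seed, {
    cs <- annotation$chrom_sizes
    if (methods::is(spec$anchor, "GRanges")) {
      anc_chrom <- as.character(GenomeInfoDb::seqnames(spec$anchor))
      anc_pos <- floor((BiocGenerics::start(spec$anchor) - 1 +
                          BiocGenerics::end(spec$anchor)) / 2)
    } else {
      anchors <- build_anchors(annotation, "TSS", flank = 0)
      anc_chrom <- anchors$chrom
      anc_pos <- anchors$anchor
    }
    n_anc <- length(anc_pos)
    amp <- rep_len(spec$peak_amplitude, n_anc)
    bg_mass <- spec$background_rate * sum(as.numeric(cs))
    peak_mass <- spec$background_rate * amp * spec$peak_shape
    mass <- c(bg_mass, peak_mass)
    comp <- sample.int(n_anc + 1L, total_fragments, replace = TRUE,
                       prob = mass / sum(mass)) - 1L # 0 = background
    n_bg <- sum(comp == 0L)
    chrom <- character(total_fragments)
    mid <- numeric(total_fragments)
    if (n_bg > 0) {
      bg_chrom <- sample(names(cs), n_bg, replace = TRUE,
                         prob = as.numeric(cs) / sum(as.numeric(cs)))
      chrom[comp == 0L] <- bg_chrom
      mid[comp == 0L] <- floor(stats::runif(n_bg) * cs[bg_chrom])
    }
    pk <- which(comp > 0L)
    if (length(pk) > 0) {
      idx <- comp[pk]
      chrom[pk] <- anc_chrom[idx]
      # triangular offset on [-h, h]: sum of two uniforms
      off <- spec$peak_shape *
        (stats::runif(length(pk)) + stats::runif(length(pk)) - 1)
      mid[pk] <- pmax(0, pmin(cs[anc_chrom[idx]] - 1, anc_pos[idx] + off))
    }
    strand <- sample(c("+", "-"), total_fragments, replace = TRUE)
    .fragments_from_midpoints(chrom, mid, strand, cs,
                              spec$fragment_length, sample_id)
  })
}

#' Simulate stranded RNA-seq fragments
#'
#' Emits `total_fragments` fragments with paired-end fragment-strand
#' semantics. Each gene contributes three categories: sense fragments on
#' the gene strand placed within the exon union, divergent antisense
#' fragments starting in the `antisense_span` upstream of the TSS, and
#' divergent antisense fragments starting in the span downstream of the
#' TES (both on the opposite strand). Category masses are
#' `level * fold_change(condition)` split as
#' `(1 - f_tss - f_tes, f_tss, f_tes)`; realized counts are one
#' multinomial draw over all categories, so counts sum exactly to
#' `total_fragments`.
#'
#' @param annotation a `gene_annotation`.
#' @param spec an [rna_expression_spec()].
#' @param condition condition label, looked up in `spec$fold_changes`.
#' @param total_fragments fragments to emit.
#' @param seed integer seed.
#' @param sample_id label stored on each fragment.
#' @return `GRanges` with `duplicate`, `unique`, `sample`, `origin`
#'   (source gene) and `category` (`sense`/`antisense_tss`/`antisense_tes`)
#'   metadata columns.
#' @export
simulate_rna_fragments <- function(annotation, spec, condition,
                                   total_fragments, seed = 1L,
                                   sample_id = condition) {
  stopifnot(inherits(spec, "rna_expression_spec"))
  if (total_fragments <= 0) stop("total_fragments must be positive")
  ng <- n_genes(annotation)
  if (ng == 0) stop("annotation holds no genes")
  level <- rep_len(spec$expression_level, ng)
  fc <- spec$fold_changes[[condition]]
  fc <- if (is.null(fc)) rep(1, ng) else rep_len(fc, ng)
  mass <- level * fc
  f_tss <- spec$antisense_fraction_tss
  f_tes <- spec$antisense_fraction_tes
  cat_mass <- c(mass * (1 - f_tss - f_tes), mass * f_tss, mass * f_tes)
  if (sum(cat_mass) <= 0) stop("total expression mass is zero")
  withr::with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, total_fragments,
                                         cat_mass / sum(cat_mass)))
    genes <- annotation$genes
    gchrom <- as.character(GenomeInfoDb::seqnames(genes))
    gstrand <- as.character(BiocGenerics::strand(genes))
    anti <- ifelse(gstrand == "+", "-", "+")
    tss <- build_anchors(annotation, "TSS", flank = 0)
    tes <- build_anchors(annotation, "TES", flank = 0)
    cs <- annotation$chrom_sizes
    red <- IRanges::reduce(annotation$exons)[genes$gene_id]
    exlen <- sum(IRanges::width(red))

    # sense: fragment start offsets drawn uniformly in exon-union
    # coordinates, then mapped back to the genome per gene
    n_sense <- counts[seq_len(ng)]
    g_s <- rep.int(seq_len(ng), n_sense)
    pos0_s <- numeric(length(g_s))
    for (g in which(n_sense > 0)) {
      sel <- g_s == g
      ex <- red[[g]]
      off <- floor(stats::runif(n_sense[g]) * exlen[g])
      cum <- cumsum(IRanges::width(ex))
      j <- findInterval(off, c(0, cum), rightmost.closed = FALSE)
      pos0_s[sel] <- BiocGenerics::start(ex)[j] - 1 + (off - c(0, cum)[j])
    }

    # antisense: upstream of TSS / downstream of TES, gene-opposite strand
    anc_pos <- c(tss$anchor, tes$anchor)
    n_anti <- counts[ng + seq_len(2L * ng)]
    idx_a <- rep.int(seq_len(2L * ng), n_anti)
    g_a <- (idx_a - 1L) %% ng + 1L
    at_tss <- idx_a <= ng
    left <- xor(!at_tss, gstrand[g_a] == "+")
    lo <- ifelse(left, anc_pos[idx_a] - spec$antisense_span,
                 anc_pos[idx_a] + 1)
    pos0_a <- pmax(0, pmin(cs[gchrom[g_a]] - 1,
                           lo + floor(stats::runif(length(g_a)) *
                                        spec$antisense_span)))

    gi <- c(g_s, g_a)
    out <- .fragments_from_midpoints(
      gchrom[gi], c(pos0_s, pos0_a) + spec$fragment_length / 2,
      c(gstrand[g_s], anti[g_a]), cs, spec$fragment_length, sample_id
    )
    out$origin <- genes$gene_id[gi]
    out$category <- c(rep("sense", length(g_s)),
                      ifelse(at_tss, "antisense_tss", "antisense_tes"))
    out
  })
}

#' Simulate a qPCR abundance panel
#'
#' Applies per-well multiplicative lognormal noise of coefficient of
#' variation `noise_cv` to a table of true transcript abundances, and
#' appends spike-in rows whose true abundance is constant across
#' conditions (the property absolute normalization relies on). The noise
#' is mean-preserving: `meanlog` is offset by `-sdlog^2 / 2` so the
#' expected measured abundance equals the truth.
#'
#' @param true_abundances data.frame with columns `target`, `sample`,
#'   `abundance` (> 0) and optionally `role` (defaults to `"target"`).
#' @param spikein_copies named numeric vector of spike-in abundances
#'   (one row per spike-in per sample is appended), e.g.
#'   `c("ERCC-00074" = 5000)`.
#' @param noise_cv coefficient of variation of the lognormal well noise;
#'   0 returns the truth exactly.
#' @param seed integer seed.
#' @param n_replicates technical replicate wells per row.
#' @return data.frame with columns `target`, `sample`, `role`,
#'   `replicate`, `abundance`.
#' @export
simulate_qpcr_panel <- function(true_abundances, spikein_copies = numeric(),
                                noise_cv = 0.1, seed = 1L,
                                n_replicates = 1L) {
  stopifnot(is.data.frame(true_abundances),
            all(c("target", "sample", "abundance") %in%
                  names(true_abundances)))
  if (any(true_abundances$abundance <= 0)) stop("abundances must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  tab <- true_abundances
  if (is.null(tab$role)) tab$role <- "target"
  samples <- unique(tab$sample)
  if (length(spikein_copies) > 0) {
    sp <- expand.grid(target = names(spikein_copies), sample = samples,
                      stringsAsFactors = FALSE)
    sp$abundance <- spikein_copies[sp$target]
    sp$role <- "spikein"
    tab <- rbind(tab[c("target", "sample", "abundance", "role")],
                 sp[c("target", "sample", "abundance", "role")])
  }
  tab <- tab[rep(seq_len(nrow(tab)), each = n_replicates), ]
  tab$replicate <- rep(seq_len(n_replicates), length.out = nrow(tab))
  withr::with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      tab$abundance <- tab$abundance *
        stats::rlnorm(nrow(tab), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tab
  })
  rownames(tab) <- NULL
  tab[c("target", "sample", "role", "replicate", "abundance")]
}
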