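#' Gene annotation container
#'
#' Bundles gene models (a `GRanges` of gene bodies with strand and
#' `gene_id`), their exon structure (a `GRangesList` named by gene), and the
#' chromosome sizes the models live on. All internal coordinates are
#' 0-based half-open; conversion to 1-based inclusive happens only at the
#' GTF boundary.
#'
#' @param genes `GRanges` with a `gene_id` metadata column and defined
#'   strand. Coordinates 0-based half-open are expressed as IRanges
#'   `start = start0 + 1`, `end = end0` (the usual GRanges convention).
#' @param exons `GRangesList` named by `gene_id`, exons within gene bounds.
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, chrom_sizes) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRangesList"))
  if (is.null(genes$gene_id)) stop("genes must carry a gene_id column")
  if (!all(names(exons) %in% genes$gene_id)) {
    stop("exon list names must be gene ids")
  }
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  GenomeInfoDb::seqlevels(genes) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(genes) <- chrom_sizes
  structure(
    list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "gene_annotation: %d genes on %d chromosome(s) (%s bp total)\n",
    length(x$genes), length(x$chrom_sizes),
    format(sum(as.numeric(x$chrom_sizes)), big.mark = ",")
  ))
  invisible(x)
}

#' Number of genes in an annotation
#' @param annotation a `gene_annotation`.
#' @return integer count.
#' @export
n_genes <- function(annotation) length(annotation$genes)

#' Exon-union length per gene
#'
#' Total non-redundant exonic bases per gene, the denominator used when
#' ranking genes by length-corrected read counts.
#'
#' @param annotation a `gene_annotation`.
#' @return named numeric vector of exon-union lengths in bp.
#' @export
gene_exon_lengths <- function(annotation) {
  red <- IRanges::reduce(annotation$exons)
  len <- sum(IRanges::width(red))
  len[annotation$genes$gene_id]
}

#' Write an annotation as GTF
#'
#' Emits `gene` and `exon` features, 1-based inclusive, with `gene_id`
#' attributes, via rtracklayer.
#'
#' @param annotation a `gene_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  g <- annotation$genes
  g$type <- "gene"
  ex <- unlist(annotation$exons)
  ex$gene_id <- names(ex)
  names(ex) <- NULL
  ex$type <- "exon"
  all <- c(g, ex)
  all$source <- "metachip"
  rtracklayer::export(sort(all), path, format = "gtf")
  invisible(path)
}

#' Read an annotation from GTF
#'
#' Inverse of [write_annotation_gtf()]: rebuilds the `gene_annotation`
#' container from `gene`/`exon` features. Chromosome sizes must be given
#' (GTF does not carry them).
#'
#' @param path GTF file.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return a `gene_annotation`.
#' @export
read_annotation_gtf <- function(path, chrom_sizes) {
  gr <- rtracklayer::import(path, format = "gtf")
  genes <- gr[gr$type == "gene"]
  genes <- genes[order(genes$gene_id)]
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = genes$gene_id)
  ex <- gr[gr$type == "exon"]
  S4Vectors::mcols(ex) <- NULL
  exons <- GenomicRanges::split(ex, gr$gene_id[gr$type == "exon"])
  gene_annotation(genes, exons[genes$gene_id], chrom_sizes)
}

#' Simulation configuration for genome annotation
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @param n_genes number of genes to place.
#' @param gene_length_range length-2 interval of gene lengths in bp.
#' @param intergenic_gap_range length-2 interval of gaps between genes (bp).
#' @param seed integer seed making placement reproducible.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(chrom_sizes,
                              n_genes,
                              gene_length_range = c(2000, 10000),
                              intergenic_gap_range = c(1000, 5000),
                              seed = 1L) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)))
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  if (n_genes < 0) stop("n_genes must be non-negative")
  stopifnot(length(gene_length_range) == 2, length(intergenic_gap_range) == 2)
  if (any(gene_length_range <= 0) || any(intergenic_gap_range < 0)) {
    stop("length ranges must be positive")
  }
  structure(
    list(
      chrom_sizes = chrom_sizes, n_genes = as.integer(n_genes),
      gene_length_range = sort(gene_length_range),
      intergenic_gap_range = sort(intergenic_gap_range),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate a gene annotation
#'
#' Places non-overlapping gene models with random strand and 1-5 exons on
#' the configured chromosomes. Genes are laid out left to right with
#' random intergenic gaps; exon/intron widths partition each gene body so
#' the first exon starts at the gene start and the last ends at the gene
#' end. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return a `gene_annotation`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_annotation_impl(config))
}

.simulate_annotation_impl <- function(config) {
  cs <- config$chrom_sizes
  ng <- config$n_genes
  empty <- GenomicRanges::GRanges(seqlengths = cs)
  empty$gene_id <- character(0)
  if (ng == 0) {
    return(gene_annotation(empty, GenomicRanges::GRangesList(), cs))
  }
  # apportion genes to chromosomes by length
  share <- as.numeric(cs) / sum(as.numeric(cs))
  per_chrom <- diff(round(cumsum(c(0, share)) * ng))
  names(per_chrom) <- names(cs)
  gid <- sprintf("gene%05d", seq_len(ng))
  rows <- list()
  i <- 0L
  for (chrom in names(cs)) {
    pos <- 0 # 0-based cursor
    for (k in seq_len(per_chrom[[chrom]])) {
      gap <- round(stats::runif(1, config$intergenic_gap_range[1],
                                config$intergenic_gap_range[2]))
      len <- round(stats::runif(1, config$gene_length_range[1],
                                config$gene_length_range[2]))
      start <- pos + gap
      if (start + len > cs[[chrom]]) {
        stop(sprintf(
          "placement error: chromosome %s (%d bp) cannot hold gene %d of %d",
          chrom, cs[[chrom]], k, per_chrom[[chrom]]
        ))
      }
      i <- i + 1L
      rows[[i]] <- list(
        chrom = chrom, start = start, end = start + len,
        strand = sample(c("+", "-"), 1), gene_id = gid[i]
      )
      pos <- start + len
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  genes <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1, df$end),
    strand = df$strand, gene_id = df$gene_id, seqlengths = cs
  )
  exons <- .simulate_exons(genes)
  gene_annotation(genes, exons, cs)
}

# Partition each gene body into alternating exon/intron segments; exon count
# 1-5, first/last segments are exons, all segments at least 50 bp (or the
# whole gene when too short for the drawn structure).
.simulate_exons <- function(genes) {
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    len <- IRanges::width(g)
    nex <- sample(1:5, 1)
    nseg <- 2L * nex - 1L
    if (len < nseg * 50L) nex <- 1L
    if (nex == 1L) {
      out[[i]] <- GenomicRanges::granges(g)
      next
    }
    nseg <- 2L * nex - 1L
    w <- stats::runif(nseg)
    w <- pmax(50L, floor(w / sum(w) * len))
    w[nseg] <- len - sum(w[-nseg])
    if (w[nseg] < 50L) { # redistribute when rounding starves the last segment
      w <- rep(len %/% nseg, nseg)
      w[nseg] <- len - sum(w[-nseg])
    }
    ends <- cumsum(w)
    starts <- c(0, ends[-nseg])
    keep <- seq(1, nseg, by = 2)
    out[[i]] <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(g),
      IRanges::IRanges(BiocGenerics::start(g) + starts[keep],
                       BiocGenerics::start(g) + ends[keep] - 1),
      strand = BiocGenerics::strand(g)
    )
  }
  names(out) <- genes$gene_id
  GenomicRanges::GRangesList(out)
}
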