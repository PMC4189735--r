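#' Fragment filtering: uniqueness and duplicate removal
#'
#' Applies the read-selection policy used throughout the pipeline: keep
#' only uniquely aligned fragments, and optionally collapse duplicates,
#' defined at the fragment level as identical `(chrom, start, end,
#' strand)` tuples (no sequence access is needed for fragment-level
#' dedup). Counts of removed records are recorded in the result's
#' `S4Vectors::metadata()` as `n_removed_nonunique` and
#' `n_removed_duplicate`.
#'
#' @param records fragment `GRanges` with logical `unique` and
#'   `duplicate` metadata columns ( `unique` defaults to all-true when
#'   absent).
#' @param require_unique drop records with `unique = FALSE`.
#' @param remove_duplicates keep at most one record per
#'   `(chrom, start, end, strand)`.
#' @return filtered `GRanges` with removal-count attributes.
#' @export
filter_fragments <- function(records, require_unique = TRUE,
                             remove_duplicates = TRUE) {
  n0 <- length(records)
  if (require_unique && !is.null(records$unique)) {
    records <- records[records$unique]
  }
  n_nonuniq <- n0 - length(records)
  n1 <- length(records)
  if (remove_duplicates && n1 > 0) {
    key <- paste(GenomeInfoDb::seqnames(records),
                 BiocGenerics::start(records),
                 BiocGenerics::end(records),
                 BiocGenerics::strand(records))
    records <- records[!duplicated(key)]
  }
  S4Vectors::metadata(records)$n_removed_nonunique <- n_nonuniq
  S4Vectors::metadata(records)$n_removed_duplicate <- n1 - length(records)
  records
}

#' Merge replicate fragment sets
#'
#' Concatenates biological replicates into a single fragment set (the
#' merged-replicate policy used before profile computation); library
#' sizes add. Errors if the replicates disagree on the chromosome
#' universe.
#'
#' @param recordsets list of fragment `GRanges` sharing seqinfo.
#' @return one concatenated `GRanges`.
#' @export
merge_replicates <- function(recordsets) {
  stopifnot(is.list(recordsets), length(recordsets) >= 1)
  lv <- lapply(recordsets, GenomeInfoDb::seqlevels)
  if (!all(vapply(lv, identical, logical(1), y = lv[[1]]))) {
    stop("replicates disagree on the chromosome universe")
  }
  do.call(c, unname(recordsets))
}

#' Per-base fragment coverage
#'
#' Pile-up of whole fragment intervals: the value at base `b` is the
#' number of fragments whose interval contains `b`. Returns an
#' unnormalized `coverage_track` (normalization factor 1) whose library
#' size is the number of fragments piled up.
#'
#' @param records fragment `GRanges` with seqlengths set.
#' @param library_size library size to record; defaults to
#'   `length(records)`.
#' @return a `coverage_track`: list with `cov` (an `RleList`),
#'   `normalization_factor`, `library_size`, `chrom_sizes`.
#' @export
compute_coverage <- function(records, library_size = length(records)) {
  cs <- GenomeInfoDb::seqlengths(records)
  if (any(is.na(cs))) stop("records must carry chromosome lengths")
  bad <- BiocGenerics::start(records) < 1 |
    BiocGenerics::end(records) > cs[as.character(GenomeInfoDb::seqnames(records))]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "fragment out of chromosome bounds: %s:%d-%d",
      as.character(GenomeInfoDb::seqnames(records))[i],
      BiocGenerics::start(records)[i], BiocGenerics::end(records)[i]
    ))
  }
  structure(
    list(
      cov = GenomicRanges::coverage(records),
      normalization_factor = 1,
      library_size = library_size,
      chrom_sizes = cs
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track: %d chromosome(s), library size %s, scale %.6g\n",
    length(x$cov), format(x$library_size, big.mark = ","),
    x$normalization_factor
  ))
  invisible(x)
}

#' Genome-wide sum of a track
#' @param track a `coverage_track`.
#' @return scalar sum of per-base values over the genome.
#' @export
track_sum <- function(track) {
  sum(vapply(track$cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                          S4Vectors::runLength(r)),
             numeric(1)))
}

#' Normalize a coverage track to library size
#'
#' Rescales every per-base value by `1e6 / library_size` (the
#' reads-per-million convention for "normalized to the total number of
#' uniquely mapped reads"); the factor is recorded on the track so that
#' any alternative constant reproduces identical comparative statistics.
#'
#' @param track a `coverage_track`.
#' @param library_size positive fragment count; defaults to the track's
#'   recorded library size.
#' @param scale_per reads-per-`scale_per` convention (default 1e6).
#' @return normalized `coverage_track`.
#' @export
normalize_track <- function(track, library_size = track$library_size,
                            scale_per = 1e6) {
  if (is.null(library_size) || library_size <= 0) {
    stop("library_size must be positive")
  }
  scale <- scale_per / library_size
  track$cov <- track$cov * scale
  track$normalization_factor <- track$normalization_factor * scale
  track$library_size <- library_size
  track
}

#' Strand-split coverage
#'
#' Splits fragments by fragment strand (the transcribed strand inferred
#' from paired-end orientation) and piles up each half over the whole
#' genome, so that plus + minus equals the unsplit track at every base.
#'
#' @param records stranded fragment `GRanges` (no `*` strands).
#' @param library_size library size recorded on both tracks (defaults to
#'   the total fragment count, so both strands share one normalization).
#' @return list with elements `plus` and `minus`, both `coverage_track`s.
#' @export
split_by_strand <- function(records, library_size = length(records)) {
  st <- as.character(BiocGenerics::strand(records))
  if (any(st == "*")) stop("unstranded fragment encountered in strand split")
  list(
    plus = compute_coverage(records[st == "+"], library_size = library_size),
    minus = compute_coverage(records[st == "-"], library_size = library_size)
  )
}

#' Write a track as bedGraph
#'
#' 0-based half-open intervals, one line per run; zero runs are omitted.
#'
#' @param track a `coverage_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  gr <- GenomicRanges::bindAsGRanges(score = track$cov)
  rtracklayer::export(gr[gr$score != 0], path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph file.
#' @param chrom_sizes named chromosome lengths.
#' @param library_size,normalization_factor metadata to record (bedGraph
#'   itself carries neither).
#' @return a `coverage_track`.
#' @export
read_track_bedgraph <- function(path, chrom_sizes, library_size = NA,
                                normalization_factor = 1) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  structure(
    list(
      cov = GenomicRanges::coverage(gr, weight = gr$score),
      normalization_factor = normalization_factor,
      library_size = library_size,
      chrom_sizes = chrom_sizes
    ),
    class = "coverage_track"
  )
}

#' Write fragments as 6-column BED
#'
#' 0-based half-open, strand in column 6, fragment name in column 4.
#'
#' @param records fragment `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(records, path) {
  out <- records
  if (is.null(out$name)) {
    nm <- if (!is.null(out$sample)) out$sample else "frag"
    out$name <- paste0(nm, "_", seq_along(out))
  }
  out$score <- 0L
  S4Vectors::mcols(out) <- S4Vectors::mcols(out)[c("name", "score")]
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read 6-column BED fragments
#'
#' @param path BED file.
#' @param chrom_sizes named chromosome lengths.
#' @param sample_id sample label to attach.
#' @return fragment `GRanges` with `duplicate`, `unique`, `sample` columns.
#' @export
read_fragments_bed <- function(path, chrom_sizes, sample_id = basename(path)) {
  gr <- rtracklayer::import(path, format = "bed")
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  gr$duplicate <- FALSE
  gr$unique <- TRUE
  gr$sample <- sample_id
  gr
}
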