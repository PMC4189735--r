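#' Build anchor regions from gene models
#'
#' Derives oriented anchor points for metagene analysis. With 0-based
#' half-open gene intervals `[start, end)`: for `+` genes TSS = `start`
#' and TES = `end - 1`; for `-` genes TSS = `end - 1` and TES = `start`.
#' Orientation is the gene strand, so relative position `+x` always means
#' `x` bases downstream in the direction of transcription.
#' `region_center` anchors (for non-promoter region sets) use the
#' interval midpoint with orientation `+`.
#'
#' Anchors whose `[anchor - flank, anchor + flank]` interval leaves the
#' chromosome are excluded; the number dropped is recorded in the
#' `n_excluded` attribute.
#'
#' @param annotation a `gene_annotation`, or a `GRanges` of regions when
#'   `anchor_kind = "region_center"`.
#' @param anchor_kind one of `"TSS"`, `"TES"`, `"region_center"`.
#' @param flank bases kept on each side of the anchor.
#' @return an `anchor_set`: data.frame with columns `chrom`, `anchor`
#'   (0-based bp), `orientation`, `label`; attributes `flank`,
#'   `n_excluded`, `chrom_sizes`.
#' @export
build_anchors <- function(annotation, anchor_kind = c("TSS", "TES",
                                                      "region_center"),
                          flank = 3000) {
  anchor_kind <- match.arg(anchor_kind)
  if (anchor_kind == "region_center") {
    gr <- if (inherits(annotation, "gene_annotation")) {
      annotation$genes
    } else {
      annotation
    }
    cs <- GenomeInfoDb::seqlengths(gr)
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    anchor <- floor((BiocGenerics::start(gr) - 1 + BiocGenerics::end(gr)) / 2)
    orientation <- rep("+", length(gr))
    label <- if (!is.null(gr$name)) gr$name else if (!is.null(gr$gene_id)) {
      gr$gene_id
    } else {
      sprintf("region%05d", seq_along(gr))
    }
  } else {
    stopifnot(inherits(annotation, "gene_annotation"))
    g <- annotation$genes
    cs <- annotation$chrom_sizes
    chrom <- as.character(GenomeInfoDb::seqnames(g))
    st <- as.character(BiocGenerics::strand(g))
    if (any(st == "*")) stop("gene strands must be defined to build anchors")
    start0 <- BiocGenerics::start(g) - 1
    end0 <- BiocGenerics::end(g)
    anchor <- if (anchor_kind == "TSS") {
      ifelse(st == "+", start0, end0 - 1)
    } else {
      ifelse(st == "+", end0 - 1, start0)
    }
    orientation <- st
    label <- g$gene_id
  }
  keep <- anchor - flank >= 0 & anchor + flank < cs[chrom]
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("build_anchors: excluded %d region(s) extending past %s",
                    n_excluded, "chromosome ends"))
  }
  out <- data.frame(
    chrom = chrom[keep], anchor = anchor[keep],
    orientation = orientation[keep], label = label[keep],
    stringsAsFactors = FALSE
  )
  structure(out, flank = flank, n_excluded = n_excluded,
            chrom_sizes = cs, class = c("anchor_set", "data.frame"))
}

# Per-base signal matrix: one row per anchor, 2*flank columns covering
# oriented relative positions -flank .. flank-1. For '-' anchors relative
# position r maps to genomic base anchor - r.
.per_base_matrix <- function(track, regions, flank = attr(regions, "flank")) {
  n <- nrow(regions)
  m <- matrix(0, nrow = n, ncol = 2 * flank)
  rownames(m) <- regions$label
  for (chrom in unique(regions$chrom)) {
    idx <- which(regions$chrom == chrom)
    rle <- track$cov[[chrom]]
    for (i in idx) {
      a <- regions$anchor[i]
      if (regions$orientation[i] == "-") {
        # genomic 0-based a - (-flank) down to a - (flank - 1)
        v <- as.numeric(S4Vectors::window(rle, a - flank + 2, a + flank + 1))
        m[i, ] <- rev(v)
      } else {
        m[i, ] <- as.numeric(S4Vectors::window(rle, a - flank + 1, a + flank))
      }
    }
  }
  m
}

#' Sliding-window occupancy matrix
#'
#' Computes the regions x windows matrix of mean per-base normalized
#' signal: windows of `window` bp every `slide` bp spanning
#' `[-flank, +flank]` around each oriented anchor (100 bp / 20 bp by
#' default). Windows start at `-flank` and advance while they fit, giving
#' `(2 * flank - window) / slide + 1` columns when divisible — 296 for a
#' 3 kb flank. Signal for `-` anchors is flipped so columns always read
#' 5' to 3'.
#'
#' @param track a normalized (or raw) `coverage_track`.
#' @param regions an `anchor_set` from [build_anchors()].
#' @param window window width in bp.
#' @param slide step between window starts in bp.
#' @return a `window_matrix`: numeric matrix with row names = region
#'   labels, attribute `positions` = window-start offsets relative to the
#'   anchor, plus `window`, `slide`, `flank`.
#' @export
compute_window_matrix <- function(track, regions, window = 100, slide = 20) {
  flank <- attr(regions, "flank")
  stopifnot(!is.null(flank), slide > 0, window >= 1)
  if (window > 2 * flank) stop("window wider than the profiled interval")
  m <- .per_base_matrix(track, regions, flank)
  n_win <- (2 * flank - window) %/% slide + 1L
  starts <- (seq_len(n_win) - 1L) * slide # 0-based offset into the interval
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  out <- (cs[, starts + window + 1, drop = FALSE] -
            cs[, starts + 1, drop = FALSE]) / window
  dimnames(out) <- list(rownames(m), starts - flank)
  structure(out, positions = starts - flank, window = window,
            slide = slide, flank = flank,
            class = c("window_matrix", "matrix"))
}

#' Median average profile
#'
#' Column-wise median of a window matrix: the per-window median signal
#' across regions, the summary plotted as an average profile.
#'
#' @param matrix a `window_matrix` with at least one row.
#' @return data.frame with columns `position` (window start relative to
#'   the anchor) and `value` (median signal).
#' @export
average_profile <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0) {
    stop("cannot profile an empty matrix")
  }
  data.frame(
    position = attr(matrix, "positions"),
    value = apply(matrix, 2, stats::median)
  )
}

#' Per-region signal density
#'
#' Mean per-base normalized signal over the full `[-flank, +flank]`
#' interval of each region — the scalar summarized in the box-plot
#' comparisons of read density.
#'
#' @param track a `coverage_track`.
#' @param regions an `anchor_set`.
#' @param group optional group label (e.g. genotype x treatment) attached
#'   to the summary.
#' @return a `density_summary`: data.frame with columns `label`,
#'   `density`, `group`.
#' @export
region_density <- function(track, regions, group = NA_character_) {
  m <- .per_base_matrix(track, regions)
  structure(
    data.frame(label = regions$label, density = rowMeans(m),
               group = group, stringsAsFactors = FALSE),
    class = c("density_summary", "data.frame")
  )
}

#' Wilcoxon rank-sum comparison of density groups
#'
#' Two-sided unpaired Wilcoxon (Mann-Whitney) test between two sets of
#' per-region densities. The exact null distribution is used when both
#' groups are small (`min(n, m) <= 8`) and tie-free; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param group_a,group_b `density_summary` objects or bare numeric
#'   vectors; both non-empty.
#' @param exact_max largest `min(n, m)` for which the exact distribution
#'   is used.
#' @return list with `statistic` (Mann-Whitney W for group A), `p.value`,
#'   `n`, `m`, `method`.
#' @export
compare_density_groups <- function(group_a, group_b, exact_max = 8) {
  a <- if (is.data.frame(group_a)) group_a$density else as.numeric(group_a)
  b <- if (is.data.frame(group_b)) group_b$density else as.numeric(group_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty")
  }
  ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) <= exact_max && !ties
  ht <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(
    statistic = unname(ht$statistic), p.value = ht$p.value,
    n = length(a), m = length(b),
    method = if (exact) "exact" else "normal approximation"
  )
}

#' K-means clustering and heatmap row ordering
#'
#' Partitions the rows of a reference window matrix into `k` clusters
#' (Euclidean k-means, fixed seed) and derives a display ordering:
#' clusters sorted by descending cluster mean signal, rows within a
#' cluster by descending row mean, ties broken by row label. `k = 1`
#' degenerates to a plain descending row-mean sort. Apply the same
#' ordering verbatim to companion matrices with [apply_ordering()].
#'
#' @param matrix_ref reference `window_matrix` (rows = regions).
#' @param k number of clusters, `1 <= k <= nrow`.
#' @param seed integer seed for the k-means initialization.
#' @param nstart random restarts passed to [stats::kmeans()].
#' @return list with `order` (integer permutation of rows), `clusters`
#'   (per-row assignment, original order), `cluster_rank` (display rank
#'   of each cluster id), `k`.
#' @export
cluster_and_order <- function(matrix_ref, k = 5, seed = 1L, nstart = 10) {
  n <- nrow(matrix_ref)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop(sprintf("k = %d exceeds the %d available rows", k, n))
  rmeans <- rowMeans(matrix_ref)
  labels <- rownames(matrix_ref)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (k == 1) {
    ord <- order(-rmeans, labels)
    return(list(order = ord, clusters = rep(1L, n),
                cluster_rank = 1L, k = 1L))
  }
  km <- withr::with_seed(seed, {
    stats::kmeans(unclass(matrix_ref), centers = k, nstart = nstart,
                  iter.max = 100)
  })
  cl <- km$cluster
  cl_mean <- tapply(rmeans, cl, mean)
  cluster_rank <- rank(-cl_mean, ties.method = "first")
  ord <- order(cluster_rank[cl], -rmeans, labels)
  list(order = ord, clusters = cl,
       cluster_rank = cluster_rank, k = as.integer(k))
}

#' Apply a row ordering to a companion matrix
#'
#' @param matrix a `window_matrix` (or any matrix) with the same rows as
#'   the reference the ordering came from.
#' @param ordering result of [cluster_and_order()].
#' @return the matrix with rows permuted into display order.
#' @export
apply_ordering <- function(matrix, ordering) {
  stopifnot(length(ordering$order) == nrow(matrix))
  out <- matrix[ordering$order, , drop = FALSE]
  for (a in c("positions", "window", "slide", "flank")) {
    attr(out, a) <- attr(matrix, a)
  }
  class(out) <- class(matrix)
  out
}
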