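#' Build a master peak table for one antibody
#'
#' Union-merges all per-sample peak calls into a set of master loci
#' (overlapping or book-ended peaks are merged), then records, per master
#' locus, presence in each sample (overlap with that sample's own peaks)
#' and, optionally, a normalized count matrix keyed by locus.
#'
#' @param peak_sets Named list of `GRanges`, one per sample.
#' @param norm_counts Optional loci x samples matrix whose rownames are
#'   `chrom:start-end` keys (see [locus_keys()]) matching the merged
#'   master loci, e.g. from [normalize_counts()].
#' @param antibody Antibody label carried in the result.
#' @return Object of class `master_peak_table`: list with `antibody`,
#'   `loci` (`GRanges`), `presence` (logical loci x samples matrix) and
#'   `norm_counts` (matrix or `NULL`).
#' @export
build_master_table <- function(peak_sets, norm_counts = NULL,
                               antibody = NA_character_) {
  stopifnot(length(peak_sets) >= 1L)
  for (nm in names(peak_sets)) {
    gr <- peak_sets[[nm]]
    if (any(GenomicRanges::width(gr) < 1L))
      stop("malformed interval (start >= end) in sample ", nm)
  }
  all_peaks <- unlist(GenomicRanges::GRangesList(lapply(peak_sets, function(g) {
    GenomicRanges::granges(g)  # strip mcols before concatenating
  })), use.names = FALSE)
  # reduce() with the default min.gapwidth = 1 merges book-ended intervals
  loci <- GenomicRanges::reduce(GenomicRanges::granges(all_peaks),
                                ignore.strand = TRUE)
  presence <- vapply(peak_sets, function(g)
    IRanges::overlapsAny(loci, g, ignore.strand = TRUE),
    logical(length(loci)))
  if (is.null(dim(presence)))
    presence <- matrix(presence, nrow = length(loci),
                       dimnames = list(NULL, names(peak_sets)))
  rownames(presence) <- locus_keys(loci)
  if (!is.null(norm_counts)) {
    norm_counts <- as.matrix(norm_counts)
    idx <- match(locus_keys(loci), rownames(norm_counts))
    if (anyNA(idx))
      stop("norm_counts rownames do not cover all master loci")
    norm_counts <- norm_counts[idx, colnames(presence), drop = FALSE]
  }
  structure(list(antibody = antibody, loci = loci, presence = presence,
                 norm_counts = norm_counts),
            class = "master_peak_table")
}

#' @export
print.master_peak_table <- function(x, ...) {
  cat("master_peak_table:", x$antibody, "-", length(x$loci), "loci x",
      ncol(x$presence), "samples;",
      if (is.null(x$norm_counts)) "no counts" else "with counts", "\n")
  invisible(x)
}

#' Filter and pair master loci across two marks for the dependency screen
#'
#' Retains loci that are (i) present in at least `min_samples` samples,
#' (ii) reach a maximal normalized count of at least `min_max_count` in
#' some sample, and (iii) overlap at least one retained locus of the
#' other mark. Surviving loci are paired across marks by maximal overlap
#' (ties broken by the leftmost partner).
#'
#' @param k27ac,brd4 `master_peak_table` objects sharing the same sample
#'   set, with `norm_counts` populated.
#' @param min_samples Minimum number of samples a locus must be detected
#'   in (default 3).
#' @param min_max_count Minimum of the per-locus maximum normalized count
#'   (default 10; loci with maximum `< min_max_count` are removed).
#' @return `data.frame` with one row per locus pair: `k27ac_idx`,
#'   `brd4_idx` (indices into each table's loci), locus keys, and the
#'   overlap width; attributes `keep_k27ac`/`keep_brd4` hold the logical
#'   filter masks before pairing.
#' @export
filter_for_screen <- function(k27ac, brd4, min_samples = 3L,
                              min_max_count = 10) {
  stopifnot(inherits(k27ac, "master_peak_table"),
            inherits(brd4, "master_peak_table"))
  if (!identical(sort(colnames(k27ac$presence)), sort(colnames(brd4$presence))))
    stop("sample sets differ between the two marks")
  if (is.null(k27ac$norm_counts) || is.null(brd4$norm_counts))
    stop("both tables need norm_counts for the max-count filter")
  keep1 <- rowSums(k27ac$presence) >= min_samples &
    apply(k27ac$norm_counts, 1L, max) >= min_max_count
  keep2 <- rowSums(brd4$presence) >= min_samples &
    apply(brd4$norm_counts, 1L, max) >= min_max_count
  g1 <- k27ac$loci[keep1]
  g2 <- brd4$loci[keep2]
  hits <- GenomicRanges::findOverlaps(g1, g2, ignore.strand = TRUE)
  if (length(hits)) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      g1[S4Vectors::queryHits(hits)], g2[S4Vectors::subjectHits(hits)]))
    hdf <- data.frame(q = S4Vectors::queryHits(hits),
                      s = S4Vectors::subjectHits(hits), ov = ov)
    # maximal-overlap partner per query; ties -> leftmost (smallest start)
    hdf <- hdf[order(hdf$q, -hdf$ov, GenomicRanges::start(g2)[hdf$s]), ]
    hdf <- hdf[!duplicated(hdf$q), ]
  } else {
    hdf <- data.frame(q = integer(0), s = integer(0), ov = integer(0))
  }
  idx1 <- which(keep1)[hdf$q]
  idx2 <- which(keep2)[hdf$s]
  out <- data.frame(
    k27ac_idx = idx1, brd4_idx = idx2,
    k27ac_locus = locus_keys(k27ac$loci)[idx1],
    brd4_locus = locus_keys(brd4$loci)[idx2],
    overlap_bp = hdf$ov, stringsAsFactors = FALSE)
  attr(out, "keep_k27ac") <- keep1
  attr(out, "keep_brd4") <- keep2
  out
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Thin validated front end to `stats::cor(..., method = "kendall")`.
#' Requires equal-length vectors of at least 3 values; an all-tied
#' vector leaves tau undefined and is an error.
#'
#' @param x,y Numeric vectors.
#' @return Kendall tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("all-tied vector: tau undefined")
  stats::cor(x, y, method = "kendall")
}

#' Cross-mark Kendall screen against dependency scores
#'
#' For each paired locus, correlates the normalized counts of both marks
#' with the per-sample dependency scores (Kendall tau-b). A locus is
#' labeled `YapD_H` when both taus are strictly greater than `cutoff`
#' (signal tracks dependency), `YapD_L` when both are strictly less than
#' `-cutoff`, and `none` otherwise (including discordant signs).
#'
#' @param pairs Output of [filter_for_screen()].
#' @param k27ac,brd4 The `master_peak_table` objects the pairs refer to.
#' @param scores Named numeric vector of dependency scores, names =
#'   sample ids (every sample of the tables must be scored).
#' @param cutoff Concordance cutoff on |tau| (default 0.3, strict).
#' @return `data.frame`: locus keys, `tau_k27ac`, `tau_brd4`, `label`
#'   (factor `YapD_H`/`YapD_L`/`none`); attribute `cutoff`.
#' @export
dependency_screen <- function(pairs, k27ac, brd4, scores, cutoff = 0.3) {
  samples <- colnames(k27ac$presence)
  if (!all(samples %in% names(scores)))
    stop("missing dependency score for sample(s): ",
         paste(setdiff(samples, names(scores)), collapse = ", "))
  s <- scores[samples]
  m1 <- k27ac$norm_counts[pairs$k27ac_idx, samples, drop = FALSE]
  m2 <- brd4$norm_counts[pairs$brd4_idx, samples, drop = FALSE]
  tau1 <- screen_taus(m1, s)
  tau2 <- screen_taus(m2, s)
  lab <- rep("none", nrow(pairs))
  lab[tau1 > cutoff & tau2 > cutoff] <- "YapD_H"
  lab[tau1 < -cutoff & tau2 < -cutoff] <- "YapD_L"
  out <- data.frame(k27ac_locus = pairs$k27ac_locus,
                    brd4_locus = pairs$brd4_locus,
                    tau_k27ac = tau1, tau_brd4 = tau2,
                    label = factor(lab, levels = c("YapD_H", "YapD_L", "none")),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

# Row-wise tau-b of a loci x samples matrix against a score vector.
# Constant rows (possible after normalization of sparse loci) get tau 0:
# a flat signal carries no rank information either way.
screen_taus <- function(m, s) {
  if (!nrow(m)) return(numeric(0))
  const <- apply(m, 1L, function(r) length(unique(r)) < 2L)
  tau <- numeric(nrow(m))
  if (any(!const))
    tau[!const] <- suppressWarnings(
      as.vector(stats::cor(t(m[!const, , drop = FALSE]), s,
                           method = "kendall")))
  tau
}

#' Rank-rank hypergeometric overlap (RRHO) grid
#'
#' For two per-locus statistics over the same locus universe, ranks both
#' lists (descending) and, for each grid point `(i, j)` on a `step`
#' lattice, computes the upper-tail hypergeometric p-value of the
#' overlap between the top-`i` set of list 1 and the top-`j` set of
#' list 2. With `signed = TRUE` three further quadrants are returned
#' (both-down, up-down, down-up), ranking each list from the other end
#' as appropriate.
#'
#' @param stat1,stat2 Numeric vectors of per-locus statistics (same
#'   length, same locus order).
#' @param step Lattice step; default `max(1, floor(N / 50))`. Must be
#'   smaller than `N`.
#' @param signed Also compute the three directional quadrants.
#' @return A list with `steps` (threshold grid) and matrices of
#'   `-log10(p)`: `up_up`, and when signed also `down_down`, `up_down`,
#'   `down_up`.
#' @export
rrho_map <- function(stat1, stat2, step = NULL, signed = FALSE) {
  if (length(stat1) != length(stat2)) stop("lists must have equal length")
  n <- length(stat1)
  step <- step %||% max(1L, n %/% 50L)
  if (step >= n) stop("step must be smaller than the number of loci")
  thr <- seq(step, n - 1L, by = step)
  o1_up <- order(stat1, decreasing = TRUE)
  o2_up <- order(stat2, decreasing = TRUE)
  grid <- function(ord1, ord2) {
    r2 <- integer(n); r2[ord2] <- seq_len(n)  # rank in list 2
    pos <- r2[ord1]  # list-2 ranks in list-1 order
    m <- matrix(0, length(thr), length(thr),
                dimnames = list(top1 = thr, top2 = thr))
    for (a in seq_along(thr)) {
      i <- thr[a]
      cnt <- tabulate(pos[seq_len(i)], nbins = n)
      cum <- cumsum(cnt)
      k <- cum[thr]  # overlap of top-i of list1 with each top-j of list2
      m[a, ] <- -stats::phyper(k - 1L, i, n - i, thr, lower.tail = FALSE,
                               log.p = TRUE) / log(10)
    }
    m
  }
  out <- list(steps = thr, up_up = grid(o1_up, o2_up))
  if (signed) {
    o1_dn <- rev(o1_up); o2_dn <- rev(o2_up)
    out$down_down <- grid(o1_dn, o2_dn)
    out$up_down <- grid(o1_up, o2_dn)
    out$down_up <- grid(o1_dn, o2_up)
  }
  out
}

#' Deterministic row/column ordering for a clustered heatmap
#'
#' Optionally z-scores rows, then clusters rows and columns by
#' agglomerative hierarchical clustering (default Euclidean distance,
#' Ward's D2 linkage). `stats::hclust` merges are deterministic for a
#' given input order; leaf order within merges keeps the lower original
#' index first, so repeated calls are reproducible.
#'
#' @param mat Numeric matrix (e.g. loci x samples of log-normalized
#'   counts).
#' @param scale `"row"` (z-score rows, default) or `"none"`.
#' @param distance Distance measure for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"ward.D2"`).
#' @param k_rows,k_cols Optional number of flat clusters to cut each
#'   dendrogram into.
#' @return List: `row_order`, `col_order`, `row_hclust`, `col_hclust`,
#'   and `row_clusters`/`col_clusters` when `k_*` given.
#' @export
cluster_heatmap_order <- function(mat, scale = c("row", "none"),
                                  distance = "euclidean",
                                  linkage = "ward.D2",
                                  k_rows = NULL, k_cols = NULL) {
  scale <- match.arg(scale)
  mat <- as.matrix(mat)
  if (scale == "row") {
    sds <- apply(mat, 1L, stats::sd)
    if (any(sds == 0))
      stop("constant row under row scaling: row ",
           which(sds == 0)[1L])
    mat <- t(scale(t(mat)))
  }
  hr <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  hc <- stats::hclust(stats::dist(t(mat), method = distance), method = linkage)
  out <- list(row_order = hr$order, col_order = hc$order,
              row_hclust = hr, col_hclust = hc)
  if (!is.null(k_rows)) out$row_clusters <- stats::cutree(hr, k = k_rows)
  if (!is.null(k_cols)) out$col_clusters <- stats::cutree(hc, k = k_cols)
  out
}
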