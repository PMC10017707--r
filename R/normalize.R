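#' Bin fragment midpoints into fixed-width genome bins
#'
#' Counts fragment midpoints per non-overlapping bin of `width` bp along
#' each contig, one column per sample. Fragments longer than `max_len`
#' are excluded (paired-end CUT&Tag fragments above ~800 bp are usually
#' artefactual concatemers). Large bins (1250 bp for TF antibodies,
#' 10,800 bp for histones/BRD4) make the resulting matrix dominated by
#' background coverage, which is what a between-sample scaling factor
#' should be estimated from.
#'
#' @param fragments Named list of `GRanges` (or data.frames with
#'   `chrom`, `start`, `end` in 0-based half-open coordinates), one per
#'   sample.
#' @param width Bin width in bp (> 0).
#' @param max_len Maximum fragment length retained (default 800).
#' @param min_len Minimum fragment length retained (default 0).
#' @return Integer matrix bins x samples; rownames `chrom:bin_start` with
#'   0-based bin starts; attribute `width` records the bin width.
#' @export
bin_fragments <- function(fragments, width, max_len = 800L, min_len = 0L) {
  if (width <= 0) stop("width must be positive")
  if (!length(fragments)) stop("no samples supplied")
  frag_df <- lapply(fragments, function(f) {
    if (is(f, "GRanges")) {
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(f)),
                 start = GenomicRanges::start(f) - 1L,
                 end = GenomicRanges::end(f))
    } else {
      data.frame(chrom = as.character(f$chrom), start = f$start, end = f$end)
    }
  })
  # midpoint of [start, end): start + floor(len/2); bin = floor(mid/width)
  keyed <- lapply(frag_df, function(d) {
    len <- d$end - d$start
    d <- d[len <= max_len & len >= min_len, , drop = FALSE]
    if (!nrow(d)) return(character(0))
    mid <- d$start + (d$end - d$start) %/% 2L
    paste0(d$chrom, ":", (mid %/% as.integer(width)) * as.integer(width))
  })
  bins <- sort(unique(unlist(keyed)))
  mat <- vapply(keyed, function(k) {
    tab <- table(factor(k, levels = bins))
    as.integer(tab)
  }, integer(length(bins)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(bins))
  rownames(mat) <- bins
  colnames(mat) <- names(fragments)
  attr(mat, "width") <- as.integer(width)
  mat
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-sample TMM factors from a bins-by-samples count matrix.
#' For each sample, per-bin log2 ratios (M) against a reference sample
#' are trimmed by `logratio_trim` on each side and by `abs_trim` on the
#' absolute-intensity (A) scale, then averaged with inverse-variance
#' (delta-method binomial) weights; the factor is 2 to that mean. Bins
#' with a zero in either sample are excluded. The reference is the
#' sample whose 75th percentile of library-scaled counts is closest to
#' the panel median of those percentiles. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param bins Non-negative count matrix, bins x samples (>= 2 samples).
#' @param logratio_trim Fraction trimmed from each tail of the M values
#'   (default 0.3).
#' @param abs_trim Fraction trimmed from each tail of the A values
#'   (default 0.05).
#' @return `data.frame`: `sample`, `library_size`, `factor`, with the
#'   reference sample name as attribute `ref`.
#' @export
tmm_factors <- function(bins, logratio_trim = 0.3, abs_trim = 0.05) {
  bins <- as.matrix(bins)
  if (ncol(bins) < 2L) stop("need at least 2 samples")
  lib <- colSums(bins)
  if (any(lib == 0)) stop("all-zero sample: ", colnames(bins)[lib == 0][1L])
  uq <- apply(sweep(bins, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - stats::median(uq)))
  f <- vapply(seq_len(ncol(bins)), function(s) {
    if (s == ref) return(1)
    2^trimmed_mean_m(bins[, s], bins[, ref], lib[s], lib[ref],
                     logratio_trim, abs_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample = colnames(bins) %||% as.character(seq_along(f)),
                    library_size = unname(lib),
                    factor = unname(f),
                    stringsAsFactors = FALSE)
  attr(out, "ref") <- out$sample[ref]
  out
}

# Doubly trimmed, precision-weighted mean of M values of sample `y`
# against reference `r` (the published TMM definition).
trimmed_mean_m <- function(y, r, ny, nr, logratio_trim, abs_trim) {
  keep <- y > 0 & r > 0
  y <- y[keep]; r <- r[keep]
  if (!length(y)) stop("no bins with positive counts in both samples")
  M <- log2((y / ny) / (r / nr))
  A <- 0.5 * log2((y / ny) * (r / nr))
  w <- (ny - y) / (ny * y) + (nr - r) / (nr * r)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(0)
  w <- 1 / w[keep2]
  sum(w * M[keep2]) / sum(w)
}

#' Scale a count matrix to counts per million with effective library sizes
#'
#' `normalized[i, s] = raw[i, s] / (library_size[s] * factor[s]) * 1e6`,
#' the counts-per-million convention with TMM-corrected effective
#' library sizes.
#'
#' @param raw Loci x samples count matrix.
#' @param factors Output of [tmm_factors()] (columns `sample`,
#'   `library_size`, `factor`), covering every column of `raw`.
#' @return Numeric matrix of the same shape as `raw`.
#' @export
normalize_counts <- function(raw, factors) {
  raw <- as.matrix(raw)
  idx <- match(colnames(raw), factors$sample)
  if (anyNA(idx))
    stop("no normalization factor for sample(s): ",
         paste(colnames(raw)[is.na(idx)], collapse = ", "))
  eff <- factors$library_size[idx] * factors$factor[idx]
  sweep(raw, 2L, eff, "/") * 1e6
}
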