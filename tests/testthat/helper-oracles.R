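# Independent brute-force oracles used across the suite. These stay
# deliberately naive (O(n^2) loops, per-fragment scans) so they cannot
# share a code path with the implementation they check.

# Kendall tau-b over all n(n-1)/2 pairs, with tie corrections.
brute_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Per-bin fragment-midpoint totals by scanning fragments one at a time.
brute_bin_counts <- function(chrom, start, end, width, max_len = 800L) {
  counts <- list()
  for (i in seq_along(start)) {
    if (end[i] - start[i] > max_len) next
    mid <- start[i] + (end[i] - start[i]) %/% 2L
    key <- paste0(chrom[i], ":", (mid %/% width) * width)
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sweep-line union-merge of intervals (0-based half-open, book-ended
# intervals merged), returning a start/end data.frame per chromosome.
brute_merge <- function(chrom, start, end) {
  out <- NULL
  for (ch in sort(unique(chrom))) {
    s <- start[chrom == ch]; e <- end[chrom == ch]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    cs <- s[1L]; ce <- e[1L]
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= ce) ce <- max(ce, e[i])
      else {
        out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
        cs <- s[i]; ce <- e[i]
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
  }
  out
}

# Upper-tail hypergeometric P(X >= k) by direct summation of choose()
# terms: overlap of a fixed i-set with a random j-set out of N.
brute_hyper_tail <- function(k, N, i, j) {
  kk <- k:min(i, j)
  sum(choose(i, kk) * choose(N - i, j - kk)) / choose(N, j)
}

# Random peak set on a small genome for merge/annotation fixtures.
random_peaks <- function(n, chroms = c("chrS", "chrT"), max_pos = 50000L,
                         max_width = 800L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  GenomicRanges::GRanges(
    sample(chroms, n, replace = TRUE),
    IRanges::IRanges(start = start + 1L,
                     width = sample.int(max_width, n, replace = TRUE)))
}

# Assemble a master_peak_table pair from a synthetic panel and run the
# screen; used by recovery/calibration tests.
screen_panel <- function(panel, cutoff = 0.3, min_samples = 3L,
                         min_max_count = 10, normalized = FALSE) {
  counts <- panel$counts
  if (normalized) {
    counts <- lapply(counts, function(m) normalize_counts(m, tmm_factors(m)))
  }
  mt1 <- build_master_table(panel$peaks$H3K27ac, counts$H3K27ac, "H3K27ac")
  mt2 <- build_master_table(panel$peaks$Brd4, counts$Brd4, "Brd4")
  pairs <- filter_for_screen(mt1, mt2, min_samples = min_samples,
                             min_max_count = min_max_count)
  scores <- stats::setNames(panel$truth$lines$dependency,
                            panel$truth$lines$line_id)
  dependency_screen(pairs, mt1, mt2, scores, cutoff = cutoff)
}

# Focal-sample peak list of a synthetic panel, named by antibody.
focal_peak_sets <- function(panel) {
  abs <- c("H3K4me3", "H3K27ac", "Brd4", "Jun", "Sox2", "Sox5",
           "Twist2", "Yap")
  out <- lapply(abs, function(ab) {
    x <- panel$peaks[[ab]]
    if (!is.null(x[[panel$focal_line]])) x[[panel$focal_line]] else x[[1L]]
  })
  names(out) <- abs
  out
}
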