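#' Aggregate per-site insertion profiles into a mean profile
#'
#' Profiles must share the same window geometry; profiles on the minus
#' strand are reversed before averaging so that all sites are oriented
#' 5'->3' along the motif.
#'
#' @param profiles Numeric matrix, sites x positions (or a list of
#'   equal-length numeric vectors).
#' @param strand Character vector of `"+"`/`"-"` per site (default all
#'   `"+"`).
#' @return Numeric vector: positionwise mean insertion count.
#' @export
aggregate_profile <- function(profiles, strand = NULL) {
  if (is.list(profiles)) {
    L <- unique(lengths(profiles))
    if (length(L) != 1L) stop("profiles differ in window geometry")
    profiles <- do.call(rbind, profiles)
  }
  profiles <- as.matrix(profiles)
  strand <- strand %||% rep("+", nrow(profiles))
  if (length(strand) != nrow(profiles))
    stop("one strand per profile required")
  neg <- strand == "-"
  if (any(neg))
    profiles[neg, ] <- profiles[neg, ncol(profiles):1, drop = FALSE]
  colMeans(profiles)
}

#' Footprint metrics from an insertion profile
#'
#' The profile covers `core` (the motif, `motif_width` central
#' positions), `flank` (`flank_width` positions immediately on each side
#' of the core) and `background` (the outermost `background_width`
#' positions on each side). All heights are expressed as fold over the
#' local background:
#' \describe{
#'   \item{flank_height}{mean(flank) / mean(background) — flanking
#'     accessibility, the amount of factor-recruited transposition
#'     around the site.}
#'   \item{footprint_depth}{flank_height - core_height, the protection
#'     of the motif relative to its flanks.}
#'   \item{relative_depth}{footprint_depth / flank_height, in `[0, 1]`
#'     for non-negative core signal; scale-invariant.}
#' }
#'
#' @param profile Numeric vector of per-base insertion counts (odd or
#'   even length `2 * half_width + motif_width`).
#' @param motif_width Width of the protected core in bp.
#' @param flank_width Width of each flank in bp (default 20).
#' @param background_width Width of each outer background margin in bp
#'   (default 50).
#' @return List: `flank_height`, `core_height`, `footprint_depth`,
#'   `relative_depth`.
#' @export
footprint_metrics <- function(profile, motif_width, flank_width = 20L,
                              background_width = 50L) {
  L <- length(profile)
  if ((L - motif_width) %% 2L != 0L)
    stop("profile length minus motif_width must be even (centered motif)")
  half <- (L - motif_width) %/% 2L
  if (half < flank_width + background_width)
    stop("window too small: need half-width >= flank_width + background_width")
  core_idx <- (half + 1L):(half + motif_width)
  flank_idx <- c((half - flank_width + 1L):half,
                 (half + motif_width + 1L):(half + motif_width + flank_width))
  bg_idx <- c(1:background_width, (L - background_width + 1L):L)
  bg <- mean(profile[bg_idx])
  if (bg <= 0) stop("zero background signal")
  flank_height <- mean(profile[flank_idx]) / bg
  core_height <- mean(profile[core_idx]) / bg
  depth <- flank_height - core_height
  list(flank_height = flank_height,
       core_height = core_height,
       footprint_depth = depth,
       relative_depth = if (flank_height > 0) depth / flank_height else NA_real_)
}

#' Classify sites as bound or unbound from per-site footprint scores
#'
#' Fits one- and two-component Gaussian mixtures (via
#' \pkg{mclust}) to the per-site depth scores. If the two-component
#' model is preferred by BIC, sites with posterior probability > 0.5 for
#' the higher-mean component are called bound; otherwise (degenerate or
#' unimodal fit) all sites are unbound, with a warning. Bound and
#' unbound always partition the input.
#'
#' @param scores Numeric per-site footprint depth scores (>= 10 sites).
#' @return List: `bound` (logical per site), `threshold` (smallest score
#'   called bound; `Inf` when none), `model` (the mclust fit or `NULL`).
#' @export
classify_bound <- function(scores) {
  if (length(scores) < 10L) stop("need at least 10 sites")
  if (stats::sd(scores) < sqrt(.Machine$double.eps)) {
    warning("degenerate (constant) scores; all sites called unbound")
    return(list(bound = rep(FALSE, length(scores)), threshold = Inf,
                model = NULL))
  }
  fit <- tryCatch(
    Mclust(scores, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$G < 2L) {
    warning("unimodal fit; all sites called unbound")
    return(list(bound = rep(FALSE, length(scores)), threshold = Inf,
                model = fit))
  }
  hi <- which.max(fit$parameters$mean)
  bound <- fit$z[, hi] > 0.5
  list(bound = bound,
       threshold = if (any(bound)) min(scores[bound]) else Inf,
       model = fit)
}

#' Simplified k-mer insertion-bias expectation and correction
#'
#' Tn5 prefers some sequence contexts; a full hexamer regression is out
#' of scope here, but a first-order expectation can be built from the
#' global insertion frequency of each k-mer: the expected insertion rate
#' at a position is proportional to the observed genome-wide (here,
#' window-wide) average insertion count of the k-mer starting at that
#' position. The corrected track is observed/expected, rescaled to
#' preserve the total signal.
#'
#' @param sequence Character scalar (A/C/G/T) covering the window.
#' @param counts Numeric insertion counts, one per position of
#'   `sequence`.
#' @param k k-mer size (default 6); positions within the last `k - 1`
#'   bases have no complete k-mer and keep their observed value.
#' @return List: `expected` (same total as `counts`), `corrected`
#'   (observed/expected, rescaled so its sum equals `sum(counts)`).
#' @export
kmer_bias_expectation <- function(sequence, counts, k = 6L) {
  L <- nchar(sequence)
  if (k > L) stop("k exceeds sequence length")
  if (length(counts) != L) stop("one count per sequence position required")
  n_kmer <- L - k + 1L
  kmers <- substring(sequence, seq_len(n_kmer), seq_len(n_kmer) + k - 1L)
  km_mean <- tapply(counts[seq_len(n_kmer)], kmers, mean)
  expected <- rep(mean(counts), L)
  expected[seq_len(n_kmer)] <- km_mean[kmers]
  expected <- expected * sum(counts) / sum(expected)
  corrected <- ifelse(expected > 0, counts / expected, 0)
  if (sum(corrected) > 0)
    corrected <- corrected * sum(counts) / sum(corrected)
  list(expected = as.numeric(expected), corrected = as.numeric(corrected))
}
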