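#' Log2 relative growth rate from a cell-competition time series
#'
#' Two populations (a test population carrying the perturbation and a
#' reference population) are mixed 50/50 and their fractions tracked by
#' sequential FACS. Under exponential growth the log2 odds
#' `log2(count_test / count_ref)` is linear in time with slope equal to
#' the difference of the populations' log2 growth rates per day. The
#' slope is estimated by ordinary least squares; the dependency score is
#' its negation, so that lines whose test population collapses fastest
#' score highest.
#'
#' Timepoints where either count is zero carry no usable odds and are
#' dropped; if fewer than two timepoints remain an error is raised.
#'
#' @param days Numeric vector of days since mixing (non-decreasing).
#' @param count_test,count_ref Non-negative integer counts of the two
#'   populations at each timepoint.
#' @param line_id Optional identifier carried through to the result.
#' @return A one-row `data.frame`: `line_id`, `log2_rel_growth`
#'   (slope per day), `standard_error`, `yap_dependency`
#'   (`-log2_rel_growth`), `n_timepoints` used.
#' @export
relative_growth_rate <- function(days, count_test, count_ref,
                                 line_id = NA_character_) {
  stopifnot(length(days) == length(count_test),
            length(days) == length(count_ref))
  if (length(days) < 2L)
    stop("need at least 2 timepoints")
  if (is.unsorted(days))
    stop("days must be non-decreasing")
  if (any(count_test < 0) || any(count_ref < 0))
    stop("counts must be non-negative")
  usable <- count_test > 0 & count_ref > 0
  if (sum(usable) < 2L)
    stop("fewer than 2 timepoints with both populations observed")
  d <- days[usable]
  y <- log2(count_test[usable] / count_ref[usable])
  if (length(unique(d)) < 2L)
    stop("all usable timepoints at the same day; slope undefined")
  fit <- stats::lm(y ~ d)
  slope <- unname(coef(fit)[2L])
  # noiseless data fits exactly; summary.lm's perfect-fit warning is
  # expected there and not informative
  se <- if (length(d) > 2L)
    suppressWarnings(summary(fit)$coefficients[2L, 2L]) else NA_real_
  data.frame(line_id = line_id,
             log2_rel_growth = slope,
             standard_error = se,
             yap_dependency = -slope,
             n_timepoints = sum(usable),
             stringsAsFactors = FALSE)
}

#' Dependency scores for a whole panel
#'
#' Applies [relative_growth_rate()] per line to a long-format competition
#' table.
#'
#' @param facs `data.frame` with columns `line_id`, `day`, `count_test`,
#'   `count_ref`.
#' @return `data.frame` with one row per line (see
#'   [relative_growth_rate()]), ordered by `line_id`.
#' @export
dependency_scores <- function(facs) {
  req <- c("line_id", "day", "count_test", "count_ref")
  miss <- setdiff(req, names(facs))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(facs, facs$line_id), function(d) {
    d <- d[order(d$day), ]
    relative_growth_rate(d$day, d$count_test, d$count_ref,
                         line_id = d$line_id[1L])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pluripotency/progenitor TF (PTF) scores
#'
#' A factor counts as "highly expressed" in a line when its expression is
#' at least a fraction `frac` of the panel-wide maximum for that factor
#' (and strictly positive). The PTF score of a line is the number of
#' highly expressed factors, an integer 0 to `ncol(expression)`.
#'
#' @param expression Numeric matrix or data.frame, lines x factors
#'   (canonically Sox2, Sox5, Twist2, Nr2f1, Nr2f2), rownames = line ids.
#' @param frac Fraction of the per-factor panel maximum above which a
#'   factor is called highly expressed. Default 0.25.
#' @param factors Character vector of required factor columns; defaults
#'   to all columns of `expression`.
#' @return `data.frame`: `line_id`, `ptf_score`, and one logical call
#'   column per factor.
#' @export
ptf_score <- function(expression, frac = 0.25, factors = colnames(expression)) {
  expression <- as.matrix(expression)
  miss <- setdiff(factors, colnames(expression))
  if (length(miss))
    stop("missing factor column(s): ", paste(miss, collapse = ", "))
  x <- expression[, factors, drop = FALSE]
  if (any(x < 0)) stop("expression values must be non-negative")
  maxes <- apply(x, 2L, max)
  calls <- sweep(x, 2L, frac * maxes, ">=") & x > 0
  data.frame(line_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             ptf_score = as.integer(rowSums(calls)),
             calls,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Partition lines into Low and High PTF groups
#'
#' Low covers scores `0..low_max` (default 0-2), High the rest (3-5 for
#' the canonical five-factor score).
#'
#' @param scores Integer PTF scores (or the output of [ptf_score()]).
#' @param low_max Largest score still assigned to the Low group.
#' @return Factor with levels `"Low"`, `"High"`, same length as `scores`.
#' @export
group_lines <- function(scores, low_max = 2L) {
  if (is.data.frame(scores)) scores <- scores$ptf_score
  if (length(scores) == 0L)
    return(factor(character(0), levels = c("Low", "High")))
  if (any(scores < 0))
    stop("scores must be non-negative")
  factor(ifelse(scores <= low_max, "Low", "High"), levels = c("Low", "High"))
}
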