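#' Classify master loci into chromatin states and TF co-binding masks
#'
#' Each master locus (the union-merge of all antibody peak sets) is
#' flagged by >= 1 bp overlap with the individual peak sets:
#' `is_tss` (H3K4me3 positivity), `is_active` (H3K27ac AND BRD4 double
#' positivity), one logical per TF in `{Jun, Sox2, Sox5, Twist2}`, and
#' `yap_bound`. Book-ended intervals do not count as overlapping here
#' (annotation, unlike merging, requires shared bases).
#'
#' Loci are further assigned to seven clusters partitioning the master
#' set: for TSS loci, `p1` (H3K27ac+ BRD4+ Jun+ Sox2+), `p2` (H3K27ac+
#' BRD4+ Jun- Sox2+), `p3` (remaining TSS); for CRE loci, `e2` (H3K27ac-
#' BRD4- Jun+ Sox2+), `e3` (H3K27ac- BRD4- Jun+ Sox2-), `e4` (H3K27ac-
#' BRD4- Jun- Sox2+), `e1` (remaining CRE). The activity split per class
#' (active = double-positive, inactive = not) yields the four state
#' classes active/inactive x TSS/CRE.
#'
#' @param master `GRanges` of master loci.
#' @param peaks Named list of `GRanges` peak sets; recognized names
#'   (case-insensitive): `H3K4me3`, `H3K27ac`, `BRD4`, `Jun`, `Sox2`,
#'   `Sox5`, `Twist2`, `Yap`. Missing antibodies yield all-FALSE flags.
#' @param require_covered Error if some locus overlaps no supplied peak
#'   set (violates the master-merge construction). Default TRUE.
#' @return `data.frame` with one row per locus: `locus` key, logical
#'   flags, `state` (factor of the four activity classes) and
#'   `cluster7` (factor p1..p3, e1..e4).
#' @export
classify_states <- function(master, peaks, require_covered = TRUE) {
  names(peaks) <- tolower(names(peaks))
  flag <- function(ab) {
    g <- peaks[[tolower(ab)]]
    if (is.null(g)) rep(FALSE, length(master))
    else IRanges::overlapsAny(master, g, ignore.strand = TRUE)
  }
  k4 <- flag("H3K4me3"); k27 <- flag("H3K27ac"); brd4 <- flag("BRD4")
  jun <- flag("Jun"); sox2 <- flag("Sox2"); sox5 <- flag("Sox5")
  twist2 <- flag("Twist2"); yap <- flag("Yap")
  covered <- k4 | k27 | brd4 | jun | sox2 | sox5 | twist2 | yap
  if (require_covered && any(!covered))
    stop(sum(!covered), " master locus/loci overlap no supplied peak set")
  active <- k27 & brd4
  cl <- character(length(master))
  tss <- k4
  cl[tss & active & jun & sox2] <- "p1"
  cl[tss & active & !jun & sox2] <- "p2"
  cl[tss & cl == ""] <- "p3"
  off <- !k27 & !brd4
  cl[!tss & off & jun & sox2] <- "e2"
  cl[!tss & off & jun & !sox2] <- "e3"
  cl[!tss & off & !jun & sox2] <- "e4"
  cl[!tss & cl == ""] <- "e1"
  state <- paste0(ifelse(active, "active_", "inactive_"),
                  ifelse(tss, "TSS", "CRE"))
  data.frame(
    locus = locus_keys(master),
    is_tss = tss, is_active = active,
    h3k4me3 = k4, h3k27ac = k27, brd4 = brd4,
    jun = jun, sox2 = sox2, sox5 = sox5, twist2 = twist2,
    yap_bound = yap,
    state = factor(state, levels = c("active_TSS", "inactive_TSS",
                                     "active_CRE", "inactive_CRE")),
    cluster7 = factor(cl, levels = c("p1", "p2", "p3",
                                     "e1", "e2", "e3", "e4")),
    stringsAsFactors = FALSE)
}

# Mutually exclusive TF-combination category for one locus, by priority:
# all four bound; exactly three (named); the exclusive "Sox5|Twist2+"
# class (exactly one of Sox5/Twist2, i.e. a site bound by both is
# excluded); a single TF only; none; remaining two-TF combinations fall
# in "other_pair".
tf_category <- function(jun, sox2, sox5, twist2) {
  n <- jun + sox2 + sox5 + twist2
  out <- character(length(n))
  out[n == 4L] <- "Jun+Sox2+Sox5+Twist2+"
  i3 <- n == 3L
  out[i3 & !twist2] <- "Jun+Sox2+Sox5+"
  out[i3 & !sox5] <- "Jun+Sox2+Twist2+"
  out[i3 & !sox2] <- "Jun+Sox5+Twist2+"
  out[i3 & !jun] <- "Sox2+Sox5+Twist2+"
  rest <- out == ""
  xor_st <- xor(sox5, twist2)
  out[rest & n == 2L & xor_st] <- "Sox5|Twist2+"
  out[rest & n == 2L & !xor_st] <- "other_pair"
  out[n == 1L & jun] <- "Jun_only"
  out[n == 1L & sox2] <- "Sox2_only"
  out[n == 1L & sox5] <- "Sox5_only"
  out[n == 1L & twist2] <- "Twist2_only"
  out[n == 0L] <- "none"
  factor(out, levels = tf_category_levels())
}

tf_category_levels <- function() {
  c("Jun+Sox2+Sox5+Twist2+",
    "Jun+Sox2+Sox5+", "Jun+Sox2+Twist2+", "Jun+Sox5+Twist2+",
    "Sox2+Sox5+Twist2+",
    "Sox5|Twist2+", "other_pair",
    "Jun_only", "Sox2_only", "Sox5_only", "Twist2_only", "none")
}

#' Combinatorial TF co-binding counts per chromatin-state class
#'
#' Tallies, within each of the four activity classes (active/inactive x
#' TSS/CRE), the mutually exclusive TF-combination categories over
#' `{Jun, Sox2, Sox5, Twist2}`: all four; each exactly-three variant;
#' `Sox5|Twist2+` (bound by either Sox5 or Twist2 but not both, with one
#' other TF); other two-TF pairs; each single TF alone; none. Categories
#' partition each class, so counts sum to class totals.
#'
#' @param annotations Output of [classify_states()].
#' @return `data.frame`: `state`, `category`, `count`, `pct` (percent of
#'   the class total, half-up to one decimal).
#' @export
combination_counts <- function(annotations) {
  cat <- tf_category(annotations$jun, annotations$sox2,
                     annotations$sox5, annotations$twist2)
  tab <- table(state = annotations$state, category = cat)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("state", "category", "count")
  tot <- rowSums(tab)[df$state]
  df$pct <- ifelse(tot > 0, round_half_up(100 * df$count / tot, 1), 0)
  df$state <- factor(df$state, levels = levels(annotations$state))
  df$category <- factor(df$category, levels = tf_category_levels())
  df[order(df$state, df$category), , drop = FALSE]
}

#' Totals and activity fractions of the TSS/CRE split
#'
#' Counts TSS and CRE loci and the active (H3K27ac+ BRD4+) subset of
#' each, with percentages rounded half-up to integers as in
#' figure-panel summaries.
#'
#' @param annotations Output of [classify_states()] (any data.frame
#'   with logical `is_tss`, `is_active`).
#' @return List: `n_total`, `n_tss`, `n_cre`, `n_active_tss`,
#'   `n_active_cre`, `pct_active_tss`, `pct_active_cre`.
#' @export
state_activity_summary <- function(annotations) {
  tss <- annotations$is_tss
  act <- annotations$is_active
  list(n_total = length(tss),
       n_tss = sum(tss), n_cre = sum(!tss),
       n_active_tss = sum(tss & act), n_active_cre = sum(!tss & act),
       pct_active_tss = round_half_up(100 * sum(tss & act) / sum(tss)),
       pct_active_cre = round_half_up(100 * sum(!tss & act) / sum(!tss)))
}

#' Co-binding of Yap-bound loci by the Jun/PTF set
#'
#' Among Yap-bound master loci, the fraction co-bound by at least one
#' and by all four of `{Jun, Sox2, Sox5, Twist2}`, with percentages
#' rounded half-up to integers as in panel-style summaries.
#'
#' @param annotations Output of [classify_states()] (or any data.frame
#'   with logical `yap_bound`, `jun`, `sox2`, `sox5`, `twist2`).
#' @return List: `n_yap`, `n_any`, `n_all4`, `pct_any`, `pct_all4`.
#' @export
yap_cobinding_summary <- function(annotations) {
  yb <- annotations$yap_bound
  if (!any(yb)) stop("no Yap-bound loci")
  a <- annotations[yb, , drop = FALSE]
  n_tf <- a$jun + a$sox2 + a$sox5 + a$twist2
  n_yap <- nrow(a)
  n_any <- sum(n_tf >= 1L)
  n_all4 <- sum(n_tf == 4L)
  list(n_yap = n_yap, n_any = n_any, n_all4 = n_all4,
       pct_any = round_half_up(100 * n_any / n_yap),
       pct_all4 = round_half_up(100 * n_all4 / n_yap))
}

#' Stitch CREs into super-enhancers with a rank-curve tangent cutoff
#'
#' Sorts loci, merges neighbours whose gap is at most `stitch_gap` bp
#' (12.5 kb by default) into stitched regions, sums their signals, ranks
#' regions by total signal ascending and scales the rank-signal curve to
#' the unit square. The cutoff is the signal at the first point where
#' the discrete slope of the scaled curve exceeds 1 (the tangent rule);
#' regions at or above the cutoff are super-enhancers (SE), the rest
#' regular enhancers (RE). A flat curve (all-equal signals) or fewer
#' than 3 regions yields no SE, with a warning in the latter case.
#'
#' @param loci `GRanges` of CRE loci.
#' @param signal Non-negative numeric vector, one value per locus
#'   (e.g. total normalized H3K27ac or BRD4 counts). Taken from
#'   `loci$score` when omitted.
#' @param stitch_gap Maximum gap in bp across which neighbouring loci
#'   are merged (default 12500).
#' @return `data.frame` of stitched regions: `chrom`, `start`, `end`
#'   (0-based half-open), `n_constituents`, `total_signal`, `rank`
#'   (ascending by signal), `is_SE`; attribute `cutoff` holds the signal
#'   cutoff (`Inf` when no SE called).
#' @export
stitch_superenhancers <- function(loci, signal = loci$score,
                                  stitch_gap = 12500L) {
  if (is.null(signal)) stop("signal values required")
  if (length(signal) != length(loci)) stop("one signal value per locus")
  if (any(signal < 0)) stop("signals must be non-negative")
  # merging across gaps <= stitch_gap == reduce with min.gapwidth = gap + 1
  red <- GenomicRanges::reduce(GenomicRanges::granges(loci),
                               min.gapwidth = stitch_gap + 1L,
                               ignore.strand = TRUE, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  total <- vapply(revmap, function(i) sum(signal[i]), 0)
  ncon <- lengths(revmap)
  o <- order(total)
  n <- length(red)
  is_se <- rep(FALSE, n)
  cutoff <- Inf
  if (n < 3L) {
    if (n > 0L) warning("fewer than 3 stitched regions; tangent undefined, ",
                        "all regions reported as RE")
  } else if (max(total) > min(total)) {
    y <- (total[o] - min(total)) / (max(total) - min(total))
    # unit-square x step is 1/(n-1); slope between consecutive points
    slope <- diff(y) * (n - 1)
    idx <- which(slope > 1)
    if (length(idx)) {
      cut_rank <- idx[1L] + 1L  # first point past the tangent crossing
      cutoff <- total[o][cut_rank]
      is_se[o[seq(cut_rank, n)]] <- TRUE
    }
  }
  rk <- integer(n); rk[o] <- seq_len(n)
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_constituents = ncon,
    total_signal = total,
    rank = rk,
    is_SE = is_se,
    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Cross-tabulate TF-combination categories against SE membership
#'
#' Assigns each annotated CRE locus to the stitched region containing it
#' and counts, per TF-combination category, how many loci fall inside SE
#' versus RE regions.
#'
#' @param annotations Output of [classify_states()]; only CRE loci
#'   (`!is_tss`) are tabulated.
#' @param se_calls Output of [stitch_superenhancers()].
#' @return `data.frame`: `category`, `n_SE`, `n_RE`, `pct_of_SE`
#'   (share of all in-SE CREs in this category, half-up to one decimal).
#' @export
se_overlap_summary <- function(annotations, se_calls) {
  cre <- annotations[!annotations$is_tss, , drop = FALSE]
  cat <- tf_category(cre$jun, cre$sox2, cre$sox5, cre$twist2)
  if (nrow(se_calls)) {
    regions <- GenomicRanges::GRanges(
      se_calls$chrom, IRanges::IRanges(se_calls$start + 1L, se_calls$end))
    g <- keys_to_granges(cre$locus)
    hit <- GenomicRanges::findOverlaps(g, regions, select = "first",
                                       ignore.strand = TRUE)
    in_se <- !is.na(hit) & se_calls$is_SE[ifelse(is.na(hit), 1L, hit)]
  } else {
    in_se <- rep(FALSE, nrow(cre))
  }
  tab <- table(category = cat, in_se = factor(in_se, c(TRUE, FALSE)))
  n_se_total <- sum(tab[, 1L])
  data.frame(category = factor(rownames(tab), levels = tf_category_levels()),
             n_SE = as.integer(tab[, 1L]),
             n_RE = as.integer(tab[, 2L]),
             pct_of_SE = if (n_se_total > 0)
               round_half_up(100 * as.integer(tab[, 1L]) / n_se_total, 1)
             else rep(0, nrow(tab)),
             stringsAsFactors = FALSE, row.names = NULL)
}
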