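#' Configuration for a synthetic dependency panel
#'
#' Bundles and validates the knobs of [generate_panel()]. Defaults
#' emulate the study conditions: a 19-line panel with heterogeneous
#' dependency scores, two co-regulated marks (H3K27ac, BRD4), planted
#' dependency-associated loci at a target rank-correlation, negative
#' binomial tag-count noise, planted TF co-binding structure and dense
#' high-signal locus clusters standing in for super-enhancers.
#'
#' @param n_lines Number of cell lines (default 19).
#' @param n_loci Number of master loci.
#' @param frac_tss Fraction of loci that are TSS (H3K4me3-positive).
#' @param n_pos_planted,n_neg_planted Numbers of loci whose signal
#'   increases / decreases with the dependency score (default 5% of
#'   `n_loci` each).
#' @param effect_tau Target magnitude of the Kendall correlation between
#'   planted-locus counts and dependency, in `(0, 1]`.
#' @param dispersion Negative-binomial dispersion of the counts
#'   (variance `mu + dispersion * mu^2`); 0 gives deterministic counts
#'   equal to the mean curve (the noiseless limit).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param baseline_mean Baseline expected tag count per locus and line.
#' @param signal_sd Log-scale spread of the planted signal across lines.
#' @param dep_range Interval the dependency scores are drawn uniformly
#'   from.
#' @param detect_threshold Count at or above which a locus is "detected"
#'   in a sample (presence flag); the default, `baseline_mean`, detects
#'   null loci in roughly half the samples.
#' @param locus_width Width of each locus in bp.
#' @param big_gap,se_gap Gap between consecutive loci, outside and
#'   inside planted SE clusters.
#' @param n_se_clusters,se_cluster_size Number and size (in loci) of
#'   planted dense high-signal CRE clusters.
#' @param se_boost Multiplicative signal boost of SE-cluster loci.
#' @param inactive_factor Multiplicative mark-signal reduction at
#'   inactive loci (H3K27ac/BRD4 means scale by this factor).
#' @return A validated list of class `panel_config`.
#' @export
panel_config <- function(n_lines = 19L, n_loci = 1000L, frac_tss = 0.3,
                         n_pos_planted = round(0.05 * n_loci),
                         n_neg_planted = round(0.05 * n_loci),
                         effect_tau = 0.6, dispersion = 0.2, seed = 1L,
                         baseline_mean = 50, signal_sd = 1.0,
                         dep_range = c(0, 1),
                         detect_threshold = baseline_mean,
                         locus_width = 1000L, big_gap = 20000L,
                         se_gap = 2000L, n_se_clusters = 5L,
                         se_cluster_size = 3L, se_boost = 8,
                         inactive_factor = 0.1) {
  cfg <- as.list(environment())
  if (n_lines < 3L) stop("n_lines must be at least 3")
  if (n_loci <= 0L) stop("n_loci must be positive")
  if (frac_tss < 0 || frac_tss > 1) stop("frac_tss must lie in [0, 1]")
  if (n_pos_planted < 0L || n_neg_planted < 0L)
    stop("planted counts must be non-negative")
  if (n_pos_planted + n_neg_planted > n_loci)
    stop("n_pos_planted + n_neg_planted must not exceed n_loci")
  if (effect_tau <= 0 || effect_tau > 1)
    stop("effect_tau must lie in (0, 1]")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  structure(cfg, class = "panel_config")
}

#' Generate a synthetic dependency panel with recorded ground truth
#'
#' Builds, deterministically from `config$seed`, a complete in-memory
#' panel on a single synthetic contig `chrS`:
#' \itemize{
#'   \item per-line dependency scores (uniform on `dep_range`), the
#'     matching competition growth rate (`-dependency` log2 units/day)
#'     and a discretized PTF score 0-5;
#'   \item non-overlapping loci, TSS/CRE and active/inactive labels, TF
#'     co-binding bitmasks over Jun/Sox2/Sox5/Twist2/Yap, and planted
#'     dense high-signal CRE clusters (SE membership);
#'   \item loci x lines count matrices for H3K27ac and BRD4. Planted
#'     loci follow mean curves monotone in dependency (concordant across
#'     the two marks, Gaussian-copula blend calibrated so the realized
#'     count-vs-dependency Kendall tau targets `effect_tau`); null loci
#'     are exchangeable across lines. Counts are negative binomial, or
#'     the mean itself at `dispersion = 0`;
#'   \item per-sample presence flags and per-antibody peak sets: H3K27ac
#'     and BRD4 peaks per line (loci detected in that line), and
#'     H3K4me3/Jun/Sox2/Sox5/Twist2/Yap peaks for the focal line (the
#'     line with the lowest dependency, where TF profiling is done);
#'   \item competition FACS series per line and per-TF footprint
#'     protection factors.
#' }
#'
#' @param config A [panel_config()].
#' @return List of class `synthetic_panel`: `config`, `truth` (list:
#'   `lines`, `loci` data.frames, `protection`), `counts` (list of two
#'   matrices), `presence` (list of two logical matrices), `peaks`
#'   (list antibody -> list sample -> `GRanges`), `facs` (long
#'   data.frame), `focal_line`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, {
    n <- config$n_lines
    p <- config$n_loci
    lines <- sprintf("line%02d", seq_len(n))

    dep <- stats::runif(n, config$dep_range[1L], config$dep_range[2L])
    dep_scaled <- (dep - config$dep_range[1L]) /
      diff(config$dep_range)
    lines_df <- data.frame(
      line_id = lines,
      dependency = dep,
      growth_rate = -dep,  # log2 units/day; dependent lines collapse
      ptf_score = as.integer(round_half_up(5 * (1 - dep_scaled))),
      stringsAsFactors = FALSE)

    ## --- loci, states, TF masks -------------------------------------
    # planted SE clusters: runs of consecutive loci, forced to CRE so
    # each cluster stays contiguous on the contig
    se_member <- rep(FALSE, p)
    need <- config$n_se_clusters * config$se_cluster_size
    if (need > 0L && need <= p) {
      starts <- floor(seq_len(config$n_se_clusters) *
                        p / (config$n_se_clusters + 1L))
      starts <- pmax(1L, pmin(starts, p - config$se_cluster_size + 1L))
      for (s in starts)
        se_member[s:(s + config$se_cluster_size - 1L)] <- TRUE
    }
    is_tss <- stats::runif(p) < config$frac_tss
    is_tss[se_member] <- FALSE
    lab <- rep("null", p)
    planted <- sample.int(p, config$n_pos_planted + config$n_neg_planted)
    lab[head(planted, config$n_pos_planted)] <- "pos"
    lab[tail(planted, config$n_neg_planted)] <- "neg"

    gaps <- ifelse(se_member & c(FALSE, se_member[-p]),
                   config$se_gap, config$big_gap)
    starts0 <- cumsum(c(1000, gaps[-1] + config$locus_width))
    loci <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(start = starts0 + 1L,
                       width = config$locus_width))

    active_prob <- ifelse(is_tss, 0.44, 0.24)
    active_prob[se_member] <- 1
    is_active <- stats::runif(p) < active_prob
    # screened loci must carry mark signal in the panel, as in the
    # active-in->=3-lines precondition of the real screen
    is_active[lab != "null"] <- TRUE

    # co-binding: active sites are co-bound by most of the TF set,
    # inactive sites rarely by more than one
    probs_active <- c(0.10, 0.10, 0.15, 0.25, 0.40)
    probs_inactive <- c(0.55, 0.30, 0.10, 0.04, 0.01)
    n_bound <- ifelse(is_active,
                      sample.int(5L, p, TRUE, probs_active),
                      sample.int(5L, p, TRUE, probs_inactive)) - 1L
    n_bound[se_member] <- 4L
    tfs <- c("jun", "sox2", "sox5", "twist2")
    mask <- matrix(FALSE, p, 4L, dimnames = list(NULL, tfs))
    for (i in seq_len(p))
      if (n_bound[i] > 0L)
        mask[i, sample.int(4L, n_bound[i])] <- TRUE
    yap_prob <- ifelse(n_bound >= 3L, 0.7, ifelse(is_active, 0.3, 0.05))
    yap_bound <- stats::runif(p) < yap_prob

    loci_df <- data.frame(
      locus = locus_keys(loci),
      label = factor(lab, levels = c("pos", "neg", "null")),
      is_tss = is_tss, is_active = is_active,
      state = paste0(ifelse(is_active, "active_", "inactive_"),
                     ifelse(is_tss, "TSS", "CRE")),
      jun = mask[, "jun"], sox2 = mask[, "sox2"],
      sox5 = mask[, "sox5"], twist2 = mask[, "twist2"],
      yap_bound = yap_bound, se_member = se_member,
      stringsAsFactors = FALSE)

    ## --- counts ------------------------------------------------------
    direction <- ifelse(lab == "pos", 1, ifelse(lab == "neg", -1, 0))
    z_dep <- stats::qnorm((rank(dep) - 0.5) / n)
    rho <- sin(pi * config$effect_tau / 2)
    if (config$dispersion > 0 || config$baseline_mean < Inf) {
      # lognormal approximation to the NB noise the ranks must survive
      noise_var <- log(1 + 1 / config$baseline_mean + config$dispersion)
    } else noise_var <- 0
    atten <- sqrt(config$signal_sd^2 / (config$signal_sd^2 + noise_var))
    rho_adj <- if (config$dispersion > 0) min(1, rho / atten) else rho

    base <- config$baseline_mean *
      ifelse(is_active, 1, config$inactive_factor) *
      ifelse(se_member, config$se_boost, 1)
    draw_mark <- function() {
      mu <- matrix(rep(base, n), nrow = p)
      pl <- which(direction != 0)
      if (length(pl)) {
        z <- rho_adj * matrix(rep(z_dep, length(pl)), ncol = n, byrow = TRUE) +
          sqrt(1 - rho_adj^2) *
          matrix(stats::rnorm(length(pl) * n), ncol = n)
        mu[pl, ] <- mu[pl, ] *
          exp(config$signal_sd * direction[pl] * z -
                config$signal_sd^2 / 2)
      }
      cnt <- if (config$dispersion > 0)
        matrix(stats::rnbinom(p * n, mu = mu, size = 1 / config$dispersion),
               nrow = p)
      else mu
      dimnames(cnt) <- list(locus_keys(loci), lines)
      cnt
    }
    counts <- list(H3K27ac = draw_mark(), Brd4 = draw_mark())
    presence <- lapply(counts, function(m) m >= config$detect_threshold)

    ## --- peaks -------------------------------------------------------
    # the focal line (lowest dependency, where TF profiling is done) has
    # its mark peak calls pinned to the planted activity states, standing
    # for deep profiling; other lines are detection-based
    focal <- lines[which.min(dep)]
    for (mark in names(presence))
      presence[[mark]][, focal] <- is_active
    mark_peaks <- function(mark) {
      out <- lapply(lines, function(l) {
        sel <- presence[[mark]][, l]
        g <- loci[sel]
        S4Vectors::mcols(g) <- S4Vectors::DataFrame(
          name = loci_df$locus[sel],
          score = counts[[mark]][sel, l],
          sample = rep(l, sum(sel)))
        g
      })
      names(out) <- lines
      out
    }
    peaks <- list(H3K27ac = mark_peaks("H3K27ac"),
                  Brd4 = mark_peaks("Brd4"))
    focal_set <- function(sel) {
      g <- loci[sel]
      S4Vectors::mcols(g) <- S4Vectors::DataFrame(
        name = loci_df$locus[sel],
        score = rep(1, sum(sel)),
        sample = rep(focal, sum(sel)))
      stats::setNames(list(g), focal)
    }
    peaks$H3K4me3 <- focal_set(is_tss)
    peaks$Jun <- focal_set(mask[, "jun"])
    peaks$Sox2 <- focal_set(mask[, "sox2"])
    peaks$Sox5 <- focal_set(mask[, "sox5"])
    peaks$Twist2 <- focal_set(mask[, "twist2"])
    peaks$Yap <- focal_set(yap_bound)

    ## --- competition assays ------------------------------------------
    facs <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- simulate_competition(rate_ref = 0,
                                rate_test = lines_df$growth_rate[i],
                                days = c(0, 3, 7, 10, 14),
                                n_cells = 10000L)
      cbind(line_id = lines[i], s)
    }))

    protection <- data.frame(
      tf = c("Jun", "Sox2", "Sox5", "Twist2"),
      protection = c(0.75, 0.60, 0.10, 0.30),
      stringsAsFactors = FALSE)

    structure(list(config = config,
                   truth = list(lines = lines_df, loci = loci_df,
                                protection = protection),
                   loci = loci,
                   counts = counts, presence = presence, peaks = peaks,
                   facs = facs, focal_line = focal),
              class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("synthetic_panel:", x$config$n_loci, "loci x", x$config$n_lines,
      "lines;", sum(x$truth$loci$label != "null"), "planted loci;",
      "focal line", x$focal_line, "\n")
  invisible(x)
}

#' Write a synthetic panel to plain-text fixture files
#'
#' Emits, under `dir`: one BED6+1 per antibody and sample
#' (`peaks/<antibody>.<sample>.bed`), TSV count matrices
#' (`counts_<mark>.tsv`), the FACS competition table (`facs.tsv`), the
#' ground-truth tables (`truth_lines.tsv`, `truth_loci.tsv`,
#' `truth_protection.tsv`) and the configuration (`config.json`). All
#' intervals are 0-based half-open. Output is byte-identical for a
#' fixed-config, fixed-seed panel.
#'
#' @param panel A `synthetic_panel` from [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  for (ab in names(panel$peaks))
    for (smp in names(panel$peaks[[ab]]))
      write_bed(panel$peaks[[ab]][[smp]],
                file.path(dir, "peaks", paste0(ab, ".", smp, ".bed")))
  for (mark in names(panel$counts))
    write_count_matrix(panel$counts[[mark]],
                       file.path(dir, paste0("counts_", mark, ".tsv")))
  data.table::fwrite(panel$facs, file.path(dir, "facs.tsv"), sep = "\t")
  data.table::fwrite(panel$truth$lines, file.path(dir, "truth_lines.tsv"),
                     sep = "\t")
  data.table::fwrite(panel$truth$loci, file.path(dir, "truth_loci.tsv"),
                     sep = "\t")
  data.table::fwrite(panel$truth$protection,
                     file.path(dir, "truth_protection.tsv"), sep = "\t")
  cfg <- unclass(panel$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate a two-population competition assay
#'
#' Equal numbers of a test and a reference population are mixed at day 0
#' and grown together; at each sampled day the expected fractions follow
#' exponential growth at `rate_test` and `rate_ref` (log2 units/day)
#' from a 50/50 start, and the observed counts are a multinomial draw of
#' `n_cells` cells at those fractions.
#'
#' @param rate_ref,rate_test Growth rates in log2 units per day.
#' @param days Sorted numeric vector of sampling days (non-empty).
#' @param n_cells Cells scored by FACS per timepoint (> 0).
#' @param seed Optional seed (the caller's RNG state is restored).
#' @return `data.frame`: `day`, `count_test`, `count_ref`.
#' @export
simulate_competition <- function(rate_ref, rate_test, days,
                                 n_cells = 10000L, seed = NULL) {
  if (!length(days)) stop("days must be non-empty")
  if (is.unsorted(days)) stop("days must be sorted")
  if (n_cells <= 0) stop("n_cells must be positive")
  with_seed(seed, {
    frac_test <- 2^(rate_test * days) /
      (2^(rate_test * days) + 2^(rate_ref * days))
    ct <- stats::rbinom(length(days), n_cells, frac_test)
    data.frame(day = days, count_test = ct, count_ref = n_cells - ct)
  })
}

#' Simulate Tn5 insertion profiles around motif sites
#'
#' Per-base insertion counts are Poisson with rate `background_rate` in
#' the outer window, `background_rate * flank_fold` in the two flanks
#' (the accessible chromatin opened around a bound factor) and
#' `background_rate * flank_fold * (1 - protection)` in the motif core
#' (the factor shields its motif from tagmentation).
#'
#' @param background_rate Poisson rate in the outer window (> 0).
#' @param flank_fold Fold enrichment of the flanks over background.
#' @param protection Fraction of flank-level insertions blocked in the
#'   core, in `[0, 1]`.
#' @param motif_width Core width in bp.
#' @param window Half-width of the window on each side of the core, in
#'   bp (must exceed `motif_width`).
#' @param n_sites Number of sites to simulate.
#' @param flank_width Width of each flank in bp (default 20).
#' @param seed Optional seed.
#' @return List: `profiles` (`n_sites` x `2 * window + motif_width`
#'   matrix), `strand` (alternating `+`/`-`), `rate` (the per-base rate
#'   vector), and the geometry parameters.
#' @export
simulate_insertion_profiles <- function(background_rate = 1, flank_fold = 4,
                                        protection = 0.75, motif_width = 12L,
                                        window = 100L, n_sites = 2000L,
                                        flank_width = 20L, seed = NULL) {
  if (background_rate <= 0 || flank_fold <= 0)
    stop("rates must be positive")
  if (protection < 0 || protection > 1)
    stop("protection must lie in [0, 1]")
  if (window <= motif_width)
    stop("window must exceed motif_width")
  L <- 2L * window + motif_width
  rate <- rep(background_rate, L)
  core <- (window + 1L):(window + motif_width)
  flank <- c((window - flank_width + 1L):window,
             (window + motif_width + 1L):(window + motif_width + flank_width))
  rate[flank] <- background_rate * flank_fold
  rate[core] <- background_rate * flank_fold * (1 - protection)
  with_seed(seed, {
    profiles <- matrix(stats::rpois(n_sites * L, rep(rate, each = n_sites)),
                       nrow = n_sites)
    list(profiles = profiles,
         strand = rep(c("+", "-"), length.out = n_sites),
         rate = rate, motif_width = motif_width, window = window,
         flank_width = flank_width, protection = protection)
  })
}
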