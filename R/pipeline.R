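#' Assemble and validate a pipeline run configuration
#'
#' Flat key space; every analysis parameter defaults to the pipeline's
#' canonical value (Kendall cutoff 0.3, presence in >= 3 samples,
#' maximal normalized count >= 10, bin widths 1250/10800 bp, stitch gap
#' 12500 bp, flank width 20 bp).
#'
#' @param input_dir Directory holding the panel files, laid out as
#'   written by [write_panel()]: `peaks/<antibody>.<sample>.bed`,
#'   `counts_H3K27ac.tsv`, `counts_Brd4.tsv`, `facs.tsv`.
#' @param output_dir Directory for stage outputs (created).
#' @param cutoff,min_samples,min_max_count,stitch_gap,flank_width,ptf_frac
#'   Stage parameters; see the stage functions.
#' @param tf_bin_width,histone_bin_width Bin widths used when factors
#'   are computed from fragment files.
#' @param seed Seed logged and used for any stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       cutoff = 0.3, min_samples = 3L, min_max_count = 10,
                       stitch_gap = 12500L, flank_width = 20L,
                       ptf_frac = 0.25,
                       tf_bin_width = 1250L, histone_bin_width = 10800L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  structure(cfg, class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

read_panel_peaks <- function(dir) {
  files <- list.files(file.path(dir, "peaks"), pattern = "\\.bed$",
                      full.names = TRUE)
  if (!length(files)) stop("no peak BED files under ", dir, "/peaks")
  parts <- strsplit(sub("\\.bed$", "", basename(files)), ".", fixed = TRUE)
  ab <- vapply(parts, `[`, "", 1L)
  smp <- vapply(parts, `[`, "", 2L)
  out <- list()
  for (i in seq_along(files))
    out[[ab[i]]][[smp[i]]] <- read_bed(files[i])
  out
}

#' Run the full screening pipeline on an input directory
#'
#' Executes the stages in order — dependency scoring, normalization,
#' the cross-mark Kendall screen, chromatin-state classification with
#' super-enhancer stitching, and (when motif-site profiles are present)
#' footprint quantification — writing each stage's tables under
#' `config$output_dir` and logging parameters and record counts. A
#' machine-readable `summary.json` collects the headline counts; the
#' function also returns them invisibly. Any stage error aborts the run
#' with a nonzero condition while earlier outputs are preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(parameters = unclass(config))

  ## stage 1: dependency scoring -------------------------------------
  stage_log("score-dependency", "reading ", config$input_dir, "/facs.tsv")
  facs_path <- file.path(config$input_dir, "facs.tsv")
  if (!file.exists(facs_path)) stop("missing scores input: ", facs_path)
  facs <- as.data.frame(data.table::fread(facs_path))
  dep <- dependency_scores(facs)
  data.table::fwrite(dep, file.path(config$output_dir, "dependency.tsv"),
                     sep = "\t")
  stage_log("score-dependency", nrow(dep), " lines scored")
  summary$n_lines <- nrow(dep)

  ## stage 2: normalization ------------------------------------------
  counts <- list()
  norm <- list()
  for (mark in c("H3K27ac", "Brd4")) {
    path <- file.path(config$input_dir, paste0("counts_", mark, ".tsv"))
    if (!file.exists(path)) stop("missing count matrix: ", path)
    raw <- read_count_matrix(path)
    fac <- tmm_factors(raw)
    nm <- normalize_counts(raw, fac)
    counts[[mark]] <- raw
    norm[[mark]] <- nm
    data.table::fwrite(fac, file.path(config$output_dir,
                                      paste0("factors_", mark, ".tsv")),
                       sep = "\t")
    write_count_matrix(nm, file.path(config$output_dir,
                                     paste0("norm_", mark, ".tsv")))
    stage_log("normalize", mark, ": ", nrow(raw), " loci x ", ncol(raw),
              " samples; ref ", attr(fac, "ref"))
  }

  ## stage 3: screen ---------------------------------------------------
  peaks <- read_panel_peaks(config$input_dir)
  for (mark in c("H3K27ac", "Brd4"))
    if (is.null(peaks[[mark]])) stop("missing per-sample peaks for ", mark)
  mt <- list(
    H3K27ac = build_master_table(peaks$H3K27ac, norm$H3K27ac, "H3K27ac"),
    Brd4 = build_master_table(peaks$Brd4, norm$Brd4, "Brd4"))
  pairs <- filter_for_screen(mt$H3K27ac, mt$Brd4,
                             min_samples = config$min_samples,
                             min_max_count = config$min_max_count)
  scores <- stats::setNames(dep$yap_dependency, dep$line_id)
  scr <- dependency_screen(pairs, mt$H3K27ac, mt$Brd4, scores,
                           cutoff = config$cutoff)
  data.table::fwrite(scr, file.path(config$output_dir, "screen.tsv"),
                     sep = "\t")
  for (lb in c("YapD_H", "YapD_L")) {
    g <- keys_to_granges(scr$k27ac_locus[scr$label == lb])
    if (length(g)) {
      g$name <- sprintf("%.3f|%.3f", scr$tau_k27ac[scr$label == lb],
                        scr$tau_brd4[scr$label == lb])
      g$score <- scr$tau_k27ac[scr$label == lb]
    }
    write_bed(g, file.path(config$output_dir, paste0(lb, ".bed")))
  }
  if (nrow(scr) > 2L) {
    rr <- rrho_map(scr$tau_k27ac, scr$tau_brd4)
    data.table::fwrite(data.table::as.data.table(rr$up_up),
                       file.path(config$output_dir, "rrho_up_up.tsv"),
                       sep = "\t")
  }
  stage_log("screen", nrow(scr), " paired loci; ",
            sum(scr$label == "YapD_H"), " YapD_H, ",
            sum(scr$label == "YapD_L"), " YapD_L at cutoff ", config$cutoff)
  summary$screen <- list(
    n_master_k27ac = length(mt$H3K27ac$loci),
    n_master_brd4 = length(mt$Brd4$loci),
    n_filtered_pairs = nrow(scr),
    n_yapd_high = sum(scr$label == "YapD_H"),
    n_yapd_low = sum(scr$label == "YapD_L"))

  ## stage 4: classify -------------------------------------------------
  tf_abs <- c("H3K4me3", "Jun", "Sox2", "Sox5", "Twist2", "Yap")
  focal_peaks <- list()
  focal <- NULL
  for (ab in tf_abs) {
    if (!is.null(peaks[[ab]])) {
      focal <- focal %||% names(peaks[[ab]])[1L]
      focal_peaks[[ab]] <- peaks[[ab]][[focal]]
    }
  }
  summary$classify <- NULL
  if (length(focal_peaks) && !is.null(focal)) {
    focal_peaks$H3K27ac <- peaks$H3K27ac[[focal]]
    focal_peaks$Brd4 <- peaks$Brd4[[focal]]
    focal_peaks <- Filter(Negate(is.null), focal_peaks)
    master <- build_master_table(focal_peaks, antibody = "all")
    ann <- classify_states(master$loci, focal_peaks)
    data.table::fwrite(ann, file.path(config$output_dir, "annotation.tsv"),
                       sep = "\t")
    comb <- combination_counts(ann)
    data.table::fwrite(comb,
                       file.path(config$output_dir, "combinations.tsv"),
                       sep = "\t")
    cre <- ann[!ann$is_tss & ann$is_active, , drop = FALSE]
    summary$classify <- list(
      focal_sample = focal,
      n_master = nrow(ann),
      n_tss = sum(ann$is_tss), n_cre = sum(!ann$is_tss),
      n_active_tss = sum(ann$is_tss & ann$is_active),
      n_active_cre = sum(!ann$is_tss & ann$is_active),
      cluster7 = as.list(table(ann$cluster7)))
    if (any(ann$yap_bound)) {
      ys <- yap_cobinding_summary(ann)
      summary$classify$yap_cobinding <- ys[c("n_yap", "n_any", "n_all4",
                                             "pct_any", "pct_all4")]
    }
    if (nrow(cre) >= 1L) {
      g <- keys_to_granges(cre$locus)
      sig <- norm$H3K27ac[match(cre$locus, rownames(norm$H3K27ac)), focal]
      sig[is.na(sig)] <- 0
      se <- stitch_superenhancers(g, sig, stitch_gap = config$stitch_gap)
      data.table::fwrite(se, file.path(config$output_dir, "stitched.tsv"),
                         sep = "\t")
      se_gr <- GenomicRanges::GRanges(se$chrom[se$is_SE],
                                      IRanges::IRanges(se$start[se$is_SE] + 1L,
                                                       se$end[se$is_SE]))
      write_bed(se_gr, file.path(config$output_dir, "SE.bed"))
      summary$classify$n_stitched <- nrow(se)
      summary$classify$n_SE <- sum(se$is_SE)
      ov <- se_overlap_summary(ann, se)
      data.table::fwrite(ov, file.path(config$output_dir, "se_overlap.tsv"),
                         sep = "\t")
    }
    stage_log("classify", nrow(ann), " master loci (",
              sum(ann$is_tss), " TSS / ", sum(!ann$is_tss), " CRE); ",
              summary$classify$n_SE %||% 0, " SE")
  } else {
    stage_log("classify", "no TF/histone peak sets found; stage skipped")
  }

  ## stage 5: footprint ------------------------------------------------
  prof_path <- file.path(config$input_dir, "profiles.tsv")
  summary$footprint <- NULL
  if (file.exists(prof_path)) {
    prof <- as.matrix(data.table::fread(prof_path))
    agg <- aggregate_profile(prof)
    fm <- footprint_metrics(agg, motif_width = 12L,
                            flank_width = config$flank_width)
    depths <- apply(prof, 1L, function(p)
      footprint_metrics(p, motif_width = 12L,
                        flank_width = config$flank_width)$footprint_depth)
    cb <- classify_bound(depths)
    summary$footprint <- list(
      n_sites = nrow(prof),
      flank_height = fm$flank_height,
      relative_depth = fm$relative_depth,
      n_bound = sum(cb$bound), n_unbound = sum(!cb$bound))
    stage_log("footprint", nrow(prof), " sites; ", sum(cb$bound), " bound")
  }

  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
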