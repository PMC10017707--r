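#' Read a BED file into a GRanges
#'
#' Accepts BED3, BED6 and BED6+1 (an extra `sample` column, as written by
#' [write_peaks()]). Coordinates on disk are 0-based half-open; the
#' returned [GenomicRanges::GRanges] follows the usual 1-based closed
#' convention. `track`/`browser` and `#` comment lines are skipped. The
#' `score` column may be any real number (tag densities are not capped at
#' the UCSC 0-1000 range).
#'
#' @param path Path to a tab-separated BED file.
#' @return A `GRanges`; metadata columns `name`, `score`, `sample` when
#'   present in the file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (length(lineno) == 0L)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 fields")
  ncol_use <- min(nf)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(ncol_use))),
              ncol = ncol_use, byrow = TRUE)
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end0 <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], ": non-numeric coordinates")
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], ": start >= end")
  strand <- if (ncol_use >= 6L) m[, 6L] else rep("*", nrow(m))
  bad <- which(!strand %in% c("+", "-", ".", "*"))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], ": unknown strand '",
         strand[bad[1L]], "'")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand)
  if (ncol_use >= 4L) gr$name <- m[, 4L]
  if (ncol_use >= 5L) gr$score <- suppressWarnings(as.numeric(m[, 5L]))
  if (ncol_use >= 7L) gr$sample <- m[, 7L]
  gr
}

#' Write a GRanges as BED
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates and the
#' `name`, `score` and `sample` metadata columns when present, producing
#' BED3/BED6/BED6+1 accordingly. Round-trip through [read_bed()] is the
#' identity.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  has_sample <- !is.null(gr$sample)
  if (!is.null(gr$name) || !is.null(gr$score) || has_sample) {
    df$name <- gr$name %||% rep(".", length(gr))
    df$score <- gr$score %||% rep(0, length(gr))
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "."
    df$strand <- st
    if (has_sample) df$sample <- gr$sample
  }
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a loci-by-samples count matrix
#'
#' Plain TSV with a `locus` first column holding `chrom:start-end` keys
#' (0-based half-open) and one column per sample.
#'
#' @param path TSV path.
#' @return Numeric matrix with locus keys as rownames.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_count_matrix
#' @param mat Matrix with locus-key rownames.
#' @export
write_count_matrix <- function(mat, path) {
  dt <- data.table::data.table(locus = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Convert between GRanges and `chrom:start-end` locus keys
#'
#' Keys use 0-based half-open coordinates, matching the BED convention of
#' the on-disk matrices.
#'
#' @param gr A `GRanges`.
#' @return Character vector of keys.
#' @export
locus_keys <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' @rdname locus_keys
#' @param keys Character vector of `chrom:start-end` keys.
#' @export
keys_to_granges <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+)$", keys))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop("malformed locus key: ", keys[bad[1L]])
  ch <- vapply(m, `[`, "", 2L)
  s0 <- as.integer(vapply(m, `[`, "", 3L))
  e0 <- as.integer(vapply(m, `[`, "", 4L))
  GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1L, e0))
}

#' Read a bedGraph track
#'
#' 4-column `chrom start end value` with 0-based half-open intervals.
#'
#' @param path bedGraph path.
#' @return `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(dt$start + 1L, dt$end),
                         score = dt$value)
}

#' @rdname read_bedgraph
#' @param gr `GRanges` with a `score` column.
#' @export
write_bedgraph <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
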