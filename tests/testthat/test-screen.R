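test_that("master merge unions per-sample peaks, merging book-ended intervals", {
  pk <- GenomicRanges::GRanges("chrS", IRanges::IRanges(101, 200))
  mt <- build_master_table(list(s1 = pk, s2 = pk))
  expect_length(mt$loci, 1L)
  expect_true(all(mt$presence))

  # [100,200) and [200,300) in BED space are book-ended: merged
  a <- GenomicRanges::GRanges("chrS", IRanges::IRanges(101, 200))
  b <- GenomicRanges::GRanges("chrS", IRanges::IRanges(201, 300))
  mt2 <- build_master_table(list(s1 = a, s2 = b))
  expect_equal(locus_keys(mt2$loci), "chrS:100-300")
  expect_equal(unname(mt2$presence[1, ]), c(TRUE, TRUE))
})

test_that("master merge equals a sweep-line oracle on random peak sets", {
  set.seed(14)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) random_peaks(60))
    names(sets) <- paste0("s", 1:4)
    mt <- build_master_table(sets)
    all_df <- do.call(rbind, lapply(sets, function(g)
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(g)),
                 start = GenomicRanges::start(g) - 1L,
                 end = GenomicRanges::end(g))))
    oracle <- brute_merge(all_df$chrom, all_df$start, all_df$end)
    oracle <- oracle[order(oracle$chrom, oracle$start), ]
    got <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(mt$loci)),
                      start = GenomicRanges::start(mt$loci) - 1L,
                      end = GenomicRanges::end(mt$loci))
    got <- got[order(got$chrom, got$start), ]
    expect_equal(got, oracle, ignore_attr = TRUE)
  }
})

make_table <- function(loci, presence, counts, antibody) {
  sets <- lapply(colnames(presence), function(s) loci[presence[, s]])
  names(sets) <- colnames(presence)
  rownames(counts) <- locus_keys(loci)
  colnames(counts) <- colnames(presence)
  build_master_table(sets, counts, antibody)
}

test_that("screen filters drop sparse, weak and unpaired loci at the stated boundaries", {
  loci <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(c(1, 5001, 10001, 15001), width = 1000))
  samples <- paste0("s", 1:5)
  pres <- matrix(TRUE, 4, 5, dimnames = list(NULL, samples))
  pres[1, 3:5] <- FALSE            # locus 1 detected in only 2 samples
  cnt <- matrix(50, 4, 5)
  cnt[2, ] <- c(10, 3, 2, 1, 1)    # locus 2 max exactly 10: retained
  cnt[3, ] <- 9.9                  # locus 3 max < 10: removed
  k27 <- make_table(loci, pres, cnt, "H3K27ac")
  # other mark: loci 1-3 same coordinates, locus 4 not covered
  brd4 <- make_table(loci[1:3], matrix(TRUE, 3, 5,
                                       dimnames = list(NULL, samples)),
                     matrix(60, 3, 5), "Brd4")
  pairs <- filter_for_screen(k27, brd4, min_samples = 3L, min_max_count = 10)
  expect_equal(pairs$k27ac_idx, 2L)  # 1 too sparse, 3 too weak, 4 unpaired
  expect_equal(unname(attr(pairs, "keep_k27ac")),
               c(FALSE, TRUE, FALSE, TRUE))
})

test_that("cross-mark pairing picks the maximal-overlap partner, leftmost on ties", {
  samples <- paste0("s", 1:3)
  k_loci <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1001, 2000))
  b_loci <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(c(801, 1501), c(1400, 2600)))  # overlaps 400 and 500 bp
  k27 <- make_table(k_loci, matrix(TRUE, 1, 3, dimnames = list(NULL, samples)),
                    matrix(50, 1, 3), "H3K27ac")
  brd4 <- make_table(b_loci, matrix(TRUE, 2, 3, dimnames = list(NULL, samples)),
                     matrix(50, 2, 3), "Brd4")
  pairs <- filter_for_screen(k27, brd4)
  expect_equal(pairs$brd4_idx, 2L)
  expect_equal(pairs$overlap_bp, 500L)
})

test_that("kendall_tau agrees with the pairwise brute-force oracle", {
  expect_equal(kendall_tau(1:10, 1:10), 1)
  expect_equal(kendall_tau(1:10, 10:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3)), 1 / 3,
               tolerance = 1e-12)
  set.seed(77)
  for (i in 1:25) {
    x <- rnorm(19); y <- rnorm(19)
    expect_equal(kendall_tau(x, y), brute_kendall(x, y), tolerance = 1e-12)
    # with ties (tau-b)
    xt <- sample(1:5, 19, replace = TRUE)
    yt <- sample(1:4, 19, replace = TRUE)
    expect_equal(kendall_tau(xt, yt), brute_kendall(xt, yt),
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "all-tied")
  expect_error(kendall_tau(1:4, 1:5), "equal length")
})

test_that("concordance labels require both taus past the cutoff with matching sign", {
  set.seed(101)
  n <- 19
  dep <- runif(n)
  mk <- function(tau_target, sign) {
    # positive pseudo-counts with a controlled tau against dep
    r <- rank(dep)
    noise <- rank(rnorm(n))
    w <- tau_target
    sign * (w * r + (1 - w) * noise) + 100
  }
  loci <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(0:3 * 5000 + 1, width = 1000))
  samples <- sprintf("s%02d", 1:n)
  pres <- matrix(TRUE, 4, n, dimnames = list(NULL, samples))
  c1 <- rbind(mk(0.9, 1), mk(0.9, 1), mk(0.9, 1), mk(0.9, -1))
  c2 <- rbind(mk(0.9, 1), mk(0.05, 1), mk(0.9, -1), mk(0.9, -1))
  k27 <- make_table(loci, pres, c1, "H3K27ac")
  brd4 <- make_table(loci, pres, c2, "Brd4")
  pairs <- filter_for_screen(k27, brd4, min_max_count = 0)
  scr <- dependency_screen(pairs, k27, brd4, setNames(dep, samples))
  # locus 1: both strongly positive -> YapD_H
  expect_equal(as.character(scr$label[1]), "YapD_H")
  # locus 2: one mark below cutoff -> none
  expect_lt(abs(scr$tau_brd4[2]), 0.3)
  expect_equal(as.character(scr$label[2]), "none")
  # locus 3: discordant signs -> none
  expect_equal(as.character(scr$label[3]), "none")
  # locus 4: both strongly negative -> YapD_L
  expect_equal(as.character(scr$label[4]), "YapD_L")
  # labels invariant under a strictly monotone transform of the scores
  scr2 <- dependency_screen(pairs, k27, brd4,
                            setNames(exp(3 * dep) + 1, samples))
  expect_equal(scr2$label, scr$label)
  expect_equal(scr2$tau_k27ac, scr$tau_k27ac, tolerance = 1e-12)
})

test_that("screen labels partition: no locus is both YapD_H and YapD_L", {
  set.seed(23)
  pan <- generate_panel(panel_config(n_loci = 150, seed = 23))
  scr <- screen_panel(pan)
  expect_true(all(table(scr$label)[c("YapD_H", "YapD_L")] >= 0))
  expect_lte(sum(scr$label != "none"), nrow(scr))
  expect_equal(sum(scr$label == "YapD_H") + sum(scr$label == "YapD_L"),
               sum(scr$label != "none"))
})

test_that("RRHO cells equal hypergeometric tail sums, with the closed form on identical lists", {
  set.seed(31)
  N <- 60
  x <- rnorm(N)
  # identical rankings: full overlap at every threshold
  rr <- rrho_map(x, x, step = 10)
  for (a in seq_along(rr$steps)) {
    i <- rr$steps[a]
    expect_equal(rr$up_up[a, a], log10(choose(N, i)), tolerance = 1e-9)
  }
  # arbitrary lists vs direct summation of the tail
  y <- rnorm(N)
  rr2 <- rrho_map(x, y, step = 7)
  top <- function(v, k) order(v, decreasing = TRUE)[seq_len(k)]
  for (a in seq_along(rr2$steps)) for (b in seq_along(rr2$steps)) {
    i <- rr2$steps[a]; j <- rr2$steps[b]
    k <- length(intersect(top(x, i), top(y, j)))
    expect_equal(rr2$up_up[a, b], -log10(brute_hyper_tail(k, N, i, j)),
                 tolerance = 1e-9)
  }
  expect_error(rrho_map(x, y, step = N), "smaller")
})

test_that("signed RRHO quadrants mirror list reversal", {
  set.seed(67)
  x <- rnorm(40); y <- rnorm(40)
  rr <- rrho_map(x, y, step = 8, signed = TRUE)
  flip <- rrho_map(-x, -y, step = 8)
  expect_equal(rr$down_down, flip$up_up)
})

test_that("hierarchical ordering is reproducible and recovers planted clusters", {
  set.seed(19)
  centers <- matrix(c(0, 8, -8), 3, 10)
  mat <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(5 * 10, centers[k, 1]), 5, 10))) +
    matrix(rnorm(150, sd = 0.5), 15, 10)
  mat <- mat + matrix(rnorm(150, sd = 0.2), 15, 10)
  res <- cluster_heatmap_order(mat, scale = "none", k_rows = 3)
  truth <- rep(1:3, each = 5)
  expect_equal(length(unique(paste(res$row_clusters, truth))), 3L)
  # permuting rows does not change memberships
  perm <- sample(15)
  res2 <- cluster_heatmap_order(mat[perm, ], scale = "none", k_rows = 3)
  expect_equal(length(unique(paste(res2$row_clusters, truth[perm]))), 3L)
  # identical columns merge first at height 0
  m2 <- cbind(a = rnorm(8), b = rnorm(8))
  m2 <- cbind(m2, c = m2[, "a"])
  res3 <- cluster_heatmap_order(m2, scale = "none")
  expect_equal(min(res3$col_hclust$height), 0)
  expect_error(cluster_heatmap_order(rbind(rep(1, 5), rnorm(5)), scale = "row"),
               "constant row")
})
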