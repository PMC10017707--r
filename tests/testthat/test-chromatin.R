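gr1 <- function(start, end) {
  GenomicRanges::GRanges("chrS", IRanges::IRanges(start + 1L, end))
}

test_that("state flags and seven-cluster assignment follow the definitions", {
  # four loci: K4me3-only TSS; fully decorated TSS; active CRE bound by
  # Jun+Sox2; silent CRE bound by Jun+Sox2
  master <- gr1(c(0, 2000, 4000, 6000), c(1000, 3000, 5000, 7000))
  pk <- list(
    H3K4me3 = gr1(c(0, 2000), c(1000, 3000)),
    H3K27ac = gr1(c(2000, 4000), c(3000, 5000)),
    BRD4 = gr1(c(2000, 4000), c(3000, 5000)),
    Jun = gr1(c(2000, 4000, 6000), c(3000, 5000, 7000)),
    Sox2 = gr1(c(2000, 4000, 6000), c(3000, 5000, 7000)))
  ann <- classify_states(master, pk)
  expect_equal(as.character(ann$cluster7), c("p3", "p1", "e1", "e2"))
  expect_equal(as.character(ann$state),
               c("inactive_TSS", "active_TSS", "active_CRE", "inactive_CRE"))
  # K4me3+ only: TSS, inactive, residual promoter cluster
  expect_false(ann$is_active[1])
  # active CRE bound by Jun+Sox2 is NOT e2 (e2 requires K27ac- BRD4-)
  expect_equal(as.character(ann$cluster7[3]), "e1")
  # an uncovered master locus violates the construction
  expect_error(classify_states(gr1(90000, 91000), pk), "overlap no")
})

test_that("book-ended peaks do not annotate a locus (annotation needs shared bases)", {
  master <- gr1(1000, 2000)
  pk <- list(H3K4me3 = gr1(2000, 3000), H3K27ac = gr1(500, 1001))
  ann <- classify_states(master, pk)
  expect_false(ann$is_tss[1])
  expect_true(ann$h3k27ac[1])
})

test_that("combination categories partition each state class and respect the Sox5|Twist2 exclusion", {
  set.seed(41)
  n <- 400
  ann <- data.frame(
    is_tss = runif(n) < 0.3, is_active = runif(n) < 0.4,
    jun = runif(n) < 0.5, sox2 = runif(n) < 0.5,
    sox5 = runif(n) < 0.4, twist2 = runif(n) < 0.4,
    yap_bound = runif(n) < 0.5)
  ann$state <- factor(paste0(ifelse(ann$is_active, "active_", "inactive_"),
                             ifelse(ann$is_tss, "TSS", "CRE")),
                      levels = c("active_TSS", "inactive_TSS",
                                 "active_CRE", "inactive_CRE"))
  cc <- combination_counts(ann)
  expect_equal(as.vector(tapply(cc$count, cc$state, sum)),
               as.vector(table(ann$state)))
  # brute-force bitmask tally of the all-four category
  for (st in levels(ann$state)) {
    idx <- ann$state == st
    expect_equal(cc$count[cc$state == st &
                            cc$category == "Jun+Sox2+Sox5+Twist2+"],
                 sum(ann$jun[idx] & ann$sox2[idx] & ann$sox5[idx] &
                       ann$twist2[idx]))
    # exclusive Sox5|Twist2: exactly one of the pair, with one of Jun/Sox2
    expect_equal(cc$count[cc$state == st & cc$category == "Sox5|Twist2+"],
                 sum(idx & xor(ann$sox5, ann$twist2) &
                       (ann$jun + ann$sox2 + ann$sox5 + ann$twist2 == 2)))
  }
  # a site bound by both Sox5 and Twist2 never lands in Sox5|Twist2+
  both <- data.frame(is_tss = FALSE, is_active = TRUE,
                     jun = FALSE, sox2 = FALSE, sox5 = TRUE, twist2 = TRUE,
                     yap_bound = FALSE,
                     state = factor("active_CRE",
                                    levels = levels(ann$state)))
  cb <- combination_counts(both)
  expect_equal(cb$count[cb$category == "Sox5|Twist2+"], rep(0L, 4))
  # no TF peaks: everything in "none"
  none <- ann
  none$jun <- none$sox2 <- none$sox5 <- none$twist2 <- FALSE
  cn <- combination_counts(none)
  expect_equal(sum(cn$count[cn$category == "none"]), n)
})

test_that("Yap co-binding summary reproduces printed-percentage arithmetic", {
  n <- 5272
  ann <- data.frame(
    yap_bound = rep(TRUE, n),
    jun = c(rep(TRUE, 4858), rep(FALSE, n - 4858)),
    sox2 = c(rep(TRUE, 3201), rep(FALSE, n - 3201)),
    sox5 = c(rep(TRUE, 3201), rep(FALSE, n - 3201)),
    twist2 = c(rep(TRUE, 3201), rep(FALSE, n - 3201)))
  ys <- yap_cobinding_summary(ann)
  expect_equal(ys$n_any, 4858)
  expect_equal(ys$n_all4, 3201)
  expect_equal(ys$pct_any, 92)
  expect_equal(ys$pct_all4, 61)
  # all-bound degenerate case
  all4 <- data.frame(yap_bound = TRUE, jun = TRUE, sox2 = TRUE,
                     sox5 = TRUE, twist2 = TRUE)
  expect_equal(yap_cobinding_summary(all4)[c("pct_any", "pct_all4")],
               list(pct_any = 100, pct_all4 = 100))
  expect_error(yap_cobinding_summary(data.frame(yap_bound = FALSE)),
               "no Yap")
})

test_that("stitching respects the 12.5 kb gap boundary", {
  near <- gr1(c(0, 13499), c(1000, 14499))    # gap 12,499: stitched
  far <- gr1(c(0, 13501), c(1000, 14501))     # gap 12,501: separate
  expect_warning(se_near <- stitch_superenhancers(near, c(1, 1)),
                 "fewer than 3")
  expect_equal(nrow(se_near), 1L)
  expect_warning(se_far <- stitch_superenhancers(far, c(1, 1)),
                 "fewer than 3")
  expect_equal(nrow(se_far), 2L)
  expect_false(any(se_far$is_SE))
})

test_that("tangent cutoff flags the heavy tail and nothing on a flat curve", {
  set.seed(61)
  starts <- (0:99) * 30000
  loci <- gr1(starts, starts + 1000)
  sig <- c(rnorm(95, 1, 0.05), rnorm(5, 100, 3))
  se <- stitch_superenhancers(loci, sig)
  expect_equal(sum(se$is_SE), 5L)
  expect_true(all(se$total_signal[se$is_SE] >= attr(se, "cutoff")))
  expect_true(all(sort(se$total_signal[se$is_SE]) >
                    max(se$total_signal[!se$is_SE])))
  # all-equal signals: scaled curve degenerate, no SE
  flat <- stitch_superenhancers(loci, rep(3, 100))
  expect_equal(sum(flat$is_SE), 0L)
  expect_error(stitch_superenhancers(loci, rep(-1, 100)), "non-negative")
})

test_that("SE/RE split conserves regions and category totals", {
  set.seed(71)
  pan <- generate_panel(panel_config(n_loci = 200, seed = 71))
  fp <- focal_peak_sets(pan)
  mt <- build_master_table(fp)
  ann <- classify_states(mt$loci, fp)
  cre <- ann[!ann$is_tss, , drop = FALSE]
  g <- keys_to_granges(cre$locus)
  sig <- pan$counts$H3K27ac[match(cre$locus,
                                  rownames(pan$counts$H3K27ac)),
                            pan$focal_line]
  se <- stitch_superenhancers(g, sig)
  # SE u RE = all stitched regions
  expect_equal(sum(se$is_SE) + sum(!se$is_SE), nrow(se))
  ov <- se_overlap_summary(ann, se)
  cc <- combination_counts(ann)
  # per category, in-SE + in-RE equals the CRE combination totals
  cre_counts <- cc[grepl("CRE", cc$state), ]
  per_cat <- tapply(cre_counts$count, cre_counts$category, sum)
  expect_equal(ov$n_SE + ov$n_RE,
               as.integer(per_cat[as.character(ov$category)]))
  # no SE called -> zero in-SE everywhere
  ov0 <- se_overlap_summary(ann, se[0, ])
  expect_equal(sum(ov0$n_SE), 0L)
})
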