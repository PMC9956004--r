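test_that("exact matches give a clean confusion matrix", {
  preds <- data.frame(time_s = c(10, 100, 500))
  refs <- data.frame(time_s = c(10, 100, 500))
  m <- match_predictions(preds, refs, time_tolerance_s = 5)
  expect_equal(m$counts, confusion_counts(3, 0, 0))
})

test_that("double-counting one fish yields a tracking false positive", {
  preds <- data.frame(time_s = c(100, 103))
  refs <- data.frame(time_s = 101)
  m <- match_predictions(preds, refs, time_tolerance_s = 5)
  expect_equal(m$counts, confusion_counts(1, 1, 0))
  expect_equal(m$fp_category, "tracking")
})

test_that("missed fish become false negatives", {
  m <- match_predictions(data.frame(time_s = numeric(0)),
                         data.frame(time_s = c(1, 60, 120, 180) * 10))
  expect_equal(m$counts, confusion_counts(0, 0, 4))
})

test_that("matching respects the range tolerance when ranges exist", {
  preds <- data.frame(time_s = 100, range_m = 2)
  refs <- data.frame(time_s = 100, range_m = 8)
  m <- match_predictions(preds, refs, time_tolerance_s = 5,
                         range_tolerance_m = 1)
  expect_equal(m$counts, confusion_counts(0, 1, 1))
})

test_that("totals are invariant to shuffling equal-time predictions", {
  with_test_seed(51, {
    for (case in 1:50) {
      times <- sort(sample(0:120, 8)) * 2
      preds <- data.frame(time_s = sample(times, 10, replace = TRUE))
      refs <- data.frame(time_s = times)
      base <- match_predictions(preds, refs, time_tolerance_s = 3)$counts
      perm <- match_predictions(preds[sample(nrow(preds)), , drop = FALSE],
                                refs, time_tolerance_s = 3)$counts
      expect_equal(perm, base)
    }
  })
})

test_that("metrics reproduce the printed per-camera performance tables", {
  # MZC-ARIS
  m1 <- metrics(confusion_counts(tp = 556, fp = 110, fn = 197))
  expect_equal(round(100 * m1$recall, 1), 73.8)
  expect_equal(round(100 * m1$precision, 1), 83.5)
  # MZC-BV
  m2 <- metrics(confusion_counts(tp = 139, fp = 48, fn = 59))
  expect_equal(round(100 * m2$recall, 1), 70.2)
  expect_equal(round(100 * m2$precision, 1), 74.3)
  expect_equal(round(100 * m2$f1, 1), 72.2)
  # PLN-ARIS: the published FP cell (485) disagrees with the published
  # predicted-eel total (832); only FP = 832 - 349 = 483 is consistent with
  # the published precision (41.9%) and F1 (43.1%), so that reading is used
  m3 <- metrics(confusion_counts(tp = 349, fp = 483, fn = 439))
  expect_equal(round(100 * m3$recall, 1), 44.3)
  expect_equal(round(100 * m3$precision, 1), 41.9)
  expect_equal(round(100 * m3$f1, 1), 43.1)
})

test_that("degenerate counts flag undefined metrics", {
  m <- metrics(confusion_counts(tp = 0, fp = 0, fn = 5))
  expect_equal(m$recall, 0)
  expect_true(is.na(m$precision))
  expect_false(m$f1_defined)
  expect_error(metrics(confusion_counts(0, 0, 0)), "undefined")
})

test_that("F1 lies between recall and precision (harmonic mean)", {
  with_test_seed(52, {
    for (case in 1:100) {
      cc <- confusion_counts(sample(1:500, 1), sample(0:300, 1),
                             sample(0:300, 1))
      m <- metrics(cc)
      expect_gte(m$f1, min(m$recall, m$precision) - 1e-12)
      expect_lte(m$f1, max(m$recall, m$precision) + 1e-12)
      expect_equal(m$f1, 2 / (1 / m$recall + 1 / m$precision),
                   tolerance = 1e-12)
    }
  })
})

test_that("identification precision excludes tracking errors only", {
  cc <- confusion_counts(tp = 556, fp = 110, fn = 197)
  bd <- fp_breakdown(arcing = 40, merged = 22, tracking = 7, other = 41)
  expect_equal(identification_precision(cc, bd), 556 / 659)
  expect_equal(round(100 * identification_precision(cc, bd), 1), 84.4)

  cc2 <- confusion_counts(tp = 139, fp = 48, fn = 59)
  bd2 <- fp_breakdown(merged = 4, tracking = 24, other = 20)
  expect_equal(identification_precision(cc2, bd2), 139 / 163)

  # no tracking errors: reduces to plain precision
  cc3 <- confusion_counts(tp = 50, fp = 10, fn = 5)
  bd3 <- fp_breakdown(other = 10)
  expect_equal(identification_precision(cc3, bd3),
               metrics(cc3)$precision)
  # inconsistent breakdown is rejected
  expect_error(identification_precision(cc3, fp_breakdown(other = 3)),
               "inconsistent")
})

test_that("FP category percentages tally the breakdown", {
  bd <- fp_breakdown(merged = 4, tracking = 24, other = 20)
  pct <- fp_category_percentages(bd)
  expect_equal(sum(pct), 100)
  expect_equal(pct[["tracking"]], 50)
})

test_that("stratified metrics bin TP/FN/FP and keep empty bins", {
  preds <- data.frame(time_s = c(10, 50, 90, 130))
  refs <- data.frame(time_s = c(10, 50, 90, 170, 210))
  m <- match_predictions(preds, refs, time_tolerance_s = 3)
  # stratify by range: TP at 2, 3, 5 m; FP at 9 m; FN at 5, 12 m
  sm <- stratified_metrics(m, pred_values = c(2, 3, 5, 9),
                           ref_values = c(2, 3, 5, 5, 12),
                           breaks = c(0, 4, 8, 10, 14))
  expect_equal(sm$tp, c(2, 1, 0, 0))
  expect_equal(sm$fn, c(0, 1, 0, 1))
  expect_equal(sm$fp, c(0, 0, 1, 0))
  expect_equal(sm$recall[1], 1)
  expect_true(is.na(sm$recall[3]))
  expect_equal(sm$cum_tp, c(2, 3, 3, 3) / 3)
})

test_that("recall rises across a planted detectability threshold", {
  # dropout by stratum: short fish detected rarely, long ones reliably
  with_test_seed(53, {
    lengths <- c(stats::runif(60, 30, 37), stats::runif(60, 37, 60))
    detected <- ifelse(lengths < 37, stats::runif(120) < 0.2,
                       stats::runif(120) < 0.9)
    refs <- data.frame(time_s = seq_len(120) * 30, length_cm = lengths)
    preds <- data.frame(time_s = refs$time_s[detected])
    m <- match_predictions(preds, refs, time_tolerance_s = 3)
    sm <- stratified_metrics(m, pred_values = lengths[detected],
                             ref_values = lengths,
                             breaks = c(30, 37, 60))
    expect_gt(sm$recall[2], sm$recall[1])
  })
})

test_that("count regression recovers identity and scaled relations", {
  rc <- c(3, 8, 1, 12, 6, 9, 4, 7, 2, 10, 5, 11)
  r1 <- bootstrap_count_regression(rc, rc, seed = 1)
  expect_equal(r1$slope, 1)
  expect_equal(r1$r2, 1)
  expect_gt(r1$t_pvalue_vs_1, 0.05)
  expect_equal(r1$n_replicates, 100)
  expect_equal(r1$subsample_frac, 0.70)

  r2 <- bootstrap_count_regression(0.5 * rc, rc, seed = 1)
  expect_equal(r2$slope, 0.5)
  expect_lt(r2$t_pvalue_vs_1, 0.05)

  expect_error(bootstrap_count_regression(1:2, 1:2), "at least 3")
})

test_that("replicate slopes are consistent with the full-data slope", {
  with_test_seed(54, {
    rc <- rpois(48, 8)
    ac <- round(0.8 * rc + rnorm(48, 0, 1))
    r <- bootstrap_count_regression(ac, rc, seed = 7)
    expect_lt(abs(r$mean_bootstrap_slope - r$slope),
              r$slope_ci95_halfwidth)
    # deterministic given the seed
    r2 <- bootstrap_count_regression(ac, rc, seed = 7)
    expect_identical(r$slopes, r2$slopes)
  })
})
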