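#' Confusion counts for detection evaluation (no true negatives)
#'
#' Operators list only the fish of interest when reading the videos, so true
#' negatives cannot be counted; the confusion matrix reduces to TP, FN, FP.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FN %d  FP %d\n", x$tp, x$fn, x$fp))
  invisible(x)
}

#' Match predicted passes against operator reference counts
#'
#' Greedy one-to-one matching in time order: each prediction is matched to
#' the nearest unmatched reference pass within `time_tolerance_s` (and within
#' `range_tolerance_m` when both sides carry a range). The first prediction
#' matching a reference fish is a TP; further predictions matching an
#' already-counted fish are FP of category `"tracking"` (the same eel counted
#' more than once); predictions matching nothing are FP of category
#' `"unmatched"`; reference fish never matched are FN.
#'
#' @param predictions Data frame with column `time_s` (and optionally
#'   `range_m`), or a list of [detection_record()] (mean passage times used).
#' @param reference Data frame with column `time_s` and optionally `range_m`,
#'   `length_cm`; one row per operator-validated pass.
#' @param time_tolerance_s Matching tolerance, seconds.
#' @param range_tolerance_m Matching tolerance on range, metres.
#' @return List with `counts` ([confusion_counts()]), `pairs` (data frame of
#'   TP matches: `pred`, `ref` row indices), `fp_pred` (FP prediction row
#'   indices), `fp_category` (`"tracking"`/`"unmatched"` per FP), and
#'   `fn_ref` (unmatched reference row indices).
#' @export
match_predictions <- function(predictions, reference, time_tolerance_s = 5,
                              range_tolerance_m = Inf) {
  if (is.list(predictions) && !is.data.frame(predictions) &&
      (length(predictions) == 0L ||
       inherits(predictions[[1L]], "detection_record"))) {
    predictions <- data.frame(
      time_s = vapply(predictions, `[[`, numeric(1L), "mean_passage_time_s"),
      range_m = vapply(predictions, function(r) mean(r$detection_ranges_m),
                       numeric(1L)))
  }
  np <- nrow(predictions); nr <- nrow(reference)
  have_range <- !is.null(predictions$range_m) && !is.null(reference$range_m) &&
    is.finite(range_tolerance_m)
  matched_ref <- logical(nr)
  pairs <- NULL
  fp_pred <- integer(0); fp_category <- character(0)
  for (i in order(predictions$time_s)) {
    dt <- abs(reference$time_s - predictions$time_s[i])
    ok <- dt <= time_tolerance_s
    if (have_range) {
      ok <- ok & abs(reference$range_m - predictions$range_m[i]) <=
        range_tolerance_m
    }
    cand <- which(ok & !matched_ref)
    if (length(cand)) {
      j <- cand[which.min(dt[cand])]
      matched_ref[j] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = i, ref = j))
    } else if (any(ok)) {
      fp_pred <- c(fp_pred, i)
      fp_category <- c(fp_category, "tracking")
    } else {
      fp_pred <- c(fp_pred, i)
      fp_category <- c(fp_category, "unmatched")
    }
  }
  list(counts = confusion_counts(tp = sum(matched_ref),
                                 fp = length(fp_pred),
                                 fn = sum(!matched_ref)),
       pairs = if (is.null(pairs)) data.frame(pred = integer(0),
                                              ref = integer(0)) else pairs,
       fp_pred = fp_pred,
       fp_category = fp_category,
       fn_ref = which(!matched_ref))
}

#' Recall, precision and F1 score
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F1 = 2 x recall x precision / (recall + precision)`.
#'
#' @param counts A [confusion_counts()].
#' @return List with `recall`, `precision`, `f1` and `f1_defined`. A metric
#'   whose denominator is zero is `NA`; if `recall + precision = 0`, `f1` is
#'   reported as 0 with `f1_defined = FALSE`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0L) stop("undefined metrics: all counts are zero")
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  rs <- sum(c(recall, precision), na.rm = TRUE)
  f1_defined <- !is.na(recall) && !is.na(precision) && rs > 0
  f1 <- if (f1_defined) 2 * recall * precision / (recall + precision) else 0
  list(recall = recall, precision = precision, f1 = f1,
       f1_defined = f1_defined)
}

#' Breakdown of false positives by error category
#'
#' @param arcing,merged,tracking,other Counts per category: arc-shaped
#'   high-intensity artifacts, several fish merged into one echo, the same
#'   fish counted more than once, and all other misidentifications.
#' @return An object of class `fp_breakdown`.
#' @export
fp_breakdown <- function(arcing = 0L, merged = 0L, tracking = 0L,
                         other = 0L) {
  structure(list(arcing = as.integer(arcing), merged = as.integer(merged),
                 tracking = as.integer(tracking), other = as.integer(other)),
            class = "fp_breakdown")
}

#' Percentage of false positives in each error category
#' @param breakdown An [fp_breakdown()].
#' @return Named numeric vector of percentages (summing to 100 when FP > 0).
#' @export
fp_category_percentages <- function(breakdown) {
  counts <- unlist(breakdown)
  total <- sum(counts)
  if (total == 0L) return(counts * NA_real_)
  100 * counts / total
}

#' Identification precision
#'
#' Precision recomputed after excluding duplicate-count ("tracking") false
#' positives, isolating the species-discrimination error from the counting
#' error: `TP / (TP + FP - FP_tracking)`.
#'
#' @param counts A [confusion_counts()].
#' @param breakdown An [fp_breakdown()] consistent with `counts` (category
#'   counts sum to FP).
#' @return The identification precision as a proportion in `[0, 1]`.
#' @export
identification_precision <- function(counts, breakdown) {
  total <- sum(unlist(breakdown))
  if (total != counts$fp) {
    stop("breakdown inconsistent with counts: categories sum to ", total,
         " but FP is ", counts$fp)
  }
  denom <- counts$tp + counts$fp - breakdown$tracking
  if (denom == 0) stop("undefined metrics: zero denominator")
  counts$tp / denom
}

#' Recall, precision and F1 stratified by range or length bins
#'
#' Bins TP by the matched reference value, FN by the unmatched reference
#' value and FP by the prediction value, then computes per-bin metrics and
#' cumulative TP/FN/FP distributions over the bin order. Empty bins are kept
#' with `NA` metrics.
#'
#' @param match Result of [match_predictions()].
#' @param pred_values Stratification value (range in m, or length in cm) per
#'   prediction row.
#' @param ref_values Stratification value per reference row.
#' @param breaks Bin breaks passed to [cut()].
#' @return Data frame with one row per bin: counts, `recall`, `precision`,
#'   `f1` and cumulative `cum_tp`, `cum_fn`, `cum_fp` fractions.
#' @export
stratified_metrics <- function(match, pred_values, ref_values, breaks) {
  bins <- levels(cut(numeric(0), breaks))
  bin_of <- function(v) cut(v, breaks)
  tp_bin <- table(bin_of(ref_values[match$pairs$ref]))
  fn_bin <- table(bin_of(ref_values[match$fn_ref]))
  fp_bin <- table(bin_of(pred_values[match$fp_pred]))
  out <- data.frame(bin = bins,
                    tp = as.integer(tp_bin), fn = as.integer(fn_bin),
                    fp = as.integer(fp_bin))
  per <- lapply(seq_len(nrow(out)), function(i) {
    if (out$tp[i] + out$fn[i] + out$fp[i] == 0L) {
      return(list(recall = NA_real_, precision = NA_real_, f1 = NA_real_))
    }
    m <- metrics(confusion_counts(out$tp[i], out$fp[i], out$fn[i]))
    list(recall = m$recall, precision = m$precision,
         f1 = if (m$f1_defined) m$f1 else NA_real_)
  })
  out$recall <- vapply(per, `[[`, numeric(1L), "recall")
  out$precision <- vapply(per, `[[`, numeric(1L), "precision")
  out$f1 <- vapply(per, `[[`, numeric(1L), "f1")
  cum_frac <- function(x) if (sum(x) > 0) cumsum(x) / sum(x) else
    rep(NA_real_, length(x))
  out$cum_tp <- cum_frac(out$tp)
  out$cum_fn <- cum_frac(out$fn)
  out$cum_fp <- cum_frac(out$fp)
  out
}

#' Bootstrap regression between automatic and reference hourly counts
#'
#' Ordinary least squares of the automatic count (AC) on the reference count
#' (RC) at an hourly resolution, plus `n_replicates` subsample replicates
#' (70% of the hours, without replacement by default) whose slopes are tested
#' against 1 (the 1:1 line) with a one-sample Student's t-test.
#'
#' @param hourly_ac,hourly_rc Paired hourly counts (length >= 3).
#' @param seed RNG seed for the subsampling.
#' @param n_replicates Number of bootstrap replicates.
#' @param subsample_frac Fraction of hours per replicate, in (0, 1).
#' @param replace Sample with replacement instead.
#' @return An object of class `regression_summary`: `slope`,
#'   `slope_ci95_halfwidth`, `r2`, `mean_bootstrap_slope`, `t_pvalue_vs_1`,
#'   `n_replicates`, `subsample_frac`, `slopes` (the replicate slopes).
#' @export
bootstrap_count_regression <- function(hourly_ac, hourly_rc, seed = 1L,
                                       n_replicates = 100L,
                                       subsample_frac = 0.70,
                                       replace = FALSE) {
  n <- length(hourly_rc)
  stopifnot(length(hourly_ac) == n, subsample_frac > 0, subsample_frac < 1)
  if (n < 3L) stop("insufficient data: need at least 3 paired hours")
  fit <- stats::lm(hourly_ac ~ hourly_rc)
  # identity-like inputs are legitimate here; silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  ci_half <- stats::qt(0.975, df = fit$df.residual) * se
  m <- max(3L, round(subsample_frac * n))
  slopes <- with_seed(seed, vapply(seq_len(n_replicates), function(i) {
    idx <- sample.int(n, m, replace = replace)
    suppressWarnings(
      unname(stats::coef(stats::lm(hourly_ac[idx] ~ hourly_rc[idx]))[2L]))
  }, numeric(1L)))
  pval <- if (stats::sd(slopes) < 1e-12) {
    if (abs(mean(slopes) - 1) < 1e-10) 1 else 0
  } else {
    stats::t.test(slopes, mu = 1)$p.value
  }
  structure(list(slope = slope,
                 slope_ci95_halfwidth = ci_half,
                 r2 = sm$r.squared,
                 mean_bootstrap_slope = mean(slopes),
                 t_pvalue_vs_1 = pval,
                 n_replicates = n_replicates,
                 subsample_frac = subsample_frac,
                 slopes = slopes),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf(
    "<regression> slope %.3f (+/- %.3f), R2 %.3f; bootstrap mean slope %.3f, p(slope=1) %.3g\n",
    x$slope, x$slope_ci95_halfwidth, x$r2, x$mean_bootstrap_slope,
    x$t_pvalue_vs_1))
  invisible(x)
}
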