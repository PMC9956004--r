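#' Pipeline parameters
#'
#' Bundles every adjustable threshold of the pipeline so a run is fully
#' reproducible from its parameters, inputs and seed.
#'
#' @param threshold_sv2,threshold_sv3 Echogram screening thresholds.
#' @param min_gap_frames Screening gap bridged when merging intervals;
#'   defaults to half a second of frames.
#' @param reference Reference (empty) frame for the echogram, or `"auto"`
#'   (see [compute_sv_echogram()]).
#' @param ratio_mode Echogram ratio mode, see [compute_sv_echogram()].
#' @param dilation_px Detection dilation kernel side, pixels.
#' @param min_axis_frac Candidate major-axis filter fraction.
#' @param max_skip_frames Tracking gap; defaults to half a second of frames.
#' @param max_theta_diff_deg Tracking orientation gate, degrees.
#' @param rules A [decision_rules()], or `NULL` to build one from the
#'   recording's length class at run time.
#' @param seed Seed for the stochastic stages (k-means restarts).
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(threshold_sv2 = 1.2, threshold_sv3 = 1.2,
                            min_gap_frames = NULL, reference = "auto",
                            ratio_mode = c("reference", "sigma1"),
                            dilation_px = 15L, min_axis_frac = 0.25,
                            max_skip_frames = NULL, max_theta_diff_deg = 25,
                            rules = NULL, seed = 1L) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(threshold_sv2 > 0, threshold_sv3 > 0, dilation_px >= 1,
            min_axis_frac > 0, max_theta_diff_deg > 0)
  structure(list(threshold_sv2 = threshold_sv2,
                 threshold_sv3 = threshold_sv3,
                 min_gap_frames = min_gap_frames,
                 reference = reference,
                 ratio_mode = ratio_mode,
                 dilation_px = as.integer(dilation_px),
                 min_axis_frac = min_axis_frac,
                 max_skip_frames = max_skip_frames,
                 max_theta_diff_deg = max_theta_diff_deg,
                 rules = rules,
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

#' Run the full detection pipeline on one frame sequence
#'
#' Screening (singular-value echogram and intervals of interest), candidate
#' detection (background subtraction), morphology, tracking and rule-based
#' classification, ending in one [detection_record()] per predicted
#' anguilliform fish.
#'
#' @param seq A [frame_sequence()].
#' @param params A [pipeline_params()].
#' @param video Video name written into the records.
#' @param out_csv Optional path: write the detections CSV there.
#' @return An object of class `eel_run`: list with `echogram`, `intervals`,
#'   `candidates`, `descriptors`, `tracks`, `predictions`, `records`,
#'   `stage_counts`, `params`.
#' @export
run_pipeline <- function(seq, params = pipeline_params(), video = "video",
                         out_csv = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  config <- seq$config
  min_gap <- if (is.null(params$min_gap_frames)) {
    round_half_up(config$fps / 2)
  } else params$min_gap_frames
  rules <- if (is.null(params$rules)) {
    decision_rules(length_class = config$length_class)
  } else params$rules

  echo <- compute_sv_echogram(seq, reference = params$reference,
                              ratio_mode = params$ratio_mode)
  intervals <- extract_intervals(echo, params$threshold_sv2,
                                 params$threshold_sv3, min_gap)
  candidates <- detect_candidates(seq, intervals, config,
                                  dilation_px = params$dilation_px,
                                  min_axis_frac = params$min_axis_frac)
  descriptors <- lapply(candidates, describe, config = config,
                        seed = params$seed)
  tracks <- track_candidates(candidates, descriptors, config,
                             max_skip_frames = params$max_skip_frames,
                             max_theta_diff_deg = params$max_theta_diff_deg)
  predictions <- lapply(tracks, classify_track, rules = rules,
                        config = config, video = video)
  records <- Filter(Negate(is.null), lapply(predictions, `[[`, "record"))
  if (!is.null(out_csv)) write_detections_csv(records, out_csv)
  structure(list(echogram = echo,
                 intervals = intervals,
                 candidates = candidates,
                 descriptors = descriptors,
                 tracks = tracks,
                 predictions = predictions,
                 records = records,
                 stage_counts = c(
                   frames = length(seq$frames),
                   frames_of_interest = if (nrow(intervals)) {
                     sum(intervals$end_frame - intervals$start_frame + 1L)
                   } else 0L,
                   candidates = length(candidates),
                   tracks = length(tracks),
                   predictions = length(records)),
                 params = params),
            class = "eel_run")
}

#' @export
print.eel_run <- function(x, ...) {
  s <- x$stage_counts
  cat(sprintf(
    "<eel_run> %d frames -> %d of interest -> %d candidates -> %d tracks -> %d eels\n",
    s["frames"], s["frames_of_interest"], s["candidates"], s["tracks"],
    s["predictions"]))
  invisible(x)
}

#' Evaluate detections against an operator reference count
#'
#' Matches predicted passes to reference passes, computes the confusion
#' counts and metrics, and (when FP categories are annotated) the category
#' percentages and identification precision.
#'
#' @param records List of [detection_record()] or a detections CSV path.
#' @param reference Reference-count data frame (columns `time_s`, optionally
#'   `range_m`, `length_cm`) or a CSV path with those columns.
#' @param time_tolerance_s Match tolerance, seconds.
#' @param annotations Optional data frame with columns `time_s`, `category`
#'   assigning operator FP categories (`"arcing"`, `"merged"`, `"other"`) to
#'   unmatched predictions by nearest time.
#' @return An object of class `eval_report`: list with `match`, `counts`,
#'   `metrics`, `breakdown`, `identification_precision`.
#' @export
evaluate_detections <- function(records, reference, time_tolerance_s = 5,
                                annotations = NULL) {
  if (is.character(records)) records <- read_detections_csv(records)
  if (is.character(reference)) {
    reference <- utils::read.csv(reference, stringsAsFactors = FALSE)
  }
  if (is.null(reference$time_s) || nrow(reference) == 0L) {
    stop("schema error: reference must have a nonempty time_s column")
  }
  mt <- match_predictions(records, reference,
                          time_tolerance_s = time_tolerance_s)
  cat_counts <- c(arcing = 0L, merged = 0L, tracking = 0L, other = 0L)
  cat_counts["tracking"] <- sum(mt$fp_category == "tracking")
  n_other <- sum(mt$fp_category == "unmatched")
  if (!is.null(annotations) && n_other > 0L) {
    if (is.list(records) && length(records)) {
      times <- vapply(records, `[[`, numeric(1L), "mean_passage_time_s")
    } else times <- numeric(0)
    for (i in mt$fp_pred[mt$fp_category == "unmatched"]) {
      j <- which.min(abs(annotations$time_s - times[i]))
      catg <- annotations$category[j]
      if (!catg %in% c("arcing", "merged", "other")) catg <- "other"
      cat_counts[catg] <- cat_counts[catg] + 1L
    }
  } else {
    cat_counts["other"] <- n_other
  }
  bd <- do.call(fp_breakdown, as.list(cat_counts))
  idp <- if (mt$counts$tp + mt$counts$fp - bd$tracking > 0) {
    identification_precision(mt$counts, bd)
  } else NA_real_
  structure(list(match = mt, counts = mt$counts,
                 metrics = metrics(mt$counts),
                 breakdown = bd,
                 identification_precision = idp),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval> TP %d FN %d FP %d | recall %.1f%% precision %.1f%% F1 %.1f%%\n",
              x$counts$tp, x$counts$fn, x$counts$fp,
              100 * m$recall, 100 * m$precision, 100 * m$f1))
  if (!is.na(x$identification_precision)) {
    cat(sprintf("  identification precision %.1f%%\n",
                100 * x$identification_precision))
  }
  invisible(x)
}

#' Tune the screening thresholds on a development scene
#'
#' Grid-sweeps the 2nd/3rd singular-value-ratio thresholds, runs the full
#' pipeline at each grid point on the development sequence, scores the
#' predictions against the reference count and reports the F1 surface and
#' the best parameter pair (ties: higher thresholds preferred, for the
#' cheaper screening).
#'
#' @param seq Development [frame_sequence()].
#' @param reference Reference-count data frame for the development scene.
#' @param params Base [pipeline_params()].
#' @param grid_sv2,grid_sv3 Threshold grids.
#' @param time_tolerance_s Match tolerance for scoring.
#' @return List with `surface` (data frame `threshold_sv2`, `threshold_sv3`,
#'   `f1`) and `best` (a [pipeline_params()] at the best grid point).
#' @export
tune_screening <- function(seq, reference, params = pipeline_params(),
                           grid_sv2 = c(1.1, 1.2, 1.5),
                           grid_sv3 = c(1.1, 1.2, 1.5),
                           time_tolerance_s = 5) {
  grid <- expand.grid(threshold_sv2 = grid_sv2, threshold_sv3 = grid_sv3)
  grid$f1 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$threshold_sv2 <- grid$threshold_sv2[i]
    p$threshold_sv3 <- grid$threshold_sv3[i]
    run <- run_pipeline(seq, p)
    rep <- evaluate_detections(run$records, reference,
                               time_tolerance_s = time_tolerance_s)
    grid$f1[i] <- if (rep$metrics$f1_defined) rep$metrics$f1 else 0
  }
  ord <- order(-grid$f1, -grid$threshold_sv2, -grid$threshold_sv3)
  best <- params
  best$threshold_sv2 <- grid$threshold_sv2[ord[1L]]
  best$threshold_sv3 <- grid$threshold_sv3[ord[1L]]
  list(surface = grid, best = best)
}
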