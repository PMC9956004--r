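#' Decision rule set for eel classification
#'
#' Thresholds applied at frame scale (body length, area, eccentricity) and at
#' track scale (mean travel distance, direction consistency, minimum and mean
#' eccentricity), with the track-scale eccentricity thresholds depending on
#' the eel length class of the local population: minimum per-frame
#' eccentricity >= 0.85 (30--60 cm) or 0.90 (60--90 cm), mean eccentricity
#' >= 0.90 (30--60 cm) or 0.92 (60--90 cm).
#'
#' The frame-scale area rule needs a reference area. Three references are
#' supported: `"thumbnail"` compares to the thumbnail area (the literal
#' reading, which a thin eel body can never satisfy inside a
#' `(L_min + 30 cm)^2` window); `"candidate_bbox"` compares to the
#' candidate's own bounding box (an undulating body fills only ~20% of its
#' box, so this too rejects eels); `"nominal_body"` (default) compares to the
#' nominal body area `L_ref x nominal_body_width_mm`, making the rule a
#' minimum-size filter consistent with the other rules.
#'
#' @param length_class `"60-90"` or `"30-60"` (cm).
#' @param min_frames_pass Minimum number of frames in which all frame rules
#'   must hold for a track to be classified anguilliform.
#' @param area_reference Area-rule reference, see Details.
#' @param nominal_body_width_mm Body width used by the `"nominal_body"`
#'   reference.
#' @param use_section_ecc If `TRUE` the frame eccentricity rule is applied to
#'   all three k-means section eccentricities instead of the overall one.
#' @param length_min_frac,area_min_frac,ecc_min_frame Frame-scale thresholds.
#' @param ecc_min_track,mean_ecc_min_track Track-scale eccentricity
#'   thresholds; default to the length-class column.
#' @param step_min_mm Track-scale minimum mean travel distance per frame, mm;
#'   defaults to `L_ref_mm / fps` (one reference length per second) at
#'   classification time.
#' @return An object of class `decision_rules`.
#' @export
decision_rules <- function(length_class = c("60-90", "30-60"),
                           min_frames_pass = 5L,
                           area_reference = c("nominal_body",
                                              "candidate_bbox", "thumbnail"),
                           nominal_body_width_mm = 30,
                           use_section_ecc = FALSE,
                           length_min_frac = 0.40,
                           area_min_frac = 0.75,
                           ecc_min_frame = 0.90,
                           ecc_min_track = NULL,
                           mean_ecc_min_track = NULL,
                           step_min_mm = NULL) {
  length_class <- match.arg(length_class)
  area_reference <- match.arg(area_reference)
  if (is.null(ecc_min_track)) {
    ecc_min_track <- if (length_class == "30-60") 0.85 else 0.90
  }
  if (is.null(mean_ecc_min_track)) {
    mean_ecc_min_track <- if (length_class == "30-60") 0.90 else 0.92
  }
  stopifnot(length_min_frac > 0, length_min_frac <= 1,
            area_min_frac > 0, area_min_frac <= 1,
            ecc_min_frame >= 0, ecc_min_frame < 1,
            ecc_min_track >= 0, ecc_min_track < 1,
            mean_ecc_min_track >= 0, mean_ecc_min_track < 1,
            min_frames_pass >= 1)
  structure(list(length_class = length_class,
                 min_frames_pass = as.integer(min_frames_pass),
                 area_reference = area_reference,
                 nominal_body_width_mm = nominal_body_width_mm,
                 use_section_ecc = use_section_ecc,
                 length_min_frac = length_min_frac,
                 area_min_frac = area_min_frac,
                 ecc_min_frame = ecc_min_frame,
                 ecc_min_track = ecc_min_track,
                 mean_ecc_min_track = mean_ecc_min_track,
                 step_min_mm = step_min_mm),
            class = "decision_rules")
}

#' Frame-scale decision rules for one candidate
#'
#' @param descriptor A `shape_descriptor`.
#' @param candidate The matching `eel_candidate`.
#' @param rules A [decision_rules()].
#' @param config A [recording_config()].
#' @return Named logical vector `length_ok`, `area_ok`, `ecc_ok`.
#' @export
frame_rules <- function(descriptor, candidate, rules, config) {
  l_ref <- eel_ref_length_mm(config)
  area_ref <- switch(rules$area_reference,
    thumbnail = candidate$thumbnail_area_mm2,
    candidate_bbox = prod(dim(candidate$mask)) *
      config$pixel_res_mm * config$cross_res_mm,
    nominal_body = l_ref * rules$nominal_body_width_mm)
  ecc_ok <- if (isTRUE(rules$use_section_ecc)) {
    all(descriptor$section_eccentricities >= rules$ecc_min_frame)
  } else {
    descriptor$eccentricity >= rules$ecc_min_frame
  }
  c(length_ok = descriptor$body_length_mm >= rules$length_min_frac * l_ref,
    area_ok = descriptor$area_mm2 >= rules$area_min_frac * area_ref,
    ecc_ok = ecc_ok)
}

#' Classify a track as anguilliform or not
#'
#' Counts the frames in which all frame-scale rules hold, then applies the
#' track-scale rules over the whole track: mean travel distance per frame
#' >= `step_min_mm` (default one reference length per second), direction
#' always positive along the flow axis, minimum per-detection eccentricity
#' >= `ecc_min_track` and mean eccentricity >= `mean_ecc_min_track`. The
#' track is anguilliform iff the count reaches `min_frames_pass` and every
#' track rule holds. Track-scale eccentricities are taken over all
#' detections (not only the frames passing the frame rules), which keeps the
#' classification monotone in every threshold: tightening a threshold can
#' only reduce the number of positives.
#'
#' @param track A track from [track_candidates()].
#' @param rules A [decision_rules()].
#' @param config A [recording_config()].
#' @param video Video name written into the detection record.
#' @return An object of class `eel_prediction`: list with `track_id`,
#'   `label`, `n_passing_frames`, `frame_outcomes`, `track_outcomes` and, for
#'   positives, `record` (a [detection_record()]).
#' @export
classify_track <- function(track, rules, config, video = "video") {
  n <- length(track$frames)
  fo <- t(vapply(seq_len(n), function(i) {
    frame_rules(track$descriptors[[i]], track$candidates[[i]], rules, config)
  }, logical(3L)))
  pass <- rowSums(fo) == ncol(fo)
  n_pass <- sum(pass)
  eccs <- vapply(track$descriptors, `[[`, numeric(1L), "eccentricity")

  step_min <- if (is.null(rules$step_min_mm)) {
    eel_ref_length_mm(config) / config$fps
  } else rules$step_min_mm
  track_out <- c(step_ok = FALSE, direction_ok = FALSE,
                 ecc_ok = FALSE, mean_ecc_ok = FALSE)
  if (n >= 2L) {
    kin <- track_kinematics(track, config)
    track_out["step_ok"] <- kin$mean_step_mm >= step_min
    track_out["direction_ok"] <- kin$direction_consistent
  }
  track_out["ecc_ok"] <- min(eccs) >= rules$ecc_min_track
  track_out["mean_ecc_ok"] <- mean(eccs) >= rules$mean_ecc_min_track
  anguilliform <- n_pass >= rules$min_frames_pass && all(track_out)

  record <- NULL
  if (anguilliform) {
    times <- (track$frames - 1) / config$fps
    record <- detection_record(
      video = video,
      mean_passage_time_s = mean(times),
      detection_frames = track$frames,
      detection_ranges_m = vapply(track$candidates, `[[`, numeric(1L),
                                  "range_m"),
      lengths_mm = vapply(track$descriptors, `[[`, numeric(1L),
                          "body_length_mm"))
  }
  structure(list(track_id = track$id,
                 label = if (anguilliform) "anguilliform"
                         else "non-anguilliform",
                 n_passing_frames = n_pass,
                 frame_outcomes = fo,
                 track_outcomes = track_out,
                 record = record),
            class = "eel_prediction")
}

#' @export
print.eel_prediction <- function(x, ...) {
  cat(sprintf("<prediction> track %d: %s (%d passing frames)\n",
              x$track_id, x$label, x$n_passing_frames))
  invisible(x)
}
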