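new_track <- function(id, frame, candidate, descriptor) {
  list(id = id,
       frames = frame,
       centroids = matrix(candidate$centroid_px, 1L, 2L,
                          dimnames = list(NULL, c("x", "y"))),
       orientations = descriptor$orientation_deg,
       candidates = list(candidate),
       descriptors = list(descriptor),
       last_seen = frame)
}

append_to_track <- function(track, frame, candidate, descriptor) {
  track$frames <- c(track$frames, frame)
  track$centroids <- rbind(track$centroids, candidate$centroid_px)
  track$orientations <- c(track$orientations, descriptor$orientation_deg)
  track$candidates <- c(track$candidates, list(candidate))
  track$descriptors <- c(track$descriptors, list(descriptor))
  track$last_seen <- frame
  track
}

#' Associate one frame's candidates with the open tracks
#'
#' A candidate may join an open track only if (a) its centroid lies inside the
#' circle of diameter `1.5 x min_eel_length` centered on the track's last
#' centroid, with the radius scaled by the number of frames elapsed since the
#' track was last seen, (b) the orientation difference (modulo 180 degrees)
#' is below `max_theta_diff_deg`, and (c) the track was seen within
#' `max_skip_frames`. Admissible pairs are matched one-to-one greedily by
#' smallest distance, ties broken by smaller orientation difference, then
#' lower track id. Unmatched candidates open new tracks; tracks unseen for
#' more than `max_skip_frames` are closed.
#'
#' @param state Tracker state from [tracker_state()].
#' @param candidates List of `eel_candidate` for frame `frame_t`.
#' @param descriptors Matching list of `shape_descriptor`.
#' @param frame_t Current frame index.
#' @param config A [recording_config()].
#' @param max_skip_frames Longest detection gap bridged within a track;
#'   defaults to half a second of frames (`round(fps / 2)`). Because the
#'   search radius is scaled by the number of elapsed frames, a longer gap
#'   would let the scaled circle span a large share of the field of view and
#'   capture the next fish entering it.
#' @param max_theta_diff_deg Orientation-consistency gate, degrees.
#' @return The updated tracker state.
#' @export
associate <- function(state, candidates, descriptors, frame_t, config,
                      max_skip_frames = NULL, max_theta_diff_deg = 25) {
  if (is.null(max_skip_frames)) {
    max_skip_frames <- max(1, round_half_up(config$fps / 2))
  }
  radius_mm <- 0.75 * eel_ref_length_mm(config)
  sx <- config$cross_res_mm; sy <- config$pixel_res_mm

  # close stale tracks
  if (length(state$open)) {
    stale <- vapply(state$open, function(tr) {
      frame_t - tr$last_seen > max_skip_frames
    }, logical(1L))
    state$closed <- c(state$closed, state$open[stale])
    state$open <- state$open[!stale]
  }

  pairs <- NULL
  for (ci in seq_along(candidates)) {
    for (ti in seq_along(state$open)) {
      tr <- state$open[[ti]]
      elapsed <- frame_t - tr$last_seen
      last <- tr$centroids[nrow(tr$centroids), ]
      cc <- candidates[[ci]]$centroid_px
      d_mm <- sqrt(((cc[[1L]] - last[[1L]]) * sx)^2 +
                   ((cc[[2L]] - last[[2L]]) * sy)^2)
      th <- orientation_diff_deg(
        descriptors[[ci]]$orientation_deg,
        tr$orientations[length(tr$orientations)])
      if (d_mm <= radius_mm * elapsed && th < max_theta_diff_deg) {
        pairs <- rbind(pairs, c(ci = ci, ti = ti, d = d_mm, th = th,
                                id = tr$id))
      }
    }
  }
  used_c <- logical(length(candidates))
  used_t <- logical(length(state$open))
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, "d"], pairs[, "th"], pairs[, "id"]), ,
                   drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      ci <- pairs[p, "ci"]; ti <- pairs[p, "ti"]
      if (used_c[ci] || used_t[ti]) next
      state$open[[ti]] <- append_to_track(state$open[[ti]], frame_t,
                                          candidates[[ci]],
                                          descriptors[[ci]])
      used_c[ci] <- TRUE; used_t[ti] <- TRUE
    }
  }
  for (ci in which(!used_c)) {
    state$next_id <- state$next_id + 1L
    state$open[[length(state$open) + 1L]] <-
      new_track(state$next_id, frame_t, candidates[[ci]], descriptors[[ci]])
  }
  state
}

#' Create an empty tracker state
#' @return List with `open` and `closed` track lists and an id counter.
#' @export
tracker_state <- function() list(open = list(), closed = list(), next_id = 0L)

#' Track candidates across a whole sequence
#'
#' Runs [associate()] frame by frame over the candidates and closes all
#' remaining tracks at the end.
#'
#' @param candidates List of `eel_candidate`.
#' @param descriptors Matching list of `shape_descriptor`.
#' @param config A [recording_config()].
#' @inheritParams associate
#' @return List of closed tracks.
#' @export
track_candidates <- function(candidates, descriptors, config,
                             max_skip_frames = NULL,
                             max_theta_diff_deg = 25) {
  state <- tracker_state()
  if (length(candidates) == 0L) return(list())
  frames <- vapply(candidates, `[[`, integer(1L), "frame_index")
  for (t in sort(unique(frames))) {
    sel <- which(frames == t)
    state <- associate(state, candidates[sel], descriptors[sel], t, config,
                       max_skip_frames, max_theta_diff_deg)
  }
  c(state$closed, state$open)
}

#' Kinematic summary of a track
#'
#' @param track A track from [track_candidates()].
#' @param config A [recording_config()].
#' @return List with `mean_step_mm` (mean centroid displacement per elapsed
#'   frame), `velocity_mm_s`, `direction_consistent` (`TRUE` iff every step's
#'   X displacement has the sign of `config$flow_axis_sign`), and the
#'   per-step `step_mm`, `step_frames`, `direction_signs`.
#' @export
track_kinematics <- function(track, config) {
  n <- length(track$frames)
  if (n < 2L) stop("undefined kinematics: track has fewer than 2 detections")
  sx <- config$cross_res_mm; sy <- config$pixel_res_mm
  dx <- diff(track$centroids[, 1L]); dy <- diff(track$centroids[, 2L])
  step_mm <- sqrt((dx * sx)^2 + (dy * sy)^2)
  step_frames <- diff(track$frames)
  mean_step <- sum(step_mm) / sum(step_frames)
  list(mean_step_mm = mean_step,
       velocity_mm_s = mean_step * config$fps,
       direction_consistent = all(sign(dx) == config$flow_axis_sign),
       step_mm = step_mm,
       step_frames = step_frames,
       direction_signs = sign(dx))
}
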