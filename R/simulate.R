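#' Synthetic sonar event specifications
#'
#' Constructors for the objects a synthetic scene can contain: undulating
#' anguilliform fish (`eel_event`), compact non-anguilliform fish
#' (`fish_event`), small slow debris (`debris_event`) and stationary
#' arc-shaped high-intensity artifacts (`arc_event`, the "arcing effect" of
#' strong near-camera reflectors).
#'
#' Eels are rendered as a constant-width band around a sinusoidally
#' undulating centerline of exactly `body_length_mm` arc length, advancing at
#' constant speed along the cross-range (x) axis while the undulation phase
#' travels along the body. `fragmentation_rate` drops random runs of body
#' pixels each frame, emulating fragmented echoes.
#'
#' @param body_length_mm Body length (arc length of the centerline), mm.
#' @param entry_frame First frame at which the head enters the field of view.
#' @param y_px Row (range axis) of the body axis.
#' @param speed_mm_s Horizontal speed; defaults to 1.2 body lengths per
#'   second (a typical migrating-eel cruising speed).
#' @param direction +1 (left to right) or -1.
#' @param width_mm Body width.
#' @param undulation_amp_mm Lateral undulation amplitude; default 8% of body
#'   length.
#' @param undulation_wavelength_mm Undulation wavelength; default 60% of body
#'   length.
#' @param undulation_freq_hz Tail-beat frequency.
#' @param fragmentation_rate Fraction of body pixels dropped per frame, in
#'   `[0, 1)`.
#' @param intensity Echo intensity added above the background, grey levels.
#' @return A `sim_event` specification list.
#' @export
eel_event <- function(body_length_mm, entry_frame = 1L, y_px = NULL,
                      speed_mm_s = NULL, direction = 1L, width_mm = 30,
                      undulation_amp_mm = NULL,
                      undulation_wavelength_mm = NULL,
                      undulation_freq_hz = 1.5,
                      fragmentation_rate = 0, intensity = 80) {
  stopifnot(body_length_mm > 0, fragmentation_rate >= 0,
            fragmentation_rate < 1, direction %in% c(-1L, 1L))
  if (is.null(speed_mm_s)) speed_mm_s <- 1.2 * body_length_mm
  if (is.null(undulation_amp_mm)) undulation_amp_mm <- 0.08 * body_length_mm
  if (is.null(undulation_wavelength_mm)) {
    undulation_wavelength_mm <- 0.6 * body_length_mm
  }
  structure(list(kind = "eel", body_length_mm = body_length_mm,
                 entry_frame = as.integer(entry_frame), y_px = y_px,
                 speed_mm_s = speed_mm_s, direction = as.integer(direction),
                 width_mm = width_mm,
                 undulation_amp_mm = undulation_amp_mm,
                 undulation_wavelength_mm = undulation_wavelength_mm,
                 undulation_freq_hz = undulation_freq_hz,
                 fragmentation_rate = fragmentation_rate,
                 intensity = intensity),
            class = "sim_event")
}

#' @rdname eel_event
#' @param aspect Minor/major axis ratio of the ellipse body (eccentricity
#'   `sqrt(1 - aspect^2)`; the default 0.6 gives eccentricity 0.8).
#' @export
fish_event <- function(body_length_mm = 250, entry_frame = 1L, y_px = NULL,
                       speed_mm_s = NULL, direction = 1L, aspect = 0.6,
                       intensity = 80) {
  stopifnot(body_length_mm > 0, aspect > 0, aspect <= 1)
  if (is.null(speed_mm_s)) speed_mm_s <- 1.5 * body_length_mm
  structure(list(kind = "fish", body_length_mm = body_length_mm,
                 entry_frame = as.integer(entry_frame), y_px = y_px,
                 speed_mm_s = speed_mm_s, direction = as.integer(direction),
                 aspect = aspect, intensity = intensity),
            class = "sim_event")
}

#' @rdname eel_event
#' @export
debris_event <- function(body_length_mm = 100, entry_frame = 1L, y_px = NULL,
                         speed_mm_s = 150, direction = 1L, intensity = 50) {
  ev <- fish_event(body_length_mm, entry_frame, y_px, speed_mm_s, direction,
                   aspect = 0.8, intensity = intensity)
  ev$kind <- "debris"
  ev
}

#' @rdname eel_event
#' @param radius_px Arc radius in pixels from the (out-of-frame) camera
#'   origin.
#' @param x_center_px Column of the arc center.
#' @param half_width_px Half horizontal extent of the arc streak.
#' @param thickness_px Arc thickness.
#' @param n_frames_visible Number of frames the artifact persists.
#' @export
arc_event <- function(radius_px = 60, entry_frame = 1L, x_center_px = NULL,
                      half_width_px = 40, thickness_px = 2,
                      n_frames_visible = 10L, intensity = 120) {
  structure(list(kind = "arc", radius_px = radius_px,
                 entry_frame = as.integer(entry_frame),
                 x_center_px = x_center_px, half_width_px = half_width_px,
                 thickness_px = thickness_px,
                 n_frames_visible = as.integer(n_frames_visible),
                 intensity = intensity),
            class = "sim_event")
}

# Centerline of an eel at time t, as n x 2 (x, y) pixel coordinates of
# points spaced ds_mm apart in arc length, head first. Truth length of the
# returned polyline is body_length_mm (up to one ds_mm step).
eel_centerline <- function(ev, t_s, head_x_px, y_px, sx, sy, ds_mm = NULL) {
  if (is.null(ds_mm)) ds_mm <- min(sx, sy) / 2
  amp <- ev$undulation_amp_mm
  lam <- ev$undulation_wavelength_mm
  phase <- 2 * pi * ev$undulation_freq_hz * t_s
  # x-parametrized sinusoid; arc-length resampled to body_length_mm
  u <- seq(0, 1.2 * ev$body_length_mm, by = ds_mm / 2)
  yoff <- amp * sin(2 * pi * u / lam - phase)
  seg <- sqrt(diff(u)^2 + diff(yoff)^2)
  s <- c(0, cumsum(seg))
  keep <- s <= ev$body_length_mm
  u <- u[keep]; yoff <- yoff[keep]; s <- s[keep]
  target_s <- seq(0, max(s), by = ds_mm)
  ux <- stats::approx(s, u, xout = target_s)$y
  uy <- stats::approx(s, yoff, xout = target_s)$y
  cbind(x = head_x_px - ev$direction * ux / sx,
        y = y_px + uy / sy)
}

# Rasterize a polyline into pixel coordinates by stamping discs of
# radius_px at each sample; returns unique (row, col) matrix.
stamp_polyline <- function(pts, radius_px, nrow_f, ncol_f) {
  r <- max(0L, floor(radius_px))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2 + 0.25, ]
  rows <- rep(round_half_up(pts[, 2L]), each = nrow(offs)) + offs$dr
  cols <- rep(round_half_up(pts[, 1L]), each = nrow(offs)) + offs$dc
  ok <- rows >= 1L & rows <= nrow_f & cols >= 1L & cols <= ncol_f
  unique(cbind(row = rows[ok], col = cols[ok]))
}

render_event_frame <- function(ev, t_frame, config, nrow_f, ncol_f) {
  sx <- config$cross_res_mm; sy <- config$pixel_res_mm
  t_s <- (t_frame - 1) / config$fps
  t0 <- (ev$entry_frame - 1) / config$fps
  if (ev$kind == "arc") {
    vis <- t_frame >= ev$entry_frame &&
      t_frame < ev$entry_frame + ev$n_frames_visible
    if (!vis) return(NULL)
    xc <- if (is.null(ev$x_center_px)) ncol_f / 2 else ev$x_center_px
    xs <- seq(-ev$half_width_px, ev$half_width_px, by = 0.5)
    ys <- sqrt(pmax(ev$radius_px^2 - xs^2, 0))
    pts <- cbind(x = xc + xs, y = ys)   # camera origin above row 1
    keep <- pts[, "y"] >= 1 & pts[, "y"] <= nrow_f
    if (!any(keep)) return(NULL)
    px <- stamp_polyline(pts[keep, , drop = FALSE],
                         ev$thickness_px / 2, nrow_f, ncol_f)
    return(list(pixels = px, centerline = NULL))
  }
  if (t_frame < ev$entry_frame) return(NULL)
  dt <- t_s - t0
  if (ev$kind == "eel") {
    entry_x <- if (ev$direction > 0) 1 else ncol_f
    head_x <- entry_x + ev$direction * ev$speed_mm_s * dt / sx
    pts <- eel_centerline(ev, t_s, head_x, ev$y_px, sx, sy)
    inside <- pts[, "x"] >= 1 & pts[, "x"] <= ncol_f &
      pts[, "y"] >= 1 & pts[, "y"] <= nrow_f
    if (!any(inside)) return(NULL)
    vis <- pts[inside, , drop = FALSE]
    radius_px <- ev$width_mm / 2 / ((sx + sy) / 2)
    px <- stamp_polyline(vis, radius_px, nrow_f, ncol_f)
    if (ev$fragmentation_rate > 0) {
      px <- fragment_pixels(px, vis, ev$fragmentation_rate)
    }
    if (nrow(px) == 0L) return(NULL)
    return(list(pixels = px, centerline = vis))
  }
  # compact fish / debris: filled ellipse advancing along x
  a <- ev$body_length_mm / 2 / sx
  b <- ev$body_length_mm * ev$aspect / 2 / sy
  entry_x <- if (ev$direction > 0) 1 - a else ncol_f + a
  cx <- entry_x + ev$direction * ev$speed_mm_s * dt / sx
  cy <- ev$y_px
  if (cx + a < 1 || cx - a > ncol_f) return(NULL)
  rows <- max(1L, floor(cy - b)):min(nrow_f, ceiling(cy + b))
  cols <- max(1L, floor(cx - a)):min(ncol_f, ceiling(cx + a))
  if (!length(rows) || !length(cols)) return(NULL)
  grid <- expand.grid(row = rows, col = cols)
  inside <- ((grid$col - cx) / a)^2 + ((grid$row - cy) / b)^2 <= 1
  px <- as.matrix(grid[inside, , drop = FALSE])
  if (nrow(px) == 0L) return(NULL)
  list(pixels = px, centerline = NULL)
}

# Drop random interior runs of centerline samples (echo fragmentation):
# body pixels nearest to dropped samples disappear, splitting the echo into
# pieces. The first and last blocks are never dropped -- fragmentation
# emulates mid-body dropouts that break one echo apart, not truncation of
# the extremities (which no reconstruction could undo).
fragment_pixels <- function(px, centerline, rate) {
  n <- nrow(centerline)
  block <- max(4L, round(n * 0.08))
  starts <- seq(1L, n, by = block)
  drop_block <- stats::runif(length(starts)) < rate
  drop_block[c(1L, length(drop_block))] <- FALSE
  if (!any(drop_block)) return(px)
  dropped <- unlist(lapply(which(drop_block), function(i) {
    starts[i]:min(n, starts[i] + block - 1L)
  }))
  # assign each pixel to its nearest centerline sample
  d2 <- outer(px[, "col"], centerline[, "x"], "-")^2 +
        outer(px[, "row"], centerline[, "y"], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  px[!(nearest %in% dropped), , drop = FALSE]
}

#' Generate a ground-truthed synthetic sonar scene
#'
#' Renders a stationary speckle background (mean = the configured reference
#' mean intensity, additive Gaussian noise clipped to 0--255) and the given
#' events, recording per-frame ground-truth masks and an event log in the
#' reference-count schema. Deterministic for a fixed seed.
#'
#' @param config A [recording_config()]; the number of image rows is derived
#'   from the window limits and pixel size.
#' @param n_frames Number of frames (>= 1).
#' @param events List of event specifications ([eel_event()] etc.).
#' @param noise_sd Grey-level standard deviation of the background speckle.
#' @param seed Random seed.
#' @param n_cols Image width in pixels.
#' @return An object of class `sim_scene`: list with `sequence` (a
#'   [frame_sequence()]), `events` (augmented with `frames`, `trajectory`,
#'   `masks`, `exit_frame`), `truth_log` (one row per eel event: `event`,
#'   `time_s`, `range_m`, `length_mm`) and `seed`.
#' @export
make_scene <- function(config, n_frames, events = list(), noise_sd = 5,
                       seed = 1L, n_cols = 280L) {
  stopifnot(n_frames >= 1L)
  n_rows <- round_half_up((config$window_stop_m - config$window_start_m) *
                          1000 / config$pixel_res_mm)
  for (ev in events) {
    if (!is.null(ev$y_px) && (ev$y_px < 1 || ev$y_px > n_rows)) {
      stop("event outside frame bounds: y_px = ", ev$y_px)
    }
  }
  with_seed(seed, {
    ev_aug <- lapply(events, function(ev) {
      if (ev$kind != "arc" && is.null(ev$y_px)) {
        ev$y_px <- round_half_up(n_rows / 2)
      }
      ev$frames <- integer(0)
      ev$trajectory <- NULL
      ev$masks <- list()
      ev
    })
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      f <- matrix(config$ref_mean_intensity, n_rows, n_cols)
      if (noise_sd > 0) {
        f <- f + matrix(stats::rnorm(n_rows * n_cols, 0, noise_sd),
                        n_rows, n_cols)
      }
      for (e in seq_along(ev_aug)) {
        r <- render_event_frame(ev_aug[[e]], t, config, n_rows, n_cols)
        if (is.null(r)) next
        f[r$pixels] <- pmax(f[r$pixels],
                            config$ref_mean_intensity +
                              ev_aug[[e]]$intensity)
        ev_aug[[e]]$frames <- c(ev_aug[[e]]$frames, t)
        ev_aug[[e]]$trajectory <- rbind(
          ev_aug[[e]]$trajectory,
          c(frame = t, x_px = mean(r$pixels[, "col"]),
            y_px = mean(r$pixels[, "row"])))
        ev_aug[[e]]$masks[[as.character(t)]] <- r$pixels
        if (!is.null(r$centerline)) {
          seg <- sqrt(diff(r$centerline[, "x"] * config$cross_res_mm)^2 +
                      diff(r$centerline[, "y"] * config$pixel_res_mm)^2)
          ev_aug[[e]]$centerline_lengths_mm[as.character(t)] <- sum(seg)
          ev_aug[[e]]$centerlines[[as.character(t)]] <- r$centerline
        }
      }
      frames[[t]] <- pmin(pmax(f, 0), 255)
    }
    ev_aug <- lapply(ev_aug, function(ev) {
      ev$exit_frame <- if (length(ev$frames)) max(ev$frames) else NA_integer_
      if (!is.null(ev$centerline_lengths_mm)) {
        # full-body visible frames carry the complete centerline
        ev$centerline_length_mm <- max(ev$centerline_lengths_mm)
      }
      ev
    })
    log_rows <- lapply(seq_along(ev_aug), function(e) {
      ev <- ev_aug[[e]]
      if (ev$kind != "eel" || length(ev$frames) == 0L) return(NULL)
      mean_row <- mean(vapply(ev$masks, function(m) mean(m[, "row"]),
                              numeric(1L)))
      data.frame(event = e,
                 time_s = mean((ev$frames - 1) / config$fps),
                 range_m = config$window_start_m +
                   (mean_row - 1) * config$pixel_res_mm / 1000,
                 length_mm = ev$body_length_mm)
    })
    truth_log <- do.call(rbind, log_rows)
    if (is.null(truth_log)) {
      truth_log <- data.frame(event = integer(0), time_s = numeric(0),
                              range_m = numeric(0), length_mm = numeric(0))
    }
    structure(list(sequence = frame_sequence(frames, config),
                   events = ev_aug, truth_log = truth_log, seed = seed),
              class = "sim_scene")
  })
}

#' @export
print.sim_scene <- function(x, ...) {
  kinds <- table(vapply(x$events, `[[`, character(1L), "kind"))
  cat(sprintf("<sim_scene> %d frames; events: %s; %d eel passes logged\n",
              length(x$sequence$frames),
              if (length(kinds)) paste(names(kinds), kinds, sep = "=",
                                       collapse = ", ") else "none",
              nrow(x$truth_log)))
  invisible(x)
}

#' Reference-count rows for a synthetic scene
#'
#' One row per eel event (time, range, length), in the schema of the
#' operator reference-count CSV; non-eel events are excluded.
#'
#' @param scene A `sim_scene` from [make_scene()].
#' @return Data frame with columns `time_s`, `range_m`, `length_cm`.
#' @export
truth_to_reference_counts <- function(scene) {
  data.frame(time_s = scene$truth_log$time_s,
             range_m = scene$truth_log$range_m,
             length_cm = scene$truth_log$length_mm / 10)
}
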