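# Shared fixtures: configurations, masks and synthetic scenes built in code.

test_config <- function(...) {
  args <- utils::modifyList(
    list(pixel_res_mm = 10, fps = 7, ref_mean_intensity = 20,
         min_eel_length_cm = 60, window_start_m = 1, window_stop_m = 3),
    list(...))
  do.call(recording_config, args)
}

# small frames (100 rows) for fast detection tests
small_config <- function(...) test_config(window_stop_m = 2, ...)

mask_from_coords <- function(coords, nrow, ncol) {
  m <- matrix(FALSE, nrow, ncol)
  m[coords] <- TRUE
  m
}

bar_mask <- function(nrow, ncol, rows, cols) {
  m <- matrix(FALSE, nrow, ncol)
  m[rows, cols] <- TRUE
  m
}

disc_mask <- function(radius, pad = 3L) {
  side <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  g <- expand.grid(r = seq_len(side), c = seq_len(side))
  m <- matrix(FALSE, side, side)
  m[as.matrix(g[(g$r - ctr)^2 + (g$c - ctr)^2 <= radius^2, ])] <- TRUE
  m
}

# minimal stubs for tracking/classification units (only the fields the
# tracker and the rules actually read)
fake_candidate <- function(x, y, frame, mask = matrix(TRUE, 3L, 70L),
                           thumbnail_area_mm2 = 810000, range_m = 2) {
  structure(list(frame_index = as.integer(frame),
                 centroid_px = c(x = x, y = y),
                 mask = mask, thumbnail_area_mm2 = thumbnail_area_mm2,
                 range_m = range_m,
                 main_axis_length_mm = 700),
            class = "eel_candidate")
}

fake_descriptor <- function(theta = 0, ecc = 0.95, len = 700,
                            area = 20000, sections = rep(ecc, 3L)) {
  structure(list(area_mm2 = area, orientation_deg = theta,
                 eccentricity = ecc, body_length_mm = len,
                 section_eccentricities = sections, n_fragments = 1L),
            class = "shape_descriptor")
}

# build a track through the public tracker from a centroid path
make_track <- function(xs, ys, frames, thetas = rep(0, length(xs)),
                       eccs = rep(0.95, length(xs)),
                       lens = rep(700, length(xs)),
                       areas = rep(20000, length(xs)),
                       config = test_config()) {
  cands <- Map(fake_candidate, xs, ys, frames)
  descs <- Map(function(th, e, l, a) fake_descriptor(th, e, l, a),
               thetas, eccs, lens, areas)
  skip <- if (length(frames) > 1L) max(diff(frames)) + 1L else 1L
  tracks <- track_candidates(cands, descs, config, max_skip_frames = skip)
  stopifnot(length(tracks) == 1L)
  tracks[[1L]]
}

# staggered two-lane scene: eels in the upper lane, compact fish in the
# lower one; entries spaced so passes never merge spatially
two_lane_scene <- function(n_eels, n_fish, seed, config = test_config(),
                           noise_sd = 4, fragmentation = 0.05,
                           eel_lengths_mm = NULL, n_cols = 260L,
                           spacing_frames = 32L) {
  if (is.null(eel_lengths_mm)) {
    eel_lengths_mm <- with_test_seed(seed, {
      round(stats::runif(n_eels, 620, 880))
    })
  }
  events <- list()
  for (i in seq_len(n_eels)) {
    events[[length(events) + 1L]] <- eel_event(
      eel_lengths_mm[i], entry_frame = 5L + (i - 1L) * spacing_frames,
      y_px = 55, fragmentation_rate = fragmentation)
  }
  for (i in seq_len(n_fish)) {
    events[[length(events) + 1L]] <- fish_event(
      300, entry_frame = 21L + (i - 1L) * spacing_frames, y_px = 150)
  }
  n_frames <- 5L + max(n_eels, n_fish) * spacing_frames + 30L
  make_scene(config, n_frames, events, noise_sd = noise_sd, seed = seed,
             n_cols = n_cols)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
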