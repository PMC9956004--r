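test_that("a steadily moving candidate forms a single track over 20 frames", {
  cfg <- test_config()
  xs <- 10 + 10 * (0:19); ys <- rep(60, 20)
  tr <- make_track(xs, ys, 1:20, config = cfg)
  expect_equal(length(tr$frames), 20)
  expect_equal(tr$frames, 1:20)
})

test_that("an orientation jump beyond the gate opens a new track", {
  cfg <- test_config()
  state <- tracker_state()
  state <- associate(state, list(fake_candidate(50, 60, 1)),
                     list(fake_descriptor(theta = 0)), 1, cfg)
  # 30 degrees away: rejected by the 25-degree gate
  state <- associate(state, list(fake_candidate(60, 60, 2)),
                     list(fake_descriptor(theta = 30)), 2, cfg)
  expect_length(state$open, 2)
  # 20 degrees away: accepted
  state2 <- tracker_state()
  state2 <- associate(state2, list(fake_candidate(50, 60, 1)),
                      list(fake_descriptor(theta = 0)), 1, cfg)
  state2 <- associate(state2, list(fake_candidate(60, 60, 2)),
                      list(fake_descriptor(theta = 20)), 2, cfg)
  expect_length(state2$open, 1)
})

test_that("distance ties break on orientation difference", {
  cfg <- test_config()
  state <- tracker_state()
  state <- associate(state, list(fake_candidate(50, 60, 1)),
                     list(fake_descriptor(theta = 10)), 1, cfg)
  # two equidistant candidates; the closer orientation wins the track
  state <- associate(state,
                     list(fake_candidate(60, 60, 2), fake_candidate(40, 60, 2)),
                     list(fake_descriptor(theta = 22),
                          fake_descriptor(theta = 11)), 2, cfg)
  expect_length(state$open, 2)
  lens <- vapply(state$open, function(tr) length(tr$frames), integer(1))
  grown <- state$open[[which(lens == 2)]]
  expect_equal(grown$orientations[2], 11)
})

test_that("the search radius scales with the number of skipped frames", {
  cfg <- test_config()  # radius = 0.75 x 600 mm = 450 mm = 45 px
  state <- tracker_state()
  state <- associate(state, list(fake_candidate(50, 60, 1)),
                     list(fake_descriptor()), 1, cfg, max_skip_frames = 3)
  # 60 px in one frame: outside the 45 px radius -> new track
  s1 <- associate(state, list(fake_candidate(110, 60, 2)),
                  list(fake_descriptor()), 2, cfg, max_skip_frames = 3)
  expect_length(s1$open, 2)
  # same 60 px after 2 skipped frames: inside 2 x 45 px -> same track
  s2 <- associate(state, list(fake_candidate(110, 60, 3)),
                  list(fake_descriptor()), 3, cfg, max_skip_frames = 3)
  expect_length(s2$open, 1)
})

test_that("tracks close after max_skip_frames without detections", {
  cfg <- test_config()
  cands <- c(lapply(1:6, function(t) fake_candidate(10 * t, 60, t)),
             lapply(16:20, function(t) fake_candidate(10 * t, 60, t)))
  descs <- replicate(length(cands), fake_descriptor(), simplify = FALSE)
  tracks <- track_candidates(cands, descs, cfg, max_skip_frames = 7)
  expect_length(tracks, 2)
  # a dropout within max_skip_frames keeps one track
  cands2 <- c(lapply(1:6, function(t) fake_candidate(10 * t, 60, t)),
              lapply(10:14, function(t) fake_candidate(10 * t, 60, t)))
  descs2 <- replicate(length(cands2), fake_descriptor(), simplify = FALSE)
  tracks2 <- track_candidates(cands2, descs2, cfg, max_skip_frames = 7)
  expect_length(tracks2, 1)
})

test_that("no candidate is ever assigned to two tracks", {
  cfg <- test_config()
  with_test_seed(31, {
    for (case in 1:20) {
      n_frames <- 12
      cands <- list()
      for (t in 1:n_frames) {
        for (k in 1:3) {
          cands[[length(cands) + 1]] <-
            fake_candidate(10 * t + 80 * k, 30 * k, t)
        }
      }
      descs <- replicate(length(cands), fake_descriptor(), simplify = FALSE)
      tracks <- track_candidates(cands, descs, cfg)
      keys <- unlist(lapply(tracks, function(tr) {
        vapply(seq_along(tr$frames), function(i) {
          paste(tr$frames[i], tr$centroids[i, 1], tr$centroids[i, 2])
        }, character(1))
      }))
      expect_false(any(duplicated(keys)))
      expect_length(keys, length(cands))
    }
  })
})

# independent oracle: repeated global-minimum selection over admissible pairs
oracle_match <- function(d, th, ids, gate_mm, theta_gate) {
  adm <- which(d <= gate_mm & th < theta_gate, arr.ind = TRUE)
  if (nrow(adm) == 0) return(integer(0))
  pool <- data.frame(ci = adm[, 1], ti = adm[, 2],
                     d = d[adm], th = th[adm], id = ids[adm[, 2]])
  out <- integer(0)
  while (nrow(pool)) {
    best <- pool[order(pool$d, pool$th, pool$id)[1], ]
    out[best$ti] <- best$ci
    pool <- pool[pool$ci != best$ci & pool$ti != best$ti, , drop = FALSE]
  }
  out
}

test_that("association equals a brute-force matching oracle on 500 instances", {
  cfg <- test_config()
  radius <- 0.75 * eel_ref_length_mm(cfg)  # one-frame gate, mm
  with_test_seed(32, {
    for (case in 1:500) {
      nt <- sample(1:5, 1); nc <- sample(1:5, 1)
      tx <- stats::runif(nt, 0, 300); ty <- stats::runif(nt, 0, 150)
      tth <- stats::runif(nt, 0, 180)
      cx <- stats::runif(nc, 0, 300); cy <- stats::runif(nc, 0, 150)
      cth <- stats::runif(nc, 0, 180)

      state <- tracker_state()
      state <- associate(state,
                         Map(fake_candidate, tx, ty, 1),
                         lapply(tth, function(a) fake_descriptor(theta = a)),
                         1, cfg)
      ids <- vapply(state$open, `[[`, integer(1), "id")
      # track order in state$open follows creation order = input order
      state <- associate(state,
                         Map(fake_candidate, cx, cy, 2),
                         lapply(cth, function(a) fake_descriptor(theta = a)),
                         2, cfg)

      d <- outer(seq_len(nc), seq_len(nt), function(i, j) {
        sqrt(((cx[i] - tx[j]) * 10)^2 + ((cy[i] - ty[j]) * 10)^2)
      })
      th <- outer(seq_len(nc), seq_len(nt), function(i, j) {
        orientation_diff_deg(cth[i], tth[j])
      })
      want <- oracle_match(d, th, ids, radius, 25)

      for (j in seq_len(nt)) {
        tr <- state$open[[j]]
        if (length(want) >= j && !is.na(want[j]) && length(tr$frames) == 2) {
          expect_equal(unname(tr$centroids[2, ]),
                       c(cx[want[j]], cy[want[j]]))
        } else {
          expect_length(tr$frames, 1)
        }
      }
    }
  })
})

test_that("track kinematics report step distance, velocity and direction", {
  cfg <- test_config(fps = 5)
  tr <- make_track(xs = 10 + 12 * (0:4), ys = rep(60, 5), frames = 1:5,
                   config = cfg)
  kin <- track_kinematics(tr, cfg)
  expect_equal(kin$mean_step_mm, 120)
  expect_equal(kin$velocity_mm_s, 600)
  expect_true(kin$direction_consistent)

  # one backward step breaks direction consistency
  tr2 <- make_track(xs = c(10, 22, 18, 30), ys = rep(60, 4), frames = 1:4,
                    config = cfg)
  expect_false(track_kinematics(tr2, cfg)$direction_consistent)

  # two-detection track: the single step is the mean
  tr3 <- make_track(xs = c(10, 14), ys = rep(60, 2), frames = 1:2,
                    config = cfg)
  expect_equal(track_kinematics(tr3, cfg)$mean_step_mm, 40)

  expect_error(track_kinematics(
    make_track(10, 60, 1, config = cfg), cfg), "fewer than 2")
})
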