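test_that("a filled disc is non-eccentric and a thin bar is nearly a line", {
  disc <- disc_mask(20)
  idx <- which(disc, arr.ind = TRUE)
  fit <- ellipse_fit(cbind(idx[, 2], idx[, 1]))
  expect_lt(fit$eccentricity, 0.05)

  bar <- cbind(x = 1:100, y = rep(1, 100))
  fitb <- ellipse_fit(bar, 10, 10)
  expect_gt(fitb$eccentricity, 0.99)
  expect_lt(fitb$eccentricity, 1)
  expect_equal(fitb$orientation_deg, 0)
})

test_that("eccentricity is invariant under translation and 90-degree rotation", {
  sc <- make_scene(test_config(), 16,
                   list(eel_event(750, entry_frame = 1, y_px = 100)),
                   noise_sd = 0, seed = 21)
  px <- sc$events[[1]]$masks[["14"]]
  coords <- cbind(x = px[, "col"], y = px[, "row"])
  base <- ellipse_fit(coords)$eccentricity
  shifted <- ellipse_fit(coords + 17)$eccentricity
  rotated <- ellipse_fit(cbind(x = -coords[, "y"], y = coords[, "x"]))
  expect_lt(abs(base - shifted), 1e-6)
  expect_lt(abs(base - rotated$eccentricity), 1e-6)
})

test_that("the moment fit agrees with an independent region-properties oracle", {
  px <- disc_mask(15) | bar_mask(37, 37, 17:21, 3:35)
  idx <- which(px, arr.ind = TRUE)
  fit <- ellipse_fit(cbind(idx[, 2], idx[, 1]))
  ftr <- EBImage::computeFeatures.moment(EBImage::Image(px * 1.0))
  expect_equal(fit$eccentricity, unname(ftr[1, "m.eccentricity"]),
               tolerance = 0.02)
  expect_equal(fit$major_axis, unname(ftr[1, "m.majoraxis"]),
               tolerance = 0.02)
})

test_that("a straight bar yields a single unbridged skeleton of the bar's length", {
  m <- bar_mask(20, 110, 9:11, 6:105)  # 100 px long, 10 mm/px
  sk <- reconstruct_skeleton(m, 10, 10)
  expect_equal(sk$n_fragments, 1)
  expect_equal(sk$n_bridges, 0)
  expect_equal(sk$length, 1000, tolerance = 0.05)
})

test_that("collinear fragments are bridged to within 3% of the unsplit length", {
  whole <- bar_mask(20, 110, 9:11, 6:105)
  split <- bar_mask(20, 110, 9:11, 6:35) |
    bar_mask(20, 110, 9:11, 40:70) | bar_mask(20, 110, 9:11, 75:105)
  sk_whole <- reconstruct_skeleton(whole, 10, 10)
  sk_split <- reconstruct_skeleton(split, 10, 10, max_gap_px = 20)
  expect_equal(sk_split$n_fragments, 3)
  expect_gte(sk_split$n_bridges, 2)
  expect_length(sk_split$chains, 1)
  expect_lt(abs(sk_split$length - sk_whole$length) / sk_whole$length, 0.03)
})

test_that("distant parallel bars are not bridged; the longer chain wins", {
  m <- bar_mask(60, 120, 9:11, 6:105) | bar_mask(60, 120, 49:51, 6:55)
  sk <- reconstruct_skeleton(m, 10, 10, max_gap_px = 20)
  expect_length(sk$chains, 2)
  expect_equal(sk$n_bridges, 0)
  expect_equal(sk$length, max(sk$chain_lengths))
  expect_equal(sk$length, 1000, tolerance = 0.06)
})

test_that("the skeleton chain cannot be shorter than its endpoint chord", {
  sc <- make_scene(test_config(), 16,
                   list(eel_event(800, entry_frame = 1, y_px = 100)),
                   noise_sd = 0, seed = 22)
  px <- sc$events[[1]]$masks[["13"]]
  m <- mask_from_coords(px, 200, 280)
  sk <- reconstruct_skeleton(m, 10, 10)
  chain <- sk$chains[[which.max(sk$chain_lengths)]]
  chord <- sqrt(sum(((chain[1, ] - chain[nrow(chain), ]) * 10)^2))
  expect_gte(sk$length, chord)
})

test_that("sinusoidal eel length is recovered within 10%", {
  cfg <- test_config()
  sc <- make_scene(cfg, 20, list(eel_event(780, entry_frame = 1, y_px = 100)),
                   noise_sd = 0, seed = 23)
  ev <- sc$events[[1]]
  full <- names(ev$centerline_lengths_mm)[
    ev$centerline_lengths_mm > 0.99 * max(ev$centerline_lengths_mm)]
  px <- ev$masks[[full[length(full)]]]
  sk <- reconstruct_skeleton(mask_from_coords(px, 200, 280), 10, 10)
  expect_lt(abs(sk$length - 780) / 780, 0.10)
})

test_that("k-means sections of a bar are straight and ordered along the body", {
  m <- bar_mask(20, 110, 9:11, 6:105)
  ks <- kmeans_sections(m, 3, seed = 1, sx = 10, sy = 10)
  expect_length(ks$eccentricities, 3)
  expect_true(all(ks$eccentricities > 0.95))
  expect_true(all(diff(ks$centers[, "x"]) > 0))  # head-to-tail order
  # deterministic for a fixed seed
  ks2 <- kmeans_sections(m, 3, seed = 1, sx = 10, sy = 10)
  expect_identical(ks$labels, ks2$labels)
})

test_that("k-means sections of a disc stay well below the eel threshold", {
  ks <- kmeans_sections(disc_mask(18), 3, seed = 1)
  # sectors of a disc are mildly elongated at most; nowhere near the 0.90
  # eccentricity an anguilliform section reaches
  expect_true(all(ks$eccentricities < 0.85))
  bar <- kmeans_sections(bar_mask(20, 110, 9:11, 6:105), 3, seed = 1)
  expect_lt(max(ks$eccentricities), min(bar$eccentricities))
})

test_that("sections of an undulating body are straighter than the whole", {
  cfg <- test_config()
  sc <- make_scene(cfg, 18,
                   list(eel_event(800, entry_frame = 1, y_px = 100,
                                  undulation_amp_mm = 90)),
                   noise_sd = 0, seed = 24)
  ev <- sc$events[[1]]
  full <- names(ev$centerline_lengths_mm)[
    ev$centerline_lengths_mm > 0.99 * max(ev$centerline_lengths_mm)]
  px <- ev$masks[[full[length(full)]]]
  m <- mask_from_coords(px, 200, 280)
  idx <- which(m, arr.ind = TRUE)
  whole <- ellipse_fit(cbind(idx[, 2], idx[, 1]), 10, 10)$eccentricity
  ks <- kmeans_sections(m, 3, seed = 1, sx = 10, sy = 10)
  expect_gte(min(ks$eccentricities), whole)
})

test_that("describe() assembles the full shape descriptor", {
  cfg <- test_config()
  sc <- make_scene(cfg, 20, list(eel_event(780, entry_frame = 1, y_px = 100)),
                   noise_sd = 0, seed = 25)
  ev <- sc$events[[1]]
  full <- names(ev$centerline_lengths_mm)[
    ev$centerline_lengths_mm > 0.99 * max(ev$centerline_lengths_mm)]
  px <- ev$masks[[full[2]]]
  r0 <- min(px[, "row"]); c0 <- min(px[, "col"])
  mask <- mask_from_coords(cbind(px[, "row"] - r0 + 1, px[, "col"] - c0 + 1),
                           max(px[, "row"]) - r0 + 1,
                           max(px[, "col"]) - c0 + 1)
  cand <- structure(list(frame_index = 10L, mask = mask,
                         offset = c(row = r0, col = c0),
                         centroid_px = c(x = mean(px[, "col"]),
                                         y = mean(px[, "row"])),
                         main_axis_length_mm = 700,
                         thumbnail = matrix(0, 90, 90),
                         thumbnail_area_mm2 = 810000, range_m = 2),
                    class = "eel_candidate")
  d <- describe(cand, cfg)
  expect_s3_class(d, "shape_descriptor")
  expect_equal(d$area_mm2, sum(mask) * 100)
  expect_gt(d$eccentricity, 0.9)
  expect_lt(abs(d$body_length_mm - 780) / 780, 0.10)
  expect_length(d$section_eccentricities, 3)
  expect_equal(d$n_fragments, 1)
  # degenerate masks are rejected
  tiny <- cand
  tiny$mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_error(describe(tiny, cfg), "degenerate")
})

test_that("fragmented eels keep their reconstructed length within 15%", {
  cfg <- test_config()
  for (rate in c(0.1, 0.2, 0.3)) {
    sc <- make_scene(cfg, 16,
                     list(eel_event(800, entry_frame = 1, y_px = 100,
                                    fragmentation_rate = rate)),
                     noise_sd = 0, seed = 26)
    ev <- sc$events[[1]]
    frames_full <- names(ev$centerlines)[
      vapply(ev$centerlines, function(cl) {
        all(cl[, "x"] >= 8 & cl[, "x"] <= 272)
      }, logical(1))]
    px <- ev$masks[[frames_full[length(frames_full)]]]
    sk <- reconstruct_skeleton(mask_from_coords(px, 200, 280), 10, 10,
                               max_gap_px = 30)
    expect_lt(abs(sk$length - 800) / 800, 0.15)
  }
})
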