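# Exact box mean filter via integral images; supports even kernel sizes and
# normalizes by the number of in-frame cells at the borders.
box_mean <- function(m, kh, kw) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  cs <- cbind(0, t(apply(cs, 1L, cumsum)))
  up <- (kh - 1L) %/% 2L; down <- kh - 1L - up
  left <- (kw - 1L) %/% 2L; right <- kw - 1L - left
  r1 <- pmax(seq_len(nr) - up, 1L); r2 <- pmin(seq_len(nr) + down, nr)
  c1 <- pmax(seq_len(nc) - left, 1L); c2 <- pmin(seq_len(nc) + right, nc)
  sums <- cs[r2 + 1L, c2 + 1L] - cs[r1, c2 + 1L] -
          cs[r2 + 1L, c1] + cs[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

# Mean-filter kernel in pixels from the mm specification (40 mm x 30 mm),
# rounded half-up with a floor of 1 px. Width (40 mm) runs along the
# cross-range (x) axis, height (30 mm) along the range (y) axis.
mean_filter_kernel_px <- function(config) {
  c(w = max(1L, round_half_up(40 / config$cross_res_mm)),
    h = max(1L, round_half_up(30 / config$pixel_res_mm)))
}

# 8-connected component labeling: 4-connected labels from EBImage::bwlabel,
# then labels touching diagonally are merged (skeletons and sonar echoes are
# 8-connected structures).
label_components <- function(mask) {
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1.0)))),
    nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]    # "\" diagonal neighbors
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]    # "/" diagonal neighbors
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # renumber to consecutive labels
  memb <- match(memb, sort(unique(memb)))
  out <- lab
  out[lab > 0L] <- memb[lab[lab > 0L]]
  out
}

#' Extract a square thumbnail centered on a candidate
#'
#' The thumbnail side is `min_eel_length_cm x 10 + 300` mm converted to
#' pixels; the window is clipped at frame borders and zero-padded so the
#' output is always square.
#'
#' @param frame Grayscale matrix.
#' @param centroid_px Numeric `(x, y)` pixel position (x = column, y = row).
#' @param config A [recording_config()].
#' @return List with `thumbnail` (square matrix), `side_px`, `side_mm`,
#'   `offset` (top-left `(row, col)` of the unclipped window, may be < 1).
#' @export
crop_thumbnail <- function(frame, centroid_px, config) {
  side_mm <- config$min_eel_length_cm * 10 + 300
  side_px <- round_half_up(side_mm / config$pixel_res_mm)
  cx <- round_half_up(centroid_px[[1L]]); cy <- round_half_up(centroid_px[[2L]])
  stopifnot(cx >= 1, cx <= ncol(frame), cy >= 1, cy <= nrow(frame))
  r0 <- cy - (side_px - 1L) %/% 2L
  c0 <- cx - (side_px - 1L) %/% 2L
  thumb <- matrix(0, side_px, side_px)
  rr <- r0:(r0 + side_px - 1L); cc <- c0:(c0 + side_px - 1L)
  rin <- rr >= 1L & rr <= nrow(frame); cin <- cc >= 1L & cc <= ncol(frame)
  thumb[rin, cin] <- frame[rr[rin], cc[cin]]
  list(thumbnail = thumb, side_px = side_px, side_mm = side_mm,
       offset = c(row = r0, col = c0))
}

new_candidate <- function(frame_index, mask, offset, centroid_px,
                          main_axis_length_mm, thumbnail, thumbnail_area_mm2,
                          range_m) {
  structure(list(frame_index = frame_index, mask = mask, offset = offset,
                 centroid_px = centroid_px,
                 main_axis_length_mm = main_axis_length_mm,
                 thumbnail = thumbnail,
                 thumbnail_area_mm2 = thumbnail_area_mm2,
                 range_m = range_m),
            class = "eel_candidate")
}

#' @export
print.eel_candidate <- function(x, ...) {
  cat(sprintf(
    "<candidate> frame %d at (%.1f, %.1f) px, %.0f mm main axis, %.2f m range\n",
    x$frame_index, x$centroid_px[1L], x$centroid_px[2L],
    x$main_axis_length_mm, x$range_m))
  invisible(x)
}

#' Detect candidate objects in the frames of interest
#'
#' For every frame inside the given intervals: box mean filter (40 mm x 30 mm
#' kernel in pixels), adaptive Gaussian-mixture foreground segmentation,
#' dilation (15 x 15 px by default) to merge nearby echo fragments into one
#' region of interest, connected-component labeling, and removal of
#' components whose fitted-ellipse major axis is shorter than
#' `min_axis_frac x min_eel_length`. Survivors are returned as candidates
#' with their (undilated) foreground mask, centroid, range and thumbnail.
#'
#' The background model is primed, per interval, on up to `history` frames
#' preceding the interval so that segmentation at the interval start reflects
#' the streaming background.
#'
#' @param seq A [frame_sequence()].
#' @param intervals Data frame from [extract_intervals()] (or any frame
#'   ranges with columns `start_frame`, `end_frame`).
#' @param config A [recording_config()].
#' @param dilation_px Side of the square dilation kernel, pixels.
#' @param min_axis_frac Minimum major-axis length as a fraction of the
#'   reference eel length.
#' @param min_pixels Components smaller than this are ignored outright.
#' @return List of `eel_candidate` objects.
#' @export
detect_candidates <- function(seq, intervals, config, dilation_px = 15L,
                              min_axis_frac = 0.25, min_pixels = 5L) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  if (nrow(intervals) > 0 &&
      (min(intervals$start_frame) < 1L || max(intervals$end_frame) > n)) {
    stop("index error: interval out of sequence bounds")
  }
  kern <- mean_filter_kernel_px(config)
  brush <- EBImage::makeBrush(dilation_px, shape = "box")
  min_axis_mm <- min_axis_frac * eel_ref_length_mm(config)
  sx <- config$cross_res_mm; sy <- config$pixel_res_mm
  out <- list()
  for (iv in seq_len(nrow(intervals))) {
    a <- intervals$start_frame[iv]; b <- intervals$end_frame[iv]
    state <- background_model(config)
    warm <- max(1L, a - state$history):(a - 1L)
    if (a > 1L) {
      for (t in warm) {
        background_apply(state, box_mean(seq$frames[[t]], kern["h"], kern["w"]))
      }
    }
    for (t in a:b) {
      smoothed <- box_mean(seq$frames[[t]], kern["h"], kern["w"])
      fg <- background_apply(state, smoothed)
      if (!any(fg)) next
      dil <- EBImage::dilate(EBImage::Image(fg * 1.0), brush) > 0
      lab <- label_components(matrix(dil, nrow(fg), ncol(fg)))
      for (comp in seq_len(max(lab))) {
        # candidate pixels are the undilated foreground within the region
        sel <- which(lab == comp & fg, arr.ind = TRUE)
        if (nrow(sel) < min_pixels) next
        coords <- cbind(x = sel[, 2L], y = sel[, 1L])
        fit <- ellipse_fit(coords, sx, sy)
        if (fit$major_axis < min_axis_mm) next
        r0 <- min(sel[, 1L]); c0 <- min(sel[, 2L])
        mask <- matrix(FALSE, max(sel[, 1L]) - r0 + 1L,
                       max(sel[, 2L]) - c0 + 1L)
        mask[cbind(sel[, 1L] - r0 + 1L, sel[, 2L] - c0 + 1L)] <- TRUE
        th <- crop_thumbnail(seq$frames[[t]], fit$centroid, config)
        out[[length(out) + 1L]] <- new_candidate(
          frame_index = t, mask = mask, offset = c(row = r0, col = c0),
          centroid_px = fit$centroid,
          main_axis_length_mm = fit$major_axis,
          thumbnail = th$thumbnail,
          thumbnail_area_mm2 = th$side_mm^2,
          range_m = config$window_start_m +
            (fit$centroid[["y"]] - 1) * config$pixel_res_mm / 1000)
      }
    }
  }
  out
}
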