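#' Singular-value-ratio echogram of a frame sequence
#'
#' For each frame the singular values `sigma_1 >= sigma_2 >= ...` of the frame
#' matrix are computed and compared with those of a reference (empty) frame:
#' `ratio_k(t) = sigma_k(frame_t) / sigma_k(reference)` for `k = 2, 3`. A
#' stationary speckle background is close to rank one (its mean), so the 2nd
#' and 3rd singular values respond selectively to elongated additive structure
#' crossing the field of view, and their ratios form a per-frame time series
#' ("echogram") used to screen frames of interest.
#'
#' Both numerator and denominator are clamped below at `1e-8`, so degenerate
#' rank-deficient frames give finite ratios (and ratio 1 when frame and
#' reference are equally degenerate).
#'
#' @param seq A [frame_sequence()].
#' @param reference A reference (empty) frame matrix -- ideally an
#'   operator-chosen empty image, as the reference mean intensity is read
#'   from one -- or `"auto"` to pick the emptiest frame of the sequence
#'   itself: the one with the smallest 2nd singular value. Objects elevate
#'   the 2nd singular value, so the minimizing frame is a background frame
#'   even when passes occupy most of the recording. (A pixel-wise median
#'   composite would average away the speckle noise and inflate every
#'   ratio; an actual frame preserves the noise floor of an empty image.)
#' @param ratio_mode `"reference"` (ratio to the reference frame's singular
#'   values, the default) or `"sigma1"` (ratio to the frame's own leading
#'   singular value).
#' @return An object of class `sv_echogram`: a data frame with columns
#'   `frame`, `ratio2`, `ratio3`.
#' @export
compute_sv_echogram <- function(seq, reference = "auto",
                                ratio_mode = c("reference", "sigma1")) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(inherits(seq, "frame_sequence"))
  dims <- dim(seq$frames[[1L]])
  eps <- 1e-8
  top_sv <- function(m) {
    d <- svd(m, nu = 0L, nv = 0L)$d
    c(d, numeric(3L))[1:3]
  }
  svs <- t(vapply(seq$frames, top_sv, numeric(3L)))
  if (identical(reference, "auto")) {
    ref_idx <- which.min(svs[, 2L])
    sv_ref <- svs[ref_idx, ]
  } else {
    if (!identical(dim(reference), dims)) {
      stop("shape error: reference frame must match the frame shape")
    }
    sv_ref <- top_sv(reference)
  }
  ratios <- t(vapply(seq_len(nrow(svs)), function(i) {
    den <- if (ratio_mode == "reference") sv_ref[2:3] else rep(svs[i, 1L], 2L)
    pmax(svs[i, 2:3], eps) / pmax(den, eps)
  }, numeric(2L)))
  structure(data.frame(frame = seq_along(seq$frames),
                       ratio2 = ratios[, 1L], ratio3 = ratios[, 2L]),
            class = c("sv_echogram", "data.frame"))
}

#' Extract intervals of frames of interest from an echogram
#'
#' Frames whose 2nd singular-value ratio exceeds `threshold_sv2` OR whose 3rd
#' ratio exceeds `threshold_sv3` are flagged; runs of flagged frames separated
#' by gaps of at most `min_gap_frames` unflagged frames are merged into one
#' interval.
#'
#' @param echo An `sv_echogram` from [compute_sv_echogram()].
#' @param threshold_sv2,threshold_sv3 Ratio thresholds (> 0).
#' @param min_gap_frames Largest unflagged gap (frame count) bridged when
#'   merging runs.
#' @return Data frame with columns `start_frame`, `end_frame` (inclusive) and
#'   `trigger` (`"sv2"`, `"sv3"` or `"both"`), sorted and pairwise disjoint.
#' @export
extract_intervals <- function(echo, threshold_sv2 = 1.2, threshold_sv3 = 1.2,
                              min_gap_frames = 0L) {
  stopifnot(threshold_sv2 > 0, threshold_sv3 > 0, min_gap_frames >= 0)
  f2 <- echo$ratio2 > threshold_sv2
  f3 <- echo$ratio3 > threshold_sv3
  flagged <- which(f2 | f3)
  if (length(flagged) == 0L) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      trigger = character(0)))
  }
  grp <- cumsum(c(1L, diff(flagged) > min_gap_frames + 1L))
  out <- do.call(rbind, lapply(split(flagged, grp), function(idx) {
    span <- echo$frame[idx[1L]]:echo$frame[idx[length(idx)]]
    has2 <- any(f2[echo$frame %in% span])
    has3 <- any(f3[echo$frame %in% span])
    data.frame(start_frame = echo$frame[idx[1L]],
               end_frame = echo$frame[idx[length(idx)]],
               trigger = if (has2 && has3) "both" else if (has2) "sv2" else "sv3")
  }))
  rownames(out) <- NULL
  out
}

#' Export an echogram as CSV
#'
#' @param echo An `sv_echogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_echogram_csv <- function(echo, path) {
  utils::write.csv(as.data.frame(echo), path, row.names = FALSE)
  invisible(path)
}
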