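#' Divide a body mask into k sections by k-means and measure each section
#'
#' K-means clustering on the body-pixel coordinates (squared-error objective)
#' splits an elongated body into `k` sections along its length; the ellipse
#' eccentricity of each section then describes the local straightness of the
#' body. An undulating anguilliform body is curved as a whole but nearly
#' straight within each of its three sections, whereas a compact fish blob is
#' non-eccentric everywhere.
#'
#' Results are deterministic for a fixed `seed` (multiple restarts, best
#' within-cluster sum of squares kept). When a skeleton chain is supplied,
#' sections are returned in head-to-tail order along the chain; otherwise they
#' are ordered by projection onto the body's major axis.
#'
#' @param mask Logical matrix with at least `k` `TRUE` pixels.
#' @param k Number of sections.
#' @param seed RNG seed for the k-means restarts.
#' @param sx,sy Physical pixel sizes (for the section ellipse fits).
#' @param chain Optional ordered skeleton-chain coordinates used to order
#'   sections head-to-tail.
#' @return List with `labels` (integer matrix, 0 outside the body),
#'   `eccentricities` (length `k`), and `centers`.
#' @export
kmeans_sections <- function(mask, k = 3L, seed = 1L, sx = 1, sy = 1,
                            chain = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < k) stop("degenerate shape: fewer pixels than sections")
  coords <- cbind(x = idx[, 2L], y = idx[, 1L])
  km <- with_seed(seed, stats::kmeans(coords, centers = k, nstart = 10L,
                                      iter.max = 50L))
  ecc <- vapply(seq_len(k), function(i) {
    ellipse_fit(coords[km$cluster == i, , drop = FALSE], sx, sy)$eccentricity
  }, numeric(1L))
  # order sections along the body
  ord <- if (!is.null(chain) && nrow(chain) > 1L) {
    pos <- vapply(seq_len(k), function(i) {
      ctr <- km$centers[i, ]
      which.min((chain[, 1L] - ctr[1L])^2 + (chain[, 2L] - ctr[2L])^2)
    }, integer(1L))
    order(pos)
  } else {
    fit <- ellipse_fit(coords, sx, sy)
    ang <- fit$orientation_deg * pi / 180
    proj <- km$centers[, 1L] * cos(ang) + km$centers[, 2L] * sin(ang)
    order(proj)
  }
  labels <- matrix(0L, nrow(mask), ncol(mask))
  relabel <- match(seq_len(k), ord)
  labels[idx] <- relabel[km$cluster]
  list(labels = labels, eccentricities = ecc[ord],
       centers = km$centers[ord, , drop = FALSE])
}

#' Shape descriptor of a candidate
#'
#' Computes the candidate's area (mm^2), fitted-ellipse orientation and
#' overall eccentricity, body length from the reconstructed skeleton, and the
#' three k-means section eccentricities.
#'
#' @param candidate An `eel_candidate` from [detect_candidates()].
#' @param config A [recording_config()].
#' @param seed Seed for the k-means sectioning.
#' @param max_bridge_frac Maximum skeleton-bridging gap as a fraction of the
#'   reference eel length.
#' @return An object of class `shape_descriptor`: list with `area_mm2`,
#'   `orientation_deg`, `eccentricity`, `body_length_mm`,
#'   `section_eccentricities`, `n_fragments`.
#' @export
describe <- function(candidate, config, seed = 1L, max_bridge_frac = 0.5) {
  mask <- candidate$mask
  if (sum(mask) < 3L) stop("degenerate shape: mask has fewer than 3 pixels")
  sx <- config$cross_res_mm; sy <- config$pixel_res_mm
  idx <- which(mask, arr.ind = TRUE)
  coords <- cbind(x = idx[, 2L], y = idx[, 1L])
  fit <- ellipse_fit(coords, sx, sy)
  max_gap_px <- max_bridge_frac * eel_ref_length_mm(config) /
    ((sx + sy) / 2)
  skel <- reconstruct_skeleton(mask, sx, sy, max_gap_px = max_gap_px)
  chain <- skel$chains[[which.max(skel$chain_lengths)]]
  sections <- kmeans_sections(mask, k = 3L, seed = seed, sx = sx, sy = sy,
                              chain = chain)
  structure(list(area_mm2 = nrow(coords) * sx * sy,
                 orientation_deg = fit$orientation_deg,
                 eccentricity = fit$eccentricity,
                 body_length_mm = skel$length,
                 section_eccentricities = sections$eccentricities,
                 n_fragments = skel$n_fragments),
            class = "shape_descriptor")
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf(
    "<shape> %.0f mm^2, %.0f deg, ecc %.3f, body %.0f mm (%d fragment%s)\n",
    x$area_mm2, x$orientation_deg, x$eccentricity, x$body_length_mm,
    x$n_fragments, if (x$n_fragments == 1L) "" else "s"))
  cat(sprintf("  section eccentricities: %s\n",
              paste(sprintf("%.3f", x$section_eccentricities), collapse = ", ")))
  invisible(x)
}
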