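#' Fit an ellipse to a set of pixel coordinates
#'
#' Moment-based ellipse fit: the ellipse with the same normalized second-order
#' central moments as the pixel set. Each pixel contributes its footprint
#' (variance `scale^2/12` per axis), so a one-pixel-wide line has eccentricity
#' strictly below 1. Eccentricity follows the focal-distance / major-axis
#' definition, `sqrt(1 - (b/a)^2)` for semi-axes `a >= b`.
#'
#' @param coords Two-column matrix of pixel coordinates (x = column,
#'   y = row).
#' @param sx,sy Physical size of one pixel along x and y (any consistent
#'   unit, e.g. mm); axis lengths are returned in that unit.
#' @return List with `centroid` (x, y, pixel units), `major_axis`,
#'   `minor_axis` (full lengths), `orientation_deg` in `[0, 180)` measured
#'   from the +x axis, and `eccentricity` in `[0, 1)`.
#' @export
ellipse_fit <- function(coords, sx = 1, sy = 1) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L, nrow(coords) >= 1L)
  x <- coords[, 1L] * sx
  y <- coords[, 2L] * sy
  mx <- mean(x); my <- mean(y)
  vxx <- mean((x - mx)^2) + sx^2 / 12
  vyy <- mean((y - my)^2) + sy^2 / 12
  vxy <- mean((x - mx) * (y - my))
  common <- sqrt((vxx - vyy)^2 / 4 + vxy^2)
  l1 <- (vxx + vyy) / 2 + common
  l2 <- (vxx + vyy) / 2 - common
  l2 <- max(l2, 0)
  theta <- 0.5 * atan2(2 * vxy, vxx - vyy) * 180 / pi
  theta <- theta %% 180
  list(centroid = c(x = mx / sx, y = my / sy),
       major_axis = 4 * sqrt(l1),
       minor_axis = 4 * sqrt(l2),
       orientation_deg = theta,
       eccentricity = sqrt(max(0, 1 - l2 / l1)))
}

#' Angular difference between two orientations, modulo 180 degrees
#'
#' Orientations of undirected axes are equivalent modulo 180 degrees; the
#' difference is folded into `[0, 90]`.
#' @param a,b Orientations in degrees.
#' @return Absolute difference in degrees, in `[0, 90]`.
#' @export
orientation_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

round_half_up <- function(x) floor(x + 0.5)

# Run a block with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
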