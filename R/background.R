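#' Adaptive Gaussian-mixture background segmenter
#'
#' Per-pixel mixture-of-Gaussians background model in the Stauffer-Grimson /
#' Zivkovic family: each pixel holds up to `n_modes` Gaussian modes with
#' weights, means and variances, updated online with learning rate
#' `1 / history`. A pixel is foreground when its value is not within the
#' variance threshold of any background-designated mode (modes ranked by
#' `weight / sd`, cumulated up to `background_ratio`).
#'
#' The two externally set parameters follow the pipeline configuration:
#' variance threshold `= 1.5 x ref_mean_intensity` (floored at 1 for a
#' degenerate blank reference) and history `= 14 x fps` frames.
#'
#' @param config A [recording_config()].
#' @param n_modes Gaussian modes per pixel.
#' @param background_ratio Cumulative weight defining background modes.
#' @param var_init Initial variance of a new mode (grey levels squared).
#' @param var_floor Variance floor.
#' @return An object of class `mog_background` (mutable environment).
#' @export
background_model <- function(config, n_modes = 3L, background_ratio = 0.9,
                             var_init = 36, var_floor = 4) {
  stopifnot(inherits(config, "recording_config"))
  st <- new.env(parent = emptyenv())
  st$var_threshold <- max(1.5 * config$ref_mean_intensity, 1)
  st$history <- round_half_up(14 * config$fps)
  st$alpha <- 1 / st$history
  st$n_modes <- as.integer(n_modes)
  st$background_ratio <- background_ratio
  st$var_init <- var_init
  st$var_floor <- var_floor
  st$w <- NULL    # npix x K weight / mean / variance arrays, lazily initialized
  class(st) <- "mog_background"
  st
}

#' @export
print.mog_background <- function(x, ...) {
  cat(sprintf("<mog_background> %d modes, varThreshold %.1f, history %d%s\n",
              x$n_modes, x$var_threshold, x$history,
              if (is.null(x$w)) " (uninitialized)" else ""))
  invisible(x)
}

#' Update the background model with one frame and segment its foreground
#'
#' @param state A [background_model()].
#' @param frame Numeric matrix, 0--255.
#' @param learn If `FALSE`, segment without adapting the model.
#' @return Logical foreground mask of the frame's shape.
#' @export
background_apply <- function(state, frame, learn = TRUE) {
  x <- as.numeric(frame)
  K <- state$n_modes
  n <- length(x)
  if (is.null(state$w)) {
    state$w <- cbind(rep(1, n), matrix(0, n, K - 1L))
    state$mu <- cbind(x, matrix(0, n, K - 1L))
    state$var <- matrix(state$var_init, n, K)
    state$dim <- dim(frame)
  }
  stopifnot(identical(dim(frame), state$dim))
  w <- state$w; mu <- state$mu; v <- state$var
  d2 <- (x - mu)^2
  match_ok <- d2 <= state$var_threshold * v & w > 0

  # rank modes by weight / sd; background modes cumulate to background_ratio
  fitness <- w / sqrt(v)
  rows <- seq_len(n)
  rk <- matrix(1L, n, K)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k) next
    rk[, k] <- rk[, k] + ((fitness[, j] > fitness[, k]) |
                          (fitness[, j] == fitness[, k] & j < k))
  }
  wcum_in_rank <- matrix(0, n, K)   # weight of modes ranked above each mode
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k) next
    wcum_in_rank[, k] <- wcum_in_rank[, k] + w[, j] * (rk[, j] < rk[, k])
  }
  is_bg_mode <- wcum_in_rank < state$background_ratio & w > 0

  # best (highest-fitness) matching mode per pixel
  fit_masked <- ifelse(match_ok, fitness, -Inf)
  best <- max.col(fit_masked, ties.method = "first")
  has_match <- fit_masked[cbind(rows, best)] > -Inf
  fg <- !has_match | !is_bg_mode[cbind(rows, best)]

  if (learn) {
    a <- state$alpha
    owner <- matrix(FALSE, n, K)
    owner[cbind(rows[has_match], best[has_match])] <- TRUE
    w <- w + a * (owner - w)
    rho <- a * owner
    mu <- mu + rho * (x - mu)
    v <- v + rho * ((x - mu)^2 - v)
    v <- pmax(v, state$var_floor)
    # unmatched pixels: replace their weakest mode with a new one
    nm <- which(!has_match)
    if (length(nm)) {
      weakest <- max.col(-w[nm, , drop = FALSE], ties.method = "last")
      idx <- cbind(nm, weakest)
      w[idx] <- a
      mu[idx] <- x[nm]
      v[idx] <- state$var_init
    }
    w <- w / rowSums(w)
    state$w <- w; state$mu <- mu; state$var <- v
  }
  matrix(fg, state$dim[1L], state$dim[2L])
}
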