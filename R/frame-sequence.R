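#' Time-ordered grayscale frame sequence
#'
#' A `frame_sequence` holds an ordered list of single-channel 8-bit frames
#' (numeric matrices, rows = range axis, columns = cross-range axis, values in
#' 0--255), their timestamps and the [recording_config()] that scales them.
#' Timestamps are `frame_index / fps` (0-based indices).
#'
#' @param frames List of numeric matrices of identical dimensions.
#' @param config A [recording_config()].
#' @param timestamps Optional per-frame times in seconds; defaults to
#'   `(seq_along(frames) - 1) / fps`.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, config, timestamps = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            inherits(config, "recording_config"))
  dims <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) {
    is.matrix(f) && identical(dim(f), dims) &&
      all(f >= 0) && all(f <= 255)
  }, logical(1L))
  if (!all(ok)) stop("all frames must share one shape with intensities in [0, 255]")
  if (is.null(timestamps)) {
    timestamps <- (seq_along(frames) - 1) / config$fps
  }
  stopifnot(length(timestamps) == length(frames),
            all(diff(timestamps) > 0) || length(timestamps) == 1L)
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 config = config),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence> %d frames of %d x %d px, %.1f fps (%.2f s)\n",
              length(x$frames), d[1L], d[2L], x$config$fps,
              utils::tail(x$timestamps, 1L)))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Read a video or frame stack into a frame sequence
#'
#' Accepts either an uncompressed 8-bit grayscale AVI file (see [read_avi()])
#' or a directory of numbered PNG/TIFF frames. Multi-channel frames are
#' collapsed to one channel by averaging. Pixel values are returned on the
#' 0--255 scale and timestamps are derived from `config$fps`.
#'
#' @param path AVI file path or directory of image frames.
#' @param config A [recording_config()].
#' @return A [frame_sequence()].
#' @export
read_sequence <- function(path, config) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) stop("no frames found in directory: ", path)
    files <- files[order(files)]
    frames <- lapply(files, read_frame_image)
  } else if (file.exists(path)) {
    if (tolower(tools::file_ext(path)) != "avi") {
      stop("unreadable input: expected an .avi file or a frame directory")
    }
    frames <- read_avi(path)
  } else {
    stop("input does not exist: ", path)
  }
  if (length(frames) == 0L) stop("empty input: no frames decoded")
  frame_sequence(frames, config)
}

read_frame_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  if (length(dim(img)) == 3L) {
    # collapse RGB(A) to one channel; ignore alpha
    nchan <- min(dim(img)[3L], 3L)
    img <- apply(img[, , seq_len(nchan), drop = FALSE], c(1L, 2L), mean)
  }
  round(img * 255)
}

#' Write a frame sequence as a PNG frame stack or AVI
#'
#' @param seq A [frame_sequence()].
#' @param path Output directory (frame stack) or `.avi` file path.
#' @param prefix Filename prefix for stack frames.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, prefix = "frame") {
  if (tolower(tools::file_ext(path)) == "avi") {
    write_avi(seq$frames, path, fps = seq$config$fps)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    f <- pmin(pmax(seq$frames[[i]], 0), 255) / 255
    png::writePNG(f, file.path(path, sprintf("%s_%05d.png", prefix, i)))
  }
  invisible(path)
}
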