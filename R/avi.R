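#' Minimal uncompressed grayscale AVI input/output
#'
#' Reads and writes the plain RIFF/AVI container with a single uncompressed
#' 8-bit palettized ("DIB") video stream -- the standard-format output of
#' sonar-to-AVI converters. No compression is supported; frames are numeric
#' matrices on the 0--255 scale (rows = image rows, top first).
#'
#' @param path File path of the `.avi` file.
#' @return `read_avi()` returns a list of numeric matrices; `write_avi()`
#'   returns `path` invisibly.
#' @export
read_avi <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 12L ||
      rawToChar(bytes[1:4]) != "RIFF" || rawToChar(bytes[9:12]) != "AVI ") {
    stop("format error: not a RIFF/AVI file: ", path)
  }
  u32 <- function(off) {
    sum(as.integer(bytes[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  u16 <- function(off) sum(as.integer(bytes[off + 1:2]) * c(1, 256))
  width <- height <- bitcount <- NULL
  frames_raw <- list()

  walk <- function(off, end) {
    while (off + 8 <= end) {
      id <- rawToChar(bytes[off + 1:4])
      size <- u32(off + 4L)
      body <- off + 8L
      if (id %in% c("RIFF", "LIST")) {
        walk(body + 4L, body + size)        # skip form type fourcc
      } else if (id == "strf" && is.null(width)) {
        width <<- u32(body + 4L)
        height <<- u32(body + 8L)
        bitcount <<- u16(body + 14L)
        compression <- u32(body + 16L)
        if (bitcount != 8L || compression != 0L) {
          stop("format error: only uncompressed 8-bit AVI streams are supported")
        }
      } else if (id %in% c("00db", "00dc") && size > 0L) {
        frames_raw[[length(frames_raw) + 1L]] <<- bytes[body + seq_len(size)]
      }
      off <- body + size + (size %% 2L)     # chunks are word-aligned
    }
  }
  walk(12L, 8L + u32(4L))   # children start after the 'AVI ' form type
  if (is.null(width)) stop("format error: no video stream header found")
  if (length(frames_raw) == 0L) stop("empty input: AVI contains no frames")
  stride <- 4L * ((width + 3L) %/% 4L)
  lapply(frames_raw, function(fr) {
    px <- matrix(as.integer(fr[seq_len(stride * height)]),
                 nrow = stride, ncol = height)[seq_len(width), , drop = FALSE]
    # DIB rows are stored bottom-up
    t(px)[height:1, , drop = FALSE] * 1.0
  })
}

#' @rdname read_avi
#' @param frames List of numeric matrices (0--255), identical dimensions.
#' @param fps Frame rate recorded in the stream header.
#' @export
write_avi <- function(frames, path, fps) {
  stopifnot(length(frames) >= 1L, fps > 0)
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  stride <- 4L * ((w + 3L) %/% 4L)
  framesize <- stride * h
  n <- length(frames)

  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con), add = TRUE)
  put_u32 <- function(x) writeBin(as.integer(round(x)), con, size = 4L,
                                  endian = "little")
  put_u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                                  endian = "little")
  put_4cc <- function(s) writeChar(s, con, nchars = 4L, eos = NULL)

  hdrl_size <- 4L + 8L + 56L + (8L + 4L + 8L + 56L + 8L + 40L + 1024L)
  movi_size <- 4L + n * (8L + framesize)
  idx_size <- n * 16L
  riff_size <- 4L + (8L + hdrl_size) + (8L + movi_size) + (8L + idx_size)

  put_4cc("RIFF"); put_u32(riff_size); put_4cc("AVI ")
  put_4cc("LIST"); put_u32(hdrl_size); put_4cc("hdrl")
  put_4cc("avih"); put_u32(56L)
  put_u32(1e6 / fps); put_u32(framesize * fps); put_u32(0L); put_u32(16L)
  put_u32(n); put_u32(0L); put_u32(1L); put_u32(framesize)
  put_u32(w); put_u32(h); for (i in 1:4) put_u32(0L)
  put_4cc("LIST"); put_u32(4L + 8L + 56L + 8L + 40L + 1024L); put_4cc("strl")
  put_4cc("strh"); put_u32(56L)
  put_4cc("vids"); put_4cc("DIB ")
  put_u32(0L); put_u32(0L); put_u32(0L)       # flags, priority/language, initial
  put_u32(1000L); put_u32(fps * 1000)          # scale, rate
  put_u32(0L); put_u32(n); put_u32(framesize); put_u32(0L); put_u32(0L)
  put_u16(0L); put_u16(0L); put_u16(w); put_u16(h)
  put_4cc("strf"); put_u32(40L + 1024L)
  put_u32(40L); put_u32(w); put_u32(h); put_u16(1L); put_u16(8L)
  put_u32(0L); put_u32(framesize); put_u32(0L); put_u32(0L)
  put_u32(256L); put_u32(0L)
  writeBin(as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256))), con)  # gray palette
  put_4cc("LIST"); put_u32(movi_size); put_4cc("movi")
  pad <- integer(stride - w)
  for (f in frames) {
    put_4cc("00db"); put_u32(framesize)
    px <- pmin(pmax(round(f), 0L), 255L)
    bottom_up <- t(px[h:1, , drop = FALSE])   # columns become raster rows
    if (length(pad)) bottom_up <- rbind(bottom_up, matrix(0L, length(pad), h))
    writeBin(as.raw(as.integer(bottom_up)), con)
  }
  put_4cc("idx1"); put_u32(idx_size)
  off <- 4L
  for (i in seq_len(n)) {
    put_4cc("00db"); put_u32(16L); put_u32(off); put_u32(framesize)
    off <- off + 8L + framesize
  }
  writeBin(rawConnectionValue(con), path)
  invisible(path)
}
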