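#' One predicted fish pass, as written to the detections CSV
#'
#' Holds the per-pass fields of the pipeline's output contract: the source
#' video, the mean time of passage, the frames and ranges where the fish was
#' detected, the number of detections and one measured body length per
#' detection frame.
#'
#' @param video Source video filename.
#' @param mean_passage_time_s Mean time of passage, seconds.
#' @param detection_frames Integer frame indices (0-based).
#' @param detection_ranges_m Detection range of each detection, metres.
#' @param lengths_mm Measured body length per detection frame, mm.
#' @return An object of class `detection_record`.
#' @export
detection_record <- function(video, mean_passage_time_s, detection_frames,
                             detection_ranges_m, lengths_mm) {
  n <- length(detection_frames)
  stopifnot(length(lengths_mm) == n, length(detection_ranges_m) == n, n >= 1L)
  structure(list(video = as.character(video),
                 mean_passage_time_s = as.numeric(mean_passage_time_s),
                 detection_frames = as.integer(detection_frames),
                 detection_ranges_m = as.numeric(detection_ranges_m),
                 n_detections = n,
                 lengths_mm = as.numeric(lengths_mm)),
            class = "detection_record")
}

detections_header <- c("video", "mean_time_s", "frames", "ranges_m",
                       "n_detections", "lengths_mm")

#' Write or read the detections CSV
#'
#' One row per predicted fish; list-valued fields (frames, ranges, lengths)
#' are `';'`-joined. The CSV is comma-separated, UTF-8, `'.'` decimal.
#'
#' @param records List of [detection_record()] objects (may be empty).
#' @param path Output CSV path.
#' @return `write_detections_csv()` returns `path` invisibly;
#'   `read_detections_csv()` returns a list of [detection_record()].
#' @export
write_detections_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(video = r$video,
               mean_time_s = r$mean_passage_time_s,
               frames = paste(r$detection_frames, collapse = ";"),
               ranges_m = paste(format(r$detection_ranges_m, trim = TRUE,
                                       digits = 15), collapse = ";"),
               n_detections = r$n_detections,
               lengths_mm = paste(format(r$lengths_mm, trim = TRUE,
                                         digits = 15), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)),
                                      length(detections_header)),
                                  detections_header))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), detections_header)) {
    stop("schema error: expected columns ", paste(detections_header,
                                                  collapse = ", "))
  }
  split_num <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
  lapply(seq_len(nrow(df)), function(i) {
    detection_record(video = df$video[i],
                     mean_passage_time_s = as.numeric(df$mean_time_s[i]),
                     detection_frames = as.integer(split_num(df$frames[i])),
                     detection_ranges_m = split_num(df$ranges_m[i]),
                     lengths_mm = split_num(df$lengths_mm[i]))
  })
}
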