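#' Recording configuration for an acoustic-camera deployment
#'
#' Bundles the camera and site parameters that drive every derived threshold in
#' the pipeline: the pixel footprint along the range axis, the frame rate, the
#' mean intensity of an empty reference image, the operator-set minimum eel
#' length, and the detection-window range limits.
#'
#' @param pixel_res_mm Length per pixel along the range (vertical) axis, in mm.
#' @param fps Frame rate, frames per second.
#' @param ref_mean_intensity Mean pixel intensity of the reference (empty)
#'   image on the 0--255 scale.
#' @param min_eel_length_cm Operator-set minimum length of the fish studied,
#'   in cm. Also the reference length for the decision rules.
#' @param window_start_m,window_stop_m Detection-range limits, in metres;
#'   image row 0 maps to `window_start_m`.
#' @param flow_axis_sign +1 or -1: direction of positive current along the
#'   image X axis.
#' @param length_class `"30-60"` or `"60-90"` (cm), selecting the decision-rule
#'   threshold column for the local eel population.
#' @param camera_label Free-text camera model label.
#' @param cross_res_mm Length per pixel along the cross-range (horizontal)
#'   axis, in mm. Defaults to `pixel_res_mm` (square pixels).
#'
#' @return An object of class `recording_config`.
#' @examples
#' cfg <- recording_config(pixel_res_mm = 6.8, fps = 7, ref_mean_intensity = 20,
#'                         min_eel_length_cm = 60, window_start_m = 0.7,
#'                         window_stop_m = 9.4)
#' pixel_to_mm(100, "range", cfg)
#' @export
recording_config <- function(pixel_res_mm, fps, ref_mean_intensity,
                             min_eel_length_cm,
                             window_start_m, window_stop_m,
                             flow_axis_sign = 1L,
                             length_class = c("60-90", "30-60"),
                             camera_label = "ARIS",
                             cross_res_mm = NULL) {
  length_class <- match.arg(length_class)
  stopifnot(
    is.numeric(pixel_res_mm), length(pixel_res_mm) == 1L, pixel_res_mm > 0,
    is.numeric(fps), length(fps) == 1L, fps > 0,
    is.numeric(ref_mean_intensity), ref_mean_intensity >= 0,
    ref_mean_intensity <= 255,
    is.numeric(min_eel_length_cm), min_eel_length_cm > 0,
    is.numeric(window_start_m), is.numeric(window_stop_m),
    window_stop_m > window_start_m,
    flow_axis_sign %in% c(-1, 1)
  )
  if (is.null(cross_res_mm)) cross_res_mm <- pixel_res_mm
  stopifnot(is.numeric(cross_res_mm), cross_res_mm > 0)
  structure(
    list(
      pixel_res_mm = as.numeric(pixel_res_mm),
      fps = as.numeric(fps),
      ref_mean_intensity = as.numeric(ref_mean_intensity),
      min_eel_length_cm = as.numeric(min_eel_length_cm),
      window_start_m = as.numeric(window_start_m),
      window_stop_m = as.numeric(window_stop_m),
      flow_axis_sign = as.integer(flow_axis_sign),
      length_class = length_class,
      camera_label = camera_label,
      cross_res_mm = as.numeric(cross_res_mm)
    ),
    class = "recording_config"
  )
}

#' @export
print.recording_config <- function(x, ...) {
  cat("<recording_config>", x$camera_label, "\n")
  cat(sprintf("  pixel: %.2f mm (range) x %.2f mm (cross); fps %.1f\n",
              x$pixel_res_mm, x$cross_res_mm, x$fps))
  cat(sprintf("  reference mean intensity: %.1f\n", x$ref_mean_intensity))
  cat(sprintf("  window: %.2f-%.2f m; min eel length %.0f cm (class %s)\n",
              x$window_start_m, x$window_stop_m, x$min_eel_length_cm,
              x$length_class))
  invisible(x)
}

#' Convert a pixel extent to millimetres
#'
#' @param candidate_extent_px Extent in pixels (>= 0).
#' @param axis `"range"` (image rows) or `"cross"` (image columns).
#' @param config A [recording_config()].
#' @return Length in mm.
#' @export
pixel_to_mm <- function(candidate_extent_px, axis = c("range", "cross"),
                        config) {
  axis <- match.arg(axis)
  stopifnot(all(candidate_extent_px >= 0))
  scale <- if (axis == "range") config$pixel_res_mm else config$cross_res_mm
  candidate_extent_px * scale
}

#' Reference length of the studied fish, in mm
#'
#' The operator-set minimum eel length expressed in mm; the frame- and
#' track-scale decision rules are proportional to it.
#' @param config A [recording_config()].
#' @return Length in mm.
#' @export
eel_ref_length_mm <- function(config) config$min_eel_length_cm * 10

#' Read or write a recording-configuration sidecar file
#'
#' Sidecars are YAML (or JSON) files holding the [recording_config()] fields,
#' stored next to the video they describe.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_config_sidecar()` returns a [recording_config()];
#'   `write_config_sidecar()` returns `path` invisibly.
#' @export
read_config_sidecar <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(recording_config, vals)
}

#' @rdname read_config_sidecar
#' @param config A [recording_config()] to serialize.
#' @export
write_config_sidecar <- function(config, path) {
  vals <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
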