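#' Pipeline configuration
#'
#' Central defaults for mask construction and artifact features. Any subset
#' can be overridden, or loaded from a YAML file with [read_qc_config()].
#'
#' @param background_threshold probability cutoff for the background-mask.
#' @param eye_boxes an [eye_box_spec()] in normalized space, or `NULL` to
#'   use [default_eye_boxes()] (valid for phantom geometry only).
#' @param ring_lower_frac,ring_top_margin ring-mask slab bounds, see
#'   [build_ring_mask()].
#' @param asf_window sagittal differencing window for ASF2.
#' @param asf_midline sagittal band center for ASF3 (`"auto"` or index).
#' @param asf_half_width half band width for ASF3.
#' @return A named list of class `qc_config`.
#' @export
qc_config <- function(background_threshold = 0.5,
                      eye_boxes = NULL,
                      ring_lower_frac = 0.6,
                      ring_top_margin = 5,
                      asf_window = 20,
                      asf_midline = "auto",
                      asf_half_width = 15) {
  structure(list(background_threshold = background_threshold,
                 eye_boxes = eye_boxes,
                 ring_lower_frac = ring_lower_frac,
                 ring_top_margin = ring_top_margin,
                 asf_window = asf_window,
                 asf_midline = asf_midline,
                 asf_half_width = asf_half_width),
            class = "qc_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [qc_config()], nested as
#' `masks: {background_threshold, eye_boxes: {left: {x: [..], ...},
#' right: ...}, ring: {lower_frac, top_margin}}` and
#' `asf: {window, midline, half_width}`. Unstated keys keep their
#' defaults.
#'
#' @param path path to a YAML file.
#' @return A `qc_config`.
#' @export
read_qc_config <- function(path) {
  if (!file.exists(path))
    stop_t1qc(sprintf("file not found: %s", path), "missing_file")
  y <- yaml::read_yaml(path)
  cfg <- qc_config()
  m <- y$masks
  if (!is.null(m$background_threshold))
    cfg$background_threshold <- m$background_threshold
  if (!is.null(m$eye_boxes))
    cfg$eye_boxes <- eye_box_spec(m$eye_boxes$left, m$eye_boxes$right)
  if (!is.null(m$ring$lower_frac)) cfg$ring_lower_frac <- m$ring$lower_frac
  if (!is.null(m$ring$top_margin)) cfg$ring_top_margin <- m$ring$top_margin
  a <- y$asf
  if (!is.null(a$window)) cfg$asf_window <- a$window
  if (!is.null(a$midline)) cfg$asf_midline <- a$midline
  if (!is.null(a$half_width)) cfg$asf_half_width <- a$half_width
  cfg
}
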