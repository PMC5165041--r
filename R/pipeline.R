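# Feature-extraction orchestration: masks -> volumetric features ->
# artifact features, for one subject or a whole cohort.

#' Extract the full feature vector for one subject
#'
#' Builds the subject's background-, eye- and ring-masks and computes the
#' three volumetric features (VF1 intensity histogram, VF2 histograms for
#' GM/WM/CSF, VF3 contrast score) and the three artifact features (ASF1
#' eye movement, ASF2 ringing, ASF3 aliasing).
#'
#' @param vol subject volume ([volume_grid()] or array).
#' @param maps the subject's [tissue_map_set()].
#' @param transform the subject's [transform_pair()]; identity for
#'   phantoms.
#' @param avg_background group-average normalized background map (3D
#'   array), or `NULL` to use the subject's own normalized background map.
#' @param config a [qc_config()].
#' @param subject_id character id carried into the output.
#' @return An object of class `feature_vector`.
#' @export
extract_features <- function(vol, maps, transform = NULL,
                             avg_background = NULL, config = qc_config(),
                             subject_id = "subject") {
  vol <- as_volume_grid(vol)
  transform <- transform %||% identity_transform(dim(vol))
  avg <- avg_background %||% normalize_map(maps$background, transform)
  bg <- background_mask(avg, transform,
                        threshold = config$background_threshold)
  boxes <- config$eye_boxes %||% default_eye_boxes(transform$target_shape)
  eye <- build_eye_mask(bg, boxes, transform)
  ring <- build_ring_mask(bg, head_extent_z(maps),
                          lower_frac = config$ring_lower_frac,
                          top_margin = config$ring_top_margin)
  structure(list(
    subject_id = subject_id,
    vf1 = vf1_histogram(vol)$counts,
    vf2_gm = vf2_class_histogram(maps$gm)$counts,
    vf2_wm = vf2_class_histogram(maps$wm)$counts,
    vf2_csf = vf2_class_histogram(maps$csf)$counts,
    vf3 = gw_t_score(vol, maps)$gw_t_score,
    asf1 = asf1_eye(vol, eye),
    asf2 = asf2_ring(vol, ring, window = config$asf_window),
    asf3 = asf3_alias(vol, midline = config$asf_midline,
                      half_width = config$asf_half_width)),
    class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(
    "<feature_vector> %s: vf3 = %.3g, asf1 = %.3g, asf2 = %.3g, asf3 = %.3g\n",
    x$subject_id, x$vf3, x$asf1, x$asf2, x$asf3))
  invisible(x)
}

# One wide data.frame row per feature vector.
.fv_row <- function(fv) {
  row <- data.frame(subject_id = fv$subject_id, vf3 = fv$vf3,
                    asf1 = fv$asf1, asf2 = fv$asf2, asf3 = fv$asf3,
                    stringsAsFactors = FALSE)
  wide <- c(stats::setNames(fv$vf1, sprintf("vf1_%03d", 1:100)),
            stats::setNames(fv$vf2_gm, sprintf("vf2gm_%03d", 1:100)),
            stats::setNames(fv$vf2_wm, sprintf("vf2wm_%03d", 1:100)),
            stats::setNames(fv$vf2_csf, sprintf("vf2csf_%03d", 1:100)))
  cbind(row, as.data.frame(as.list(wide)))
}

#' Extract features for a whole cohort
#'
#' Runs the group pipeline: every subject's background map is spatially
#' normalized, the normalized maps are averaged into the group background
#' region of interest, and each subject's masks and features are then
#' computed against that average (transformed back to native space).
#'
#' @param cohort list of subject records as returned by
#'   [generate_cohort()], i.e. each with `volume`, `maps`, `transform`,
#'   `label`.
#' @param config a [qc_config()].
#' @return A data.frame with one row per subject: `subject_id`, `final`
#'   (usable / not-usable, if labels are present), the scalar features
#'   `vf3`, `asf1`, `asf2`, `asf3`, and the 400 histogram count columns
#'   `vf1_001..vf1_100`, `vf2gm_*`, `vf2wm_*`, `vf2csf_*`.
#' @export
cohort_features <- function(cohort, config = qc_config()) {
  normalized <- lapply(cohort, function(s)
    normalize_map(s$maps$background, s$transform))
  avg <- average_background(normalized)
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    fv <- extract_features(s$volume, s$maps, s$transform,
                           avg_background = avg, config = config,
                           subject_id = s$label$subject_id %||%
                             sprintf("sub%03d", i))
    row <- .fv_row(fv)
    if (!is.null(s$label)) row <- cbind(row, final = s$label$final,
                                        stringsAsFactors = FALSE)
    row
  })
  do.call(rbind, rows)
}

# Column names backing each feature-combination token.
feature_columns <- function(combination, available) {
  sets <- list(
    VF1 = grep("^vf1_", available, value = TRUE),
    VF2 = grep("^vf2(gm|wm|csf)_", available, value = TRUE),
    VF3 = intersect("vf3", available),
    ASF1 = intersect("asf1", available),
    ASF2 = intersect("asf2", available),
    ASF3 = intersect("asf3", available))
  unknown <- setdiff(combination, names(sets))
  if (length(unknown))
    stop_t1qc(sprintf("unknown feature name(s): %s",
                      paste(unknown, collapse = ", ")), "feature_name")
  cols <- unlist(sets[combination], use.names = FALSE)
  if (!length(cols))
    stop_t1qc("feature combination selects no columns", "feature_name")
  cols
}

#' Write a feature table to CSV
#' @param features data.frame from [cohort_features()].
#' @param path output CSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV path written by [write_feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop_t1qc(sprintf("file not found: %s", path), "missing_file")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
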