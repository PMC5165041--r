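# Quality labels from the visual-inspection data model: a stage-I color
# (green / yellow / red), a per-artifact severity grade, and a final
# usable / not-usable call. Green volumes are usable by definition and red
# volumes not-usable; yellow volumes get their final call from a majority
# vote among raters.

.label_colors <- c("green", "yellow", "red")
.label_severities <- c("heavy", "moderate", "slight", "none")
.label_finals <- c("usable", "not-usable")
.label_artifacts <- c("eye_movement", "ringing", "aliasing",
                      "grainy", "head_movement", "teeth_filling")

#' Visual-inspection quality label
#'
#' @param subject_id character scalar.
#' @param stage1_color one of `"green"`, `"yellow"`, `"red"`.
#' @param severity named character vector grading each artifact
#'   (`eye_movement`, `ringing`, `aliasing`, `grainy`, `head_movement`,
#'   `teeth_filling`) as `"heavy"`, `"moderate"`, `"slight"` or `"none"`.
#'   Missing artifacts default to `"none"`.
#' @param final `"usable"` or `"not-usable"`. Green implies usable and red
#'   implies not-usable; violations raise a consistency error.
#' @return An object of class `quality_label`.
#' @export
#' @examples
#' quality_label("s01", "green", final = "usable")
quality_label <- function(subject_id, stage1_color,
                          severity = character(), final) {
  if (!stage1_color %in% .label_colors)
    stop_t1qc(sprintf("unknown stage-I color '%s'", stage1_color),
              "label_vocabulary")
  if (!final %in% .label_finals)
    stop_t1qc(sprintf("unknown final category '%s'", final),
              "label_vocabulary")
  sev <- rep("none", length(.label_artifacts))
  names(sev) <- .label_artifacts
  if (length(severity)) {
    bad <- setdiff(names(severity), .label_artifacts)
    if (length(bad))
      stop_t1qc(sprintf("unknown artifact name(s): %s",
                        paste(bad, collapse = ", ")), "label_vocabulary")
    if (!all(severity %in% .label_severities))
      stop_t1qc(sprintf("unknown severity grade(s): %s",
                        paste(setdiff(severity, .label_severities),
                              collapse = ", ")), "label_vocabulary")
    sev[names(severity)] <- severity
  }
  if (stage1_color == "green" && final != "usable")
    stop_t1qc(sprintf("subject %s: green volumes must be usable", subject_id),
              "label_consistency")
  if (stage1_color == "red" && final != "not-usable")
    stop_t1qc(sprintf("subject %s: red volumes must be not-usable",
                      subject_id), "label_consistency")
  structure(list(subject_id = as.character(subject_id),
                 stage1_color = stage1_color, severity = sev, final = final),
            class = "quality_label")
}

#' @export
print.quality_label <- function(x, ...) {
  cat(sprintf("<quality_label> %s: %s / %s\n", x$subject_id,
              x$stage1_color, x$final))
  invisible(x)
}

#' Read a label table from CSV
#'
#' Expects columns `subject_id`, `stage1_color`, one column per artifact
#' (`eye_movement`, `ringing`, `aliasing`, `grainy`, `head_movement`,
#' `teeth_filling`; missing columns are treated as all-`"none"`), and
#' `final`. The closed label vocabulary and the green-implies-usable /
#' red-implies-not-usable rules are enforced per row.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return A list of [quality_label()] objects.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path))
    stop_t1qc(sprintf("file not found: %s", path), "missing_file")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("subject_id", "stage1_color", "final")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_t1qc(sprintf("label table misses column(s): %s",
                      paste(miss, collapse = ", ")), "label_schema")
  sev_cols <- intersect(.label_artifacts, names(df))
  lapply(seq_len(nrow(df)), function(i) {
    sev <- vapply(sev_cols, function(cc) as.character(df[[cc]][i]),
                  character(1))
    tryCatch(
      quality_label(df$subject_id[i], df$stage1_color[i], sev, df$final[i]),
      t1qc_error = function(e)
        stop_t1qc(sprintf("row %d: %s", i, conditionMessage(e)),
                  "label_consistency"))
  })
}

#' Write a label table to CSV
#' @param labels list of [quality_label()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  df <- do.call(rbind, lapply(labels, function(l) {
    data.frame(subject_id = l$subject_id, stage1_color = l$stage1_color,
               as.list(l$severity), final = l$final,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Majority vote over usable / not-usable ratings
#'
#' Combines the per-rater calls for a yellow volume into a final category.
#' The winning category needs strictly more votes; an exact tie is an error
#' (panels have an odd number of raters, typically five to nine).
#'
#' @param votes character vector of `"usable"` / `"not-usable"`.
#' @return `"usable"` or `"not-usable"`.
#' @export
#' @examples
#' majority_vote(c("usable", "usable", "not-usable"))
majority_vote <- function(votes) {
  if (length(votes) < 1L)
    stop_t1qc("empty vote list", "vote")
  if (!all(votes %in% .label_finals))
    stop_t1qc("votes must be 'usable' or 'not-usable'", "label_vocabulary")
  n_u <- sum(votes == "usable")
  n_n <- length(votes) - n_u
  if (n_u == n_n)
    stop_t1qc("exact tie in majority vote", "vote_tie")
  if (n_u > n_n) "usable" else "not-usable"
}

#' Artifact bookkeeping summary
#'
#' Cross-tabulates a labelled cohort into three artifact classes: volumes
#' with no artifacts at all, volumes carrying at least one of the three
#' targeted artifacts (eye movement, ringing, aliasing), and volumes whose
#' only artifacts are other types (grainy, head movement, teeth filling).
#' Percentages are of the cohort total, rounded to whole percent.
#'
#' @param labels list of [quality_label()] objects.
#' @return A data.frame with columns `class`, `n`, `percent` and a final
#'   `total` row.
#' @export
artifact_breakdown <- function(labels) {
  targeted <- c("eye_movement", "ringing", "aliasing")
  other <- setdiff(.label_artifacts, targeted)
  has <- function(l, set) any(l$severity[set] != "none")
  any_targeted <- vapply(labels, has, logical(1), set = targeted)
  any_other <- vapply(labels, has, logical(1), set = other)
  n_none <- sum(!any_targeted & !any_other)
  n_targeted <- sum(any_targeted)
  n_other <- sum(!any_targeted & any_other)
  n <- length(labels)
  data.frame(
    class = c("no artifacts", "eye movement or ringing or aliasing",
              "other artifacts", "total"),
    n = c(n_none, n_targeted, n_other, n),
    percent = round(100 * c(n_none, n_targeted, n_other, n) / n),
    stringsAsFactors = FALSE)
}
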