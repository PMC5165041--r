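# Balanced, repeated, cross-validated SVM evaluation. Each repeat draws a
# class-balanced subsample, splits it into stratified folds, standardizes
# features on the training portion only, trains an RBF-kernel SVM and
# pools the fold predictions into accuracy, sensitivity (% of not-usable
# volumes correctly flagged) and specificity (% of usable volumes
# correctly passed). A permutation variant shuffles the training labels to
# build the chance distribution.

.finals_of <- function(labels) {
  y <- if (is.list(labels) && all(vapply(labels, inherits, logical(1),
                                         "quality_label")))
    vapply(labels, `[[`, character(1), "final") else as.character(labels)
  if (!all(y %in% c("usable", "not-usable")))
    stop_t1qc("labels must be 'usable' or 'not-usable'", "label_vocabulary")
  factor(y, levels = c("usable", "not-usable"))
}

#' Evaluation protocol configuration
#'
#' @param feature_combination character subset of `c("VF1", "VF2", "VF3",
#'   "ASF1", "ASF2", "ASF3")` naming the features fed to the SVM, or
#'   `NULL` to use every column of the feature matrix.
#' @param n_folds cross-validation folds (default 10).
#' @param n_repeats balanced-subsample repeats (default 1000).
#' @param n_permutations label permutations for the null (default 10000).
#' @param seed integer master seed; all subsampling, fold assignment and
#'   permutation randomness derives from it.
#' @param kernel,cost SVM kernel and regularization constant
#'   (\code{e1071::svm}).
#' @param gamma `"median"` for the median-distance heuristic on the
#'   training fold, or a numeric kernel width.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(feature_combination = NULL, n_folds = 10,
                              n_repeats = 1000, n_permutations = 10000,
                              seed = 1, kernel = "radial", cost = 1,
                              gamma = "median") {
  if (!is.null(feature_combination) && !length(feature_combination))
    stop_t1qc("feature combination must be non-empty", "config")
  if (n_folds < 2) stop_t1qc("need at least 2 folds", "config")
  if (n_repeats < 1 || n_permutations < 1)
    stop_t1qc("repeats and permutations must be >= 1", "config")
  structure(list(feature_combination = feature_combination,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), kernel = kernel, cost = cost,
                 gamma = gamma),
            class = "experiment_config")
}

#' Class-balanced subsample
#'
#' Keeps every minority-class index and draws, uniformly without
#' replacement, an equal number of majority-class indices.
#'
#' @param labels usable / not-usable labels (character, factor, or list of
#'   [quality_label()]).
#' @param seed integer seed.
#' @return Integer index vector, equal class counts.
#' @export
balanced_subsample <- function(labels, seed = 1) {
  y <- .finals_of(labels)
  n_u <- sum(y == "usable"); n_n <- sum(y == "not-usable")
  if (n_u == 0 || n_n == 0)
    stop_t1qc("both classes must be present", "empty_class")
  minority <- if (n_u <= n_n) "usable" else "not-usable"
  majority <- setdiff(levels(y), minority)
  min_idx <- which(y == minority)
  maj_idx <- which(y == majority)
  picked <- with_seed(seed,
                      maj_idx[sample.int(length(maj_idx), length(min_idx))])
  sort(c(min_idx, picked))
}

#' Stratified k-fold split
#'
#' Partitions indices into k disjoint test folds covering all samples,
#' stratified so each fold's class ratio is within one sample of the
#' global ratio; training sets are the complements.
#'
#' @param labels class labels (length n).
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of k elements, each `list(train = ..., test = ...)`.
#' @export
kfold_split <- function(labels, k = 10, seed = 1) {
  y <- as.factor(labels)
  n <- length(y)
  if (n < k) stop_t1qc(sprintf("n = %d < k = %d", n, k), "config")
  assignment <- integer(n)
  sizes <- integer(k)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      # extras go to the currently smallest folds to even out totals
      extra_folds <- order(sizes, seq_len(k))[seq_len(extra)]
      counts <- rep(base, k)
      counts[extra_folds] <- counts[extra_folds] + 1L
      fold_of <- rep(seq_len(k), counts)
      assignment[idx] <- fold_of
      sizes <- sizes + counts
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(assignment != f), test = which(assignment == f)))
}

# Median-distance heuristic for the RBF kernel width on (standardized)
# training data; deterministic, capped at 200 evenly spaced rows.
.median_gamma <- function(x) {
  n <- nrow(x)
  if (n > 200) x <- x[round(seq(1, n, length.out = 200)), , drop = FALSE]
  m <- stats::median(stats::dist(x))
  if (!is.finite(m) || m <= 0) 1 / ncol(x) else 1 / (2 * m^2)
}

# Train on one fold and predict its test set. `shuffle_seed`, when not
# NULL, permutes the *training* labels (the permutation-null protocol).
.fold_predict <- function(x, y, fold, config, shuffle_seed = NULL) {
  xtr <- x[fold$train, , drop = FALSE]
  ytr <- y[fold$train]
  ctr <- colMeans(xtr)
  str <- apply(xtr, 2, stats::sd)
  str[str == 0 | !is.finite(str)] <- 1
  xs <- scale(xtr, center = ctr, scale = str)
  xt <- scale(x[fold$test, , drop = FALSE], center = ctr, scale = str)
  if (!is.null(shuffle_seed))
    ytr <- with_seed(shuffle_seed, sample(ytr))
  g <- if (identical(config$gamma, "median")) .median_gamma(xs)
       else config$gamma
  fit <- e1071::svm(x = xs, y = ytr, kernel = config$kernel,
                    cost = config$cost, gamma = g, scale = FALSE)
  stats::predict(fit, xt)
}

# Rates from pooled predictions, in percent.
.rates <- function(pred, truth) {
  c(accuracy = 100 * mean(pred == truth),
    sensitivity = 100 * mean(pred[truth == "not-usable"] == "not-usable"),
    specificity = 100 * mean(pred[truth == "usable"] == "usable"))
}

# One repeat of the protocol: balanced subsample, stratified k-fold,
# per-fold standardize + SVM, pooled rates. Redraws (with a warning) if a
# training fold degenerates to a single class.
.one_repeat <- function(x, y, config, rep_seed, permute = FALSE) {
  for (attempt in 0:9) {
    s <- child_seed(rep_seed, attempt * 977)
    idx <- balanced_subsample(y, seed = s)
    ys <- droplevels(y[idx])
    folds <- kfold_split(ys, k = config$n_folds,
                         seed = child_seed(s, 13))
    if (!all(vapply(folds, function(f)
      nlevels(droplevels(ys[f$train])) == 2L, logical(1)))) {
      warning("degenerate training fold (single class); redrawing repeat")
      next
    }
    xs <- x[idx, , drop = FALSE]
    pred <- factor(rep(NA_character_, length(idx)), levels = levels(ys))
    for (j in seq_along(folds)) {
      shuffle_seed <- if (permute) child_seed(s, 7000 + j) else NULL
      pred[folds[[j]]$test] <- .fold_predict(xs, ys, folds[[j]], config,
                                             shuffle_seed)
    }
    return(.rates(pred, ys))
  }
  stop_t1qc("could not draw a non-degenerate repeat", "degenerate_fold")
}

# Resolve the design matrix from a feature data.frame or matrix.
.design_matrix <- function(features, config) {
  if (is.data.frame(features)) {
    cols <- if (is.null(config$feature_combination)) {
      setdiff(names(features)[vapply(features, is.numeric, logical(1))],
              c("final"))
    } else feature_columns(config$feature_combination, names(features))
    as.matrix(features[, cols, drop = FALSE])
  } else {
    as.matrix(features)
  }
}

#' Repeated balanced cross-validated SVM evaluation
#'
#' Runs `n_repeats` iterations of: balanced subsample, stratified k-fold
#' cross-validation with training-fold-only standardization, SVM training
#' and test-fold prediction; fold predictions are pooled into per-repeat
#' accuracy, sensitivity and specificity (percent).
#'
#' @param features data.frame from [cohort_features()] (columns selected
#'   via `config$feature_combination`) or a plain numeric matrix.
#' @param labels usable / not-usable labels, aligned with `features` rows.
#' @param config an [experiment_config()].
#' @return An object of class `evaluation_result`: per-repeat `accuracy`,
#'   `sensitivity`, `specificity` vectors plus their means and standard
#'   errors.
#' @export
train_and_evaluate <- function(features, labels, config) {
  x <- .design_matrix(features, config)
  y <- .finals_of(labels)
  if (nrow(x) != length(y))
    stop_t1qc("features and labels disagree in length", "config")
  out <- vapply(seq_len(config$n_repeats), function(r)
    .one_repeat(x, y, config, child_seed(config$seed, r)),
    numeric(3))
  res <- list(accuracy = out["accuracy", ],
              sensitivity = out["sensitivity", ],
              specificity = out["specificity", ],
              config = config)
  res$mean <- vapply(res[1:3], mean, numeric(1))
  res$se <- vapply(res[1:3], function(v)
    stats::sd(v) / sqrt(length(v)), numeric(1))
  structure(res, class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_result> %d repeats\n",
           "  accuracy    %.1f%% (SE %.2f)\n",
           "  sensitivity %.1f%% (SE %.2f)\n",
           "  specificity %.1f%% (SE %.2f)\n"),
    length(x$accuracy),
    x$mean["accuracy"], x$se["accuracy"],
    x$mean["sensitivity"], x$se["sensitivity"],
    x$mean["specificity"], x$se["specificity"]))
  invisible(x)
}

#' Permutation null for the classification accuracy
#'
#' Repeats the full protocol with the training labels randomly shuffled in
#' every fold (test labels intact), building the chance distribution of
#' accuracies. The p-value for the observed mean accuracy uses the add-one
#' estimator `(1 + #{null >= observed}) / (1 + n_permutations)`, which
#' cannot return zero from finitely many permutations.
#'
#' @inheritParams train_and_evaluate
#' @param observed observed mean accuracy (percent); computed via
#'   [train_and_evaluate()] when `NULL`.
#' @return An object of class `permutation_result` with the null accuracy
#'   distribution, the observed mean and the p-value.
#' @export
permutation_null <- function(features, labels, config, observed = NULL) {
  x <- .design_matrix(features, config)
  y <- .finals_of(labels)
  if (is.null(observed)) {
    obs <- train_and_evaluate(features, labels, config)
    observed <- unname(obs$mean["accuracy"])
  }
  null_acc <- vapply(seq_len(config$n_permutations), function(p)
    .one_repeat(x, y, config, child_seed(config$seed, 500000 + p),
                permute = TRUE)[["accuracy"]],
    numeric(1))
  p_value <- (1 + sum(null_acc >= observed)) / (1 + length(null_acc))
  structure(list(null_accuracy = null_acc, observed = observed,
                 p_value = p_value, config = config),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.1f%% vs null mean %.1f%% over %d permutations, p = %.4g\n",
    x$observed, mean(x$null_accuracy), length(x$null_accuracy), x$p_value))
  invisible(x)
}

.sig_flag <- function(p) ifelse(p < 1e-3, "**", ifelse(p < 0.05, "*", ""))

#' Pairwise comparison of feature combinations
#'
#' Student's two-sample two-tailed t-test between every pair of accuracy
#' distributions, flagging p < 0.05 (`*`) and p < 1e-3 (`**`);
#' Bonferroni-adjusted p-values are reported alongside the unadjusted
#' ones.
#'
#' @param results named list (>= 2) of [train_and_evaluate()] results with
#'   equal repeat counts.
#' @return data.frame with one row per pair: means, `t`, `p`, `sig`,
#'   `p_bonferroni`.
#' @export
compare_combinations <- function(results) {
  if (length(results) < 2L)
    stop_t1qc("need at least two combinations to compare", "config")
  ns <- vapply(results, function(r) length(r$accuracy), integer(1))
  if (length(unique(ns)) != 1L)
    stop_t1qc("repeat counts differ across combinations", "config")
  nms <- names(results)
  pairs <- utils::combn(seq_along(results), 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- results[[pr[1]]]$accuracy; b <- results[[pr[2]]]$accuracy
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop_t1qc("zero-variance accuracy distributions", "zero_variance")
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(combination_1 = nms[pr[1]], combination_2 = nms[pr[2]],
               mean_1 = mean(a), mean_2 = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sig <- .sig_flag(out$p)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Severity-group contrasts for a feature
#'
#' Groups a per-subject scalar feature by visual-inspection severity
#' (none < slight < moderate < heavy; empty groups are dropped), reports
#' each group's mean and standard error, and tests every pair of groups
#' with Student's two-tailed t-test. Pairs involving a single-subject
#' group carry no variance and are marked untestable.
#'
#' @param values numeric per-subject feature values.
#' @param severities per-subject severity grades.
#' @return List with `groups` (severity, n, mean, se) and `tests`
#'   (pairwise t, p, sig, testable).
#' @export
severity_contrast <- function(values, severities) {
  sev <- factor(severities, levels = c("none", "slight", "moderate",
                                       "heavy"))
  if (any(is.na(sev)))
    stop_t1qc("unknown severity grade(s)", "label_vocabulary")
  sev <- droplevels(sev)
  groups <- data.frame(
    severity = levels(sev),
    n = as.integer(table(sev)),
    mean = as.numeric(tapply(values, sev, mean)),
    se = as.numeric(tapply(values, sev, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)),
    stringsAsFactors = FALSE)
  if (nlevels(sev) < 2L)
    return(list(groups = groups,
                tests = data.frame(group_1 = character(),
                                   group_2 = character(), t = numeric(),
                                   p = numeric(), sig = character(),
                                   testable = logical())))
  pairs <- utils::combn(levels(sev), 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- values[sev == pr[1]]; b <- values[sev == pr[2]]
    res <- data.frame(group_1 = pr[1], group_2 = pr[2], t = NA_real_,
                      p = NA_real_, sig = "", testable = FALSE,
                      stringsAsFactors = FALSE)
    if (length(a) > 1 && length(b) > 1) {
      tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                     error = function(e) NULL)
      if (!is.null(tt)) {
        res$t <- unname(tt$statistic); res$p <- tt$p.value
        res$sig <- .sig_flag(tt$p.value); res$testable <- TRUE
      }
    }
    res
  })
  list(groups = groups, tests = do.call(rbind, rows))
}
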