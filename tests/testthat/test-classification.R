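test_that("balanced subsampling equalizes class counts", {
  y <- c(rep("usable", 40), rep("not-usable", 12))
  idx <- balanced_subsample(y, seed = 1)
  expect_length(idx, 24)
  expect_identical(unname(table(y[idx])["usable"]), 12L)
  expect_identical(idx, balanced_subsample(y, seed = 1))
  expect_false(identical(idx, balanced_subsample(y, seed = 2)))
  # already balanced: everything is returned
  yb <- rep(c("usable", "not-usable"), 10)
  expect_identical(balanced_subsample(yb, seed = 3), 1:20)
  expect_error(balanced_subsample(rep("usable", 5), seed = 1),
               class = "t1qc_empty_class_error")
})

test_that("stratified k-fold partitions with near-equal sizes", {
  y <- rep(c("usable", "not-usable"), each = 190)
  folds <- kfold_split(y, k = 10, seed = 2)
  test_sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_true(all(test_sizes == 38))
  expect_true(all(vapply(folds, function(f) length(f$train), integer(1))
                  == 342))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_along(y))     # disjoint cover
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    ratio <- table(y[f$test])
    expect_lte(abs(diff(as.integer(ratio))), 1)
  }
  # uneven class sizes still give fold sizes within one of each other
  y2 <- c(rep("usable", 30), rep("not-usable", 23))
  sz <- vapply(kfold_split(y2, k = 10, seed = 4), function(f)
    length(f$test), integer(1))
  expect_lte(diff(range(sz)), 1)
  expect_identical(sum(sz), 53L)
  expect_error(kfold_split(y2[1:5], k = 10),
               class = "t1qc_config_error")
})

test_that("evaluation is deterministic and internally consistent", {
  blobs <- make_blobs(n = 60, gap = 3, seed = 13)
  cfg <- experiment_config(n_repeats = 5, seed = 11)
  r1 <- train_and_evaluate(blobs$x, blobs$y, cfg)
  r2 <- train_and_evaluate(blobs$x, blobs$y, cfg)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$sensitivity, r2$sensitivity)
  # pooled predictions on a balanced subsample: accuracy is the average of
  # the class rates
  expect_equal(r1$accuracy, (r1$sensitivity + r1$specificity) / 2,
               tolerance = 1e-12)
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 100))
})

test_that("permutation null centres on chance", {
  blobs <- make_blobs(n = 60, gap = 3, seed = 17)
  cfg <- experiment_config(n_repeats = 5, n_permutations = 30, seed = 19)
  pn <- permutation_null(blobs$x, blobs$y, cfg)
  se <- sd(pn$null_accuracy) / sqrt(length(pn$null_accuracy))
  expect_lt(abs(mean(pn$null_accuracy) - 50), 3 * se + 1e-9)
  expect_gt(pn$p_value, 0)
  expect_lte(pn$p_value, 1)
  # separable blobs: observed accuracy beats every permutation
  expect_identical(pn$p_value, 1 / (1 + 30))
})

test_that("combination comparison flags clear differences", {
  fake <- function(mu, sd, n = 1000, seed) {
    old <- .Random.seed; on.exit(.Random.seed <<- old)
    set.seed(seed)
    structure(list(accuracy = rnorm(n, mu, sd)),
              class = "evaluation_result")
  }
  a <- fake(80, 2, seed = 23); b <- fake(70, 2, seed = 24)
  tab <- compare_combinations(list(ASF = a, VF = b))
  expect_identical(nrow(tab), 1L)
  expect_lt(tab$p, 1e-3)
  expect_identical(tab$sig, "**")
  # a distribution against itself: t = 0, p = 1
  self <- compare_combinations(list(A = a, B = a))
  expect_equal(self$t, 0)
  expect_equal(self$p, 1)
  const <- structure(list(accuracy = rep(50, 1000)),
                     class = "evaluation_result")
  expect_error(compare_combinations(list(A = const, B = const)),
               class = "t1qc_zero_variance_error")
})

test_that("severity contrasts report group means and pairwise tests", {
  old <- .Random.seed; on.exit(.Random.seed <<- old)
  set.seed(29)
  sev <- rep(c("none", "slight", "moderate", "heavy"), each = 20)
  vals <- rnorm(80, rep(c(0, 1, 2, 3), each = 20), 0.1)
  sc <- severity_contrast(vals, sev)
  expect_identical(sc$groups$severity,
                   c("none", "slight", "moderate", "heavy"))
  expect_true(all(diff(sc$groups$mean) > 0))
  expect_true(all(sc$tests$p < 1e-3))
  expect_true(all(sc$tests$sig == "**"))

  # same-distribution null: mostly non-significant
  null <- severity_contrast(rnorm(40), rep(c("none", "slight"), each = 20))
  expect_identical(nrow(null$tests), 1L)
  expect_true(null$tests$testable)

  # absent groups are dropped; single group yields an empty table
  one <- severity_contrast(rnorm(5), rep("heavy", 5))
  expect_identical(nrow(one$tests), 0L)
  # n = 1 group: untestable pairs
  tiny <- severity_contrast(c(rnorm(10), 5),
                            c(rep("none", 10), "heavy"))
  expect_false(tiny$tests$testable)
  expect_true(is.na(tiny$tests$p))
})
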