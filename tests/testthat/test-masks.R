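test_that("normalize_map is exact for identity and translation", {
  set.seed(21)
  m <- array(runif(10 * 10 * 10), dim = c(10, 10, 10))
  t_id <- identity_transform(c(10, 10, 10))
  expect_identical(normalize_map(m, t_id), m)

  ones <- array(1, dim = c(10, 10, 10))
  expect_identical(normalize_map(ones, t_id), ones)

  # integer translation by (2, 0, 0): a delta moves exactly
  fw <- diag(4); fw[1, 4] <- 2
  tr <- transform_pair(fw, native_shape = c(10, 10, 10))
  delta <- array(0, dim = c(10, 10, 10)); delta[4, 5, 6] <- 1
  out <- normalize_map(delta, tr)
  expect_equal(out[6, 5, 6], 1)
  expect_equal(sum(out), 1)
})

test_that("average_background equals the per-voxel loop oracle", {
  set.seed(31)
  maps <- replicate(5, array(runif(6 * 5 * 4), dim = c(6, 5, 4)),
                    simplify = FALSE)
  avg <- average_background(maps)
  oracle <- array(0, dim = c(6, 5, 4))
  for (i in 1:6) for (j in 1:5) for (k in 1:4)
    oracle[i, j, k] <- mean(vapply(maps, function(m) m[i, j, k],
                                   numeric(1)))
  expect_equal(avg, oracle, tolerance = 0)
  expect_identical(average_background(list(maps[[1]], maps[[1]])),
                   maps[[1]])
  expect_error(average_background(list()), class = "t1qc_empty_input_error")
  expect_error(average_background(list(maps[[1]],
                                       array(0, dim = c(2, 2, 2)))),
               class = "t1qc_map_shape_error")
})

test_that("background-mask thresholding is closed at 0.5", {
  t_id <- identity_transform(c(5, 5, 5))
  low <- array(0.4, dim = c(5, 5, 5))
  expect_identical(sum(background_mask(low, t_id)$data), 0L)
  edge <- array(0.5, dim = c(5, 5, 5))
  expect_identical(sum(background_mask(edge, t_id)$data), 125L)
})

test_that("phantom background-mask excludes all head tissue", {
  ph <- small_phantom(noise_sd = 0)
  mk <- phantom_masks(ph)
  head_prob <- 1 - ph$maps$background
  expect_identical(sum(mk$bg$data & (head_prob > 0.5)), 0L)
})

test_that("eye-mask is anterior background inside the socket footprint", {
  ph <- small_phantom(noise_sd = 0)
  mk <- phantom_masks(ph)
  expect_gt(sum(mk$eye$data), 0)
  expect_true(all(mk$bg$data[mk$eye$data]))          # eye subset of bg
  head <- !mk$bg$data
  boxes <- default_eye_boxes(small_shape)
  in_fp <- array(FALSE, dim = small_shape)
  for (b in boxes[c("left", "right")])
    in_fp[b$x[1]:b$x[2], , b$z[1]:b$z[2]] <- TRUE
  expect_true(all(in_fp[mk$eye$data]))
  # strictly anterior: no head voxel at the same (x, z) with smaller y
  idx <- which(mk$eye$data, arr.ind = TRUE)
  for (r in sample(nrow(idx), min(50, nrow(idx)))) {
    x <- idx[r, 1]; y <- idx[r, 2]; z <- idx[r, 3]
    expect_false(any(head[x, 1:y, z]))
  }
  empty_bg <- binary_mask(array(FALSE, dim = small_shape), "background")
  expect_identical(sum(build_eye_mask(empty_bg, boxes,
                                      ph$transform)$data), 0L)
})

test_that("ring-mask is a background slab near the top of the head", {
  ph <- small_phantom(noise_sd = 0)
  mk <- phantom_masks(ph)
  expect_gt(sum(mk$ring$data), 0)
  expect_true(all(mk$bg$data[mk$ring$data]))
  head_prob <- 1 - ph$maps$background
  expect_identical(sum(mk$ring$data & (head_prob > 0.5)), 0L)
  zext <- head_extent_z(ph$maps)
  zs <- which(apply(mk$ring$data, 3, any))
  expect_true(min(zs) >= zext[1] + 0.6 * diff(zext) - 1)
  expect_true(max(zs) <= zext[2] - 5)
  expect_error(build_ring_mask(mk$bg, zext, lower_frac = 1),
               class = "t1qc_empty_slab_error")
})

test_that("estimated background agrees with phantom ground truth", {
  ph <- small_phantom(noise_sd = 0)
  est <- estimate_background_map(ph$volume)
  truth <- ph$maps$background >= 0.5
  agreement <- mean((est$data >= 0.5) == truth)
  expect_gte(agreement, 0.99)
  expect_error(estimate_background_map(array(3, dim = c(8, 8, 8))),
               class = "t1qc_constant_volume_error")
})
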