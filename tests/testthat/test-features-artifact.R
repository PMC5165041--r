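test_that("noise vector takes the median of non-zero in-mask voxels", {
  d <- c(6, 8, 4)
  vol <- array(0, dim = d)
  mask <- binary_mask(array(TRUE, dim = d), "eye")
  nv0 <- noise_vector(vol, mask, 2)
  expect_identical(nv0$values, rep(0, 6))

  vol[2, 1:3, 2] <- c(2, 4, 6)
  vol[3, 1:2, 2] <- c(2, 4)
  nv <- noise_vector(vol, mask, 2)
  expect_identical(nv$values[2], 4)        # odd count: middle value
  expect_identical(nv$values[3], 3)        # even count: midpoint
  expect_identical(nv$values[1], 0)        # empty column -> 0

  # zeros and out-of-mask voxels are excluded
  m2 <- array(TRUE, dim = d); m2[2, 3, 2] <- FALSE
  nv2 <- noise_vector(vol, binary_mask(m2, "eye"), 2)
  expect_identical(nv2$values[2], 3)       # {2, 4} left
  expect_error(noise_vector(vol, mask, 9),
               class = "t1qc_index_range_error")
})

test_that("noise-vector difference has the documented step response", {
  expect_identical(noise_vector_difference(rep(5, 50), 20), rep(0, 30))
  step <- c(rep(0, 30), rep(7, 34))        # length 64, step height 7
  nvd <- noise_vector_difference(step, 20)
  expect_length(nvd, 44)
  expect_identical(sum(nvd > 0), 20L)
  expect_true(all(nvd[nvd > 0] == 7 / 20))
  expect_length(noise_vector_difference(numeric(124), 20), 104)
  expect_error(noise_vector_difference(numeric(20), 20),
               class = "t1qc_window_error")
})

test_that("ASF1 of a constant in-mask ghost is k * g", {
  d <- c(40, 48, 48)
  vol <- array(0, dim = d)
  m <- array(FALSE, dim = d)
  m[10:19, 5:10, 7] <- TRUE                # k = 10 sagittal columns
  m[25, 30, 30] <- TRUE                    # second, empty slice: skipped
  vol[10:19, 5:10, 7] <- 3
  eye <- binary_mask(m, "eye")
  expect_identical(asf1_eye(vol, eye), 10 * 3)
  expect_error(asf1_eye(vol, binary_mask(array(FALSE, dim = d), "eye")),
               class = "t1qc_empty_mask_error")
})

test_that("ASF2 of a single-slice step is exactly the step height", {
  d <- c(40, 48, 48)
  vol <- array(0, dim = d)
  m <- array(FALSE, dim = d)
  m[, 3:8, 9] <- TRUE
  vol[21:40, 3:8, 9] <- 5                  # step of height 5 along x
  ring <- binary_mask(m, "ring")
  expect_identical(asf2_ring(vol, ring, window = 20), 5)
  expect_error(asf2_ring(array(0, dim = c(10, 5, 5)),
                         binary_mask(array(TRUE, dim = c(10, 5, 5)),
                                     "ring"), window = 20),
               class = "t1qc_window_error")
})

test_that("ASF3 of a full-width slab is k * u and 0 given any empty plane", {
  d <- c(40, 48, 48)
  vol <- array(0, dim = d)
  vol[6:35, , 11:14] <- 2                  # k = 4 axial planes, u = 2
  expect_identical(asf3_alias(vol), 4 * 2)
  # an empty coronal plane in every band slice floors the minimum
  vol2 <- vol; vol2[, 25, ] <- 0
  expect_identical(asf3_alias(vol2), 0)
  expect_error(asf3_alias(vol, midline = 5, half_width = 15),
               class = "t1qc_index_range_error")
})

test_that("each ASF tracks its own injected artifact monotonically", {
  ph <- small_phantom(noise_sd = 0)
  mk <- phantom_masks(ph)
  expect_identical(asf1_eye(ph$volume, mk$eye), 0)
  expect_identical(asf2_ring(ph$volume, mk$ring), 0)
  expect_identical(asf3_alias(ph$volume), 0)
  a1 <- vapply(c(0.3, 0.9), function(a)
    asf1_eye(inject_eye_movement(ph$volume, ph$maps, a, seed = 6), mk$eye),
    numeric(1))
  expect_true(a1[1] > 0 && a1[2] > a1[1])
  a2 <- vapply(c(0.3, 0.9), function(a)
    asf2_ring(inject_ringing(ph$volume, ph$maps, a, seed = 6), mk$ring),
    numeric(1))
  expect_true(a2[1] > 0 && a2[2] > a2[1])
  a3 <- vapply(c(0.3, 0.9), function(a)
    asf3_alias(inject_aliasing(ph$volume, a, overlay = TRUE)),
    numeric(1))
  expect_true(a3[1] > 0 && a3[2] > a3[1])
  # the gap scenario scores below the overlay scenario at equal amplitude
  gap <- asf3_alias(inject_aliasing(ph$volume, 0.5, overlay = FALSE))
  ovl <- asf3_alias(inject_aliasing(ph$volume, 0.5, overlay = TRUE))
  expect_lt(gap, ovl)
})
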