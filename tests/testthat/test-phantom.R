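test_that("ground-truth maps are a partition of unity and WM is exact", {
  ph <- small_phantom(noise_sd = 0)
  psum <- Reduce(`+`, lapply(unclass(ph$maps), identity))
  expect_lt(max(abs(psum - 1)), 1e-6)
  spec <- phantom_spec(shape = small_shape, noise_sd = 0)
  wm_core <- ph$maps$wm >= 0.5
  expect_true(any(wm_core))
  expect_true(all(ph$volume$data[wm_core] == spec$intensities["wm"]))
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_head_phantom(phantom_spec(shape = small_shape, seed = 9))
  b <- generate_head_phantom(phantom_spec(shape = small_shape, seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$maps$gm, b$maps$gm)
  c <- generate_head_phantom(phantom_spec(shape = small_shape, seed = 10))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("too-small grids are rejected", {
  expect_error(generate_head_phantom(phantom_spec(shape = c(16, 48, 48))),
               class = "t1qc_phantom_shape_error")
})

test_that("all injectors are the identity at zero amplitude", {
  ph <- small_phantom(noise_sd = 0)
  expect_identical(inject_eye_movement(ph$volume, ph$maps, 0)$data,
                   ph$volume$data)
  expect_identical(inject_ringing(ph$volume, ph$maps, 0)$data,
                   ph$volume$data)
  expect_identical(inject_aliasing(ph$volume, 0)$data, ph$volume$data)
})

test_that("eye-movement ghosts land anterior of the eyes and grow with amp", {
  ph <- small_phantom(noise_sd = 0)
  g <- t1qc:::phantom_geometry(small_shape)
  bg <- ph$maps$background >= 0.5
  anterior <- array(FALSE, dim = small_shape)
  xs <- round(g$eye_x[1] - g$eye_r):round(g$eye_x[1] + g$eye_r)
  zs <- round(g$eye_z - g$eye_r):round(g$eye_z + g$eye_r)
  anterior[xs, 1:floor(g$eye_y - g$eye_r - 1), zs] <- TRUE
  region <- anterior & bg
  expect_true(any(region))
  v5 <- inject_eye_movement(ph$volume, ph$maps, 0.5, seed = 3)
  expect_gt(sum(v5$data[region] > 0), 0)
  v2 <- inject_eye_movement(ph$volume, ph$maps, 0.2, seed = 3)
  v8 <- inject_eye_movement(ph$volume, ph$maps, 0.8, seed = 3)
  expect_gt(mean(v8$data[region]), mean(v2$data[region]))
})

test_that("ringing ghosts land lateral to the upper skull and grow with amp", {
  ph <- small_phantom(noise_sd = 0)
  bg <- ph$maps$background >= 0.5
  v5 <- inject_ringing(ph$volume, ph$maps, 0.5, seed = 3)
  added <- (v5$data - ph$volume$data) > 0
  expect_gt(sum(added & bg), 0)
  zext <- head_extent_z(ph$maps)
  z_added <- which(apply(added, 3, any))
  expect_true(all(z_added >= zext[1] + (2 / 3) * diff(zext) - 1))
  v2 <- inject_ringing(ph$volume, ph$maps, 0.2, seed = 3)
  v8 <- inject_ringing(ph$volume, ph$maps, 0.8, seed = 3)
  expect_gt(sum(v8$data - ph$volume$data), sum(v2$data - ph$volume$data))
})

test_that("aliasing leaves a background gap without overlay and none with", {
  ph <- small_phantom(noise_sd = 0)
  g <- t1qc:::phantom_geometry(small_shape)
  xm <- round(small_shape[1] / 2)
  empty_planes <- function(vol) {
    sl <- vol$data[xm, , ]
    which(apply(sl, 1, max) == 0)
  }
  ny <- small_shape[2]
  gap <- inject_aliasing(ph$volume, 0.5, overlay = FALSE)
  posterior <- (round(g$head_y[2]) + 1):ny
  expect_gt(length(intersect(empty_planes(gap), posterior)), 0)
  ovl <- inject_aliasing(ph$volume, 0.5, overlay = TRUE)
  expect_length(empty_planes(ovl), 0)
})

test_that("cohorts honour the usable fraction and are reproducible", {
  co <- generate_cohort(10, 0.5, seed = 5, shape = small_shape)
  finals <- vapply(co, function(s) s$label$final, character(1))
  expect_identical(sum(finals == "usable"), 5L)
  # usable subjects stay below the high-amplitude cutoff on every artifact;
  # not-usable subjects cross it on at least one
  for (s in co) {
    if (s$label$final == "usable") {
      expect_true(all(s$amplitudes < 0.45))
      expect_true(all(s$label$severity != "heavy"))
    } else {
      expect_true(any(s$amplitudes >= 0.55))
    }
  }
  co2 <- generate_cohort(10, 0.5, seed = 5, shape = small_shape)
  expect_identical(co[[3]]$volume$data, co2[[3]]$volume$data)
  expect_identical(vapply(co2, function(s) s$label$final, character(1)),
                   finals)
  expect_error(generate_cohort(10, 1.2, seed = 1),
               class = "t1qc_cohort_error")
})

test_that("amplitude severity cutpoints are ordered and fixed", {
  expect_identical(t1qc:::amp_to_severity(c(0, 0.09, 0.1, 0.34, 0.35,
                                            0.64, 0.65, 1)),
                   c("none", "none", "slight", "slight", "moderate",
                     "moderate", "heavy", "heavy"))
})
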