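# Shared fixtures. Phantoms and masks are cached per (shape, noise, seed)
# so independent tests can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

small_shape <- c(40L, 48L, 48L)

small_phantom <- function(noise_sd = 0, seed = 1, shape = small_shape) {
  key <- paste("ph", paste(shape, collapse = "x"), noise_sd, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_head_phantom(
      phantom_spec(shape = shape, noise_sd = noise_sd, seed = seed))
  .fixture_cache[[key]]
}

phantom_masks <- function(ph) {
  key <- paste("mk", paste(dim(ph$volume), collapse = "x"),
               substr(digest_arr(ph$maps$background), 1, 8))
  if (is.null(.fixture_cache[[key]])) {
    t0 <- ph$transform
    bg <- background_mask(normalize_map(ph$maps$background, t0), t0)
    eye <- build_eye_mask(bg, default_eye_boxes(dim(ph$volume)), t0)
    ring <- build_ring_mask(bg, head_extent_z(ph$maps))
    .fixture_cache[[key]] <- list(bg = bg, eye = eye, ring = ring)
  }
  .fixture_cache[[key]]
}

digest_arr <- function(a) paste(format(sum(a), digits = 12),
                                format(sum(a * seq_along(a)), digits = 12))

# Independent brute-force oracle for the 100-bin histograms: per-voxel loop
# over explicit bin edges, first bin closed at zero.
brute_hist100 <- function(v, domain_max) {
  edges <- domain_max * (0:100) / 100
  counts <- integer(100)
  for (val in v) {
    for (n in 1:100) {
      in_bin <- (val > edges[n] && val <= edges[n + 1]) ||
        (n == 1L && val >= 0 && val <= edges[2])
      if (in_bin) { counts[n] <- counts[n] + 1L; break }
    }
  }
  counts
}

# Small separable two-blob feature set for classifier checks.
make_blobs <- function(n = 200, gap = 6, sd = 1, seed = 42) {
  stopifnot(n %% 2 == 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, 0, sd), ncol = 2),
             matrix(rnorm(n, gap, sd), ncol = 2))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(x = x,
       y = rep(c("usable", "not-usable"), each = n / 2))
}

# Two-block volume with Gaussian intensities per class and matching
# one-hot-style maps; used for contrast-score checks.
two_class_volume <- function(n_per_class = 1000, mu = c(gm = 2, wm = 3),
                             sd = 0.1, seed = 7) {
  set.seed(seed)
  d <- c(n_per_class, 2, 1)
  vol <- array(0, dim = d)
  vol[, 1, 1] <- rnorm(n_per_class, mu["gm"], sd)
  vol[, 2, 1] <- rnorm(n_per_class, mu["wm"], sd)
  vol <- pmax(vol, 1e-6)
  gm <- array(0, dim = d); gm[, 1, 1] <- 1
  wm <- array(0, dim = d); wm[, 2, 1] <- 1
  zero <- array(0, dim = d)
  list(vol = vol,
       maps = tissue_map_set(gm, wm, zero, zero, zero,
                             background = 1 - gm - wm))
}

# 6-neighbour box blur used to degrade phantom contrast.
box_blur3 <- function(a) {
  s <- function(dx = 0, dy = 0, dz = 0) {
    d <- dim(a); out <- array(0, d)
    sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
    fx <- pmin(pmax(sx - dx, 1), d[1]); fy <- pmin(pmax(sy - dy, 1), d[2])
    fz <- pmin(pmax(sz - dz, 1), d[3])
    a[fx, fy, fz]
  }
  (a + s(1) + s(-1) + s(0, 1) + s(0, -1) + s(0, 0, 1) + s(0, 0, -1)) / 7
}
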