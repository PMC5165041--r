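# Synthetic head phantoms. The phantom is an ellipsoidal head (skull and
# subcutaneous-fat shell, gray-matter shell, white-matter core, CSF
# ventricles) with two anterior eye globes and a nose running from the face
# to the anterior edge of the field of view, so that wrap-around aliasing
# has anatomy to fold. Ground-truth tissue probability maps and an identity
# transform pair accompany every phantom, giving downstream stages inputs
# with known labels. Artifact injectors add image-space ghost replicas at
# controlled amplitude; at amplitude zero every injector is the identity.

#' Phantom specification
#'
#' @param shape integer length-3 grid (each axis >= 32). The default echoes
#'   a 124-slice sagittal acquisition.
#' @param intensities named mean intensity per tissue class; the ordering
#'   background << CSF < GM < WM <= skull/fat is enforced (bright fat is
#'   what motion ghosts replicate).
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units); applied everywhere and clamped at zero.
#' @param soften mixing weight pulling the one-hot ground-truth tissue maps
#'   toward uniform, so probabilities are in (0, 1) rather than binary.
#' @param seed integer seed for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(124, 128, 128),
                         intensities = c(background = 0, csf = 40, gm = 70,
                                         wm = 100, skull = 110, fat = 120),
                         noise_sd = 2, soften = 0.05, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L)
    stop_t1qc("`shape` must have length 3", "phantom_spec")
  need <- c("background", "csf", "gm", "wm", "skull", "fat")
  if (!all(need %in% names(intensities)))
    stop_t1qc("intensities must name all six tissue classes", "phantom_spec")
  i <- intensities
  if (!(i["wm"] > i["gm"] && i["gm"] > i["csf"] && i["csf"] > i["background"]))
    stop_t1qc("need WM > GM > CSF > background mean intensity",
              "phantom_spec")
  if (noise_sd < 0) stop_t1qc("noise_sd must be >= 0", "phantom_spec")
  if (soften < 0 || soften >= 0.5)
    stop_t1qc("soften must be in [0, 0.5)", "phantom_spec")
  structure(list(shape = shape, intensities = i, noise_sd = noise_sd,
                 soften = soften, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic phantom geometry for a given grid shape. All injectors and
# the default eye boxes derive their coordinates from this single source.
phantom_geometry <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  a <- 0.36 * nx; b <- 0.30 * ny; cc <- 0.36 * nz
  re <- max(2, round(0.055 * min(shape)))
  ex <- c(cx - 0.22 * nx, cx + 0.22 * nx)
  ez <- cz - 0.06 * nz
  u <- 1 - ((ex[1] - cx) / a)^2 - ((ez - cz) / cc)^2
  y_surf_eye <- cy - b * sqrt(max(0, u))
  ey <- y_surf_eye - 0.9 * re
  nose_hw <- max(2, round(0.05 * nx))
  nose_z <- c(cz - 0.26 * nz, cz - 0.12 * nz)
  un <- 1 - ((mean(nose_z) - cz) / cc)^2
  nose_y_base <- cy - b * sqrt(max(0, un))
  list(center = c(cx, cy, cz), semi = c(a, b, cc),
       eye_x = ex, eye_y = ey, eye_z = ez, eye_r = re,
       nose_x = c(cx - nose_hw, cx + nose_hw),
       nose_y = c(1, nose_y_base), nose_z = nose_z,
       head_z = c(cz - cc, cz + cc), head_y = c(cy - b, cy + b))
}

# Squared normalized ellipsoid radius on the full grid.
.ellipsoid_r2 <- function(shape, center, semi) {
  ex2 <- ((seq_len(shape[1]) - center[1]) / semi[1])^2
  ey2 <- ((seq_len(shape[2]) - center[2]) / semi[2])^2
  ez2 <- ((seq_len(shape[3]) - center[3]) / semi[3])^2
  outer(outer(ex2, ey2, "+"), ez2, "+")
}

# Boolean sphere on the grid (isotropic, voxel units).
.sphere <- function(shape, center, r) {
  .ellipsoid_r2(shape, center, c(r, r, r)) <= 1
}

# Class index array: 1 gm, 2 wm, 3 csf, 4 skull, 5 fat, 6 background.
.phantom_classes <- function(shape) {
  g <- phantom_geometry(shape)
  r2 <- .ellipsoid_r2(shape, g$center, g$semi)
  cls <- array(6L, dim = shape)
  cls[r2 <= 1] <- 4L              # skull band (0.96, 1]
  cls[r2 <= 0.96^2] <- 5L         # fat band (0.92, 0.96]
  cls[r2 <= 0.92^2] <- 1L         # gm shell (0.80, 0.92]
  cls[r2 <= 0.80^2] <- 2L         # wm core
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  for (sgn in c(-1, 1)) {         # lateral ventricles
    vc <- c(g$center[1] + sgn * 0.08 * nx, g$center[2],
            g$center[3] + 0.05 * nz)
    vent <- .ellipsoid_r2(shape, vc, c(0.05 * nx, 0.10 * ny, 0.08 * nz)) <= 1
    cls[vent & cls == 2L] <- 3L
  }
  for (i in 1:2) {                # eye globes, anterior of the head shell
    eye <- .sphere(shape, c(g$eye_x[i], g$eye_y, g$eye_z), g$eye_r)
    cls[eye & cls == 6L] <- 5L
  }
  xs <- max(1, round(g$nose_x[1])):min(nx, round(g$nose_x[2]))
  ys <- 1:max(1, round(g$nose_y[2]))
  zs <- max(1, round(g$nose_z[1])):min(nz, round(g$nose_z[2]))
  sub <- cls[xs, ys, zs, drop = FALSE]
  sub[sub == 6L] <- 5L            # nose: fat-bright wedge out to the FOV edge
  cls[xs, ys, zs] <- sub
  cls
}

#' Generate a head phantom with ground-truth tissue maps
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([volume_grid()]), `maps`
#'   ([tissue_map_set()], a softened partition of unity), and `transform`
#'   (an identity [transform_pair()]; phantoms are born in normalized
#'   space).
#' @export
#' @examples
#' ph <- generate_head_phantom(phantom_spec(shape = c(40, 48, 48),
#'                                          noise_sd = 0))
#' range(ph$volume$data)
generate_head_phantom <- function(spec = phantom_spec()) {
  shape <- spec$shape
  if (any(shape < 32L))
    stop_t1qc("shape too small to contain the head model (min 32 per axis)",
              "phantom_shape")
  cls <- .phantom_classes(shape)
  class_names <- c("gm", "wm", "csf", "skull", "fat", "background")
  lut <- spec$intensities[class_names]
  vol <- array(as.numeric(lut[cls]), dim = shape)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       array(stats::rnorm(prod(shape), 0, spec$noise_sd),
                             dim = shape))
    vol <- pmax(vol + noise, 0)
  }
  s <- spec$soften
  maps <- lapply(seq_along(class_names), function(k) {
    (1 - s) * (cls == k) + s / 6
  })
  names(maps) <- class_names
  list(volume = volume_grid(vol),
       maps = do.call(tissue_map_set, maps),
       transform = identity_transform(shape))
}

#' Default eye-socket boxes for the phantom geometry
#'
#' Bounding boxes (normalized-space voxel index ranges) around the two eye
#' globes. For scanner data the boxes must be estimated once per template
#' and supplied through the configuration; these defaults only match the
#' phantom geometry.
#'
#' @param shape integer length-3 normalized grid dimensions.
#' @param margin voxels of padding around each globe.
#' @return An object of class `eye_box_spec`: a list with `left` and
#'   `right`, each holding integer `x`, `y`, `z` ranges.
#' @export
default_eye_boxes <- function(shape, margin = 2) {
  g <- phantom_geometry(shape)
  box <- function(i) {
    list(x = c(max(1, floor(g$eye_x[i] - g$eye_r - margin)),
               min(shape[1], ceiling(g$eye_x[i] + g$eye_r + margin))),
         y = c(max(1, floor(g$eye_y - g$eye_r)),
               min(shape[2], ceiling(g$eye_y + g$eye_r))),
         z = c(max(1, floor(g$eye_z - g$eye_r - margin)),
               min(shape[3], ceiling(g$eye_z + g$eye_r + margin))))
  }
  structure(list(left = box(1), right = box(2)), class = "eye_box_spec")
}

.check_amp <- function(amp) {
  if (!is.numeric(amp) || length(amp) != 1L || amp < 0 || amp > 1)
    stop_t1qc("artifact amplitude must be a scalar in [0, 1]", "amplitude")
}

#' Inject eye-movement ghosting
#'
#' Adds attenuated replicas of the eye-globe signal, shifted anteriorly
#' along the coronal (phase-encode) axis so that ghost energy lands in the
#' background directly in front of the eyes. Total injected energy is
#' proportional to `amp`; `amp = 0` returns the input unchanged.
#'
#' @param vol phantom volume ([volume_grid()] or array).
#' @param maps the phantom's [tissue_map_set()] (fixes the grid; eye
#'   locations derive from the phantom geometry).
#' @param amp ghost amplitude in \[0, 1\].
#' @param seed integer; seeds the per-replica attenuation jitter.
#' @return A [volume_grid()].
#' @export
inject_eye_movement <- function(vol, maps, amp, seed = 1) {
  .check_amp(amp)
  vol <- as_volume_grid(vol)
  if (amp == 0) return(vol)
  shape <- dim(vol)
  g <- phantom_geometry(shape)
  eyes <- .sphere(shape, c(g$eye_x[1], g$eye_y, g$eye_z), g$eye_r) |
    .sphere(shape, c(g$eye_x[2], g$eye_y, g$eye_z), g$eye_r)
  src <- vol$data * eyes
  dy <- max(2, round(0.08 * shape[2]))
  k_max <- 4L
  jitter <- with_seed(seed, stats::runif(k_max, 0.8, 1.2))
  add <- array(0, dim = shape)
  for (k in seq_len(k_max)) {
    add <- add + shift3d(src, dy = -k * dy) * (amp * 0.5 * 0.6^(k - 1) *
                                                 jitter[k])
  }
  volume_grid(vol$data + add, voxel_size = vol$voxel_size)
}

#' Inject motion ringing from the bright fat of the skull
#'
#' Adds laterally shifted, attenuated replicas of the bright skull/fat rim
#' in the upper third of the head, placing wave-like ghost energy in the
#' background surrounding the upper axial slices.
#'
#' @inheritParams inject_eye_movement
#' @return A [volume_grid()].
#' @export
inject_ringing <- function(vol, maps, amp, seed = 1) {
  .check_amp(amp)
  vol <- as_volume_grid(vol)
  if (amp == 0) return(vol)
  shape <- dim(vol)
  g <- phantom_geometry(shape)
  r2 <- .ellipsoid_r2(shape, g$center, g$semi)
  zlow <- g$head_z[1] + (2 / 3) * diff(g$head_z)
  zmask <- array(rep(seq_len(shape[3]) >= zlow, each = shape[1] * shape[2]),
                 dim = shape)
  rim <- (r2 > 0.92^2) & (r2 <= 1) & zmask
  src <- vol$data * rim
  dx <- max(2, round(0.09 * shape[1]))
  k_max <- 3L
  jitter <- with_seed(seed, stats::runif(k_max, 0.8, 1.2))
  add <- array(0, dim = shape)
  for (k in seq_len(k_max)) {
    att <- amp * 0.4 * 0.6^(k - 1) * jitter[k]
    add <- add + (shift3d(src, dx = k * dx) + shift3d(src, dx = -k * dx)) * att
  }
  volume_grid(vol$data + add, voxel_size = vol$voxel_size)
}

#' Inject wrap-around aliasing of the nose
#'
#' Simulates a coronal field of view smaller than the head: the
#' anterior-most `ceiling(amp * ny * 0.2)` coronal planes (which contain
#' the nose) fold back over the posterior edge of the grid, scaled by
#' `amp` so total injected energy grows with amplitude. With
#' `overlay = FALSE` the folded nose stays clear of the head, leaving a
#' pure-background gap; with `overlay = TRUE` the wrap is shifted so the
#' folded planes tile the posterior of the grid and the nose signal lands
#' on the back of the head, removing every clear air plane behind it.
#'
#' @param vol phantom volume ([volume_grid()] or array); must contain the
#'   phantom nose.
#' @param amp wrap amplitude in \[0, 1\]; 0 is the identity.
#' @param overlay logical; see above.
#' @return A [volume_grid()].
#' @export
inject_aliasing <- function(vol, amp, overlay = FALSE) {
  .check_amp(amp)
  vol <- as_volume_grid(vol)
  if (amp == 0) return(vol)
  shape <- dim(vol)
  ny <- shape[2]
  k <- ceiling(amp * ny * 0.2)
  g <- phantom_geometry(shape)
  # fold only the nose's axial band: the wrapped anatomy, not the whole
  # noise field, replicates
  zs <- max(1, floor(g$nose_z[1])):min(shape[3], ceiling(g$nose_z[2]))
  src <- vol$data[, seq_len(k), zs, drop = FALSE]
  out <- vol$data
  if (!overlay) {
    dest <- (ny - k + 1):ny
    out[, dest, zs] <- out[, dest, zs] + amp * src
  } else {
    y0 <- max(1, round(g$head_y[2]) - max(1L, floor(k / 2)))
    dest <- y0:ny
    src_idx <- ((dest - y0) %% k) + 1L
    out[, dest, zs] <- out[, dest, zs] + amp * src[, src_idx, , drop = FALSE]
  }
  volume_grid(out, voxel_size = vol$voxel_size)
}

# Severity grade for a synthetic artifact amplitude. Fixed cutpoints; only
# the ordering matters downstream.
amp_to_severity <- function(amp) {
  ifelse(amp < 0.1, "none",
         ifelse(amp < 0.35, "slight",
                ifelse(amp < 0.65, "moderate", "heavy")))
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject artifact amplitudes, injects eye-movement ghosting,
#' ringing and aliasing accordingly, and assigns a [quality_label()] whose
#' per-artifact severity follows the fixed amplitude cutpoints none < 0.1
#' <= slight < 0.35 <= moderate < 0.65 <= heavy. Usable subjects draw all
#' three amplitudes below the low cutoff 0.45 (so, as with visually
#' accepted borderline scans, they may carry slight-to-moderate
#' artifacts); not-usable subjects have one or two amplitudes above the
#' high cutoff 0.55 and the rest below 0.45.
#'
#' Per-subject tissue contrast (CSF, GM and WM mean intensities) and
#' tissue-map softness are jittered within physiological-looking ranges so
#' that, as in scanner cohorts, global histogram features vary between
#' subjects for reasons unrelated to artifact load.
#'
#' @param n number of subjects (>= 2).
#' @param usable_fraction fraction of usable subjects in (0, 1); the usable
#'   count is `round(n * usable_fraction)`.
#' @param seed integer master seed; the whole cohort is reproducible.
#' @param shape phantom grid per subject.
#' @param noise_sd Gaussian noise level passed to [phantom_spec()].
#' @return A list of subject records, each a list with `volume`, `maps`,
#'   `transform`, `label` and the drawn `amplitudes`.
#' @export
generate_cohort <- function(n, usable_fraction = 0.5, seed = 1,
                            shape = c(48, 56, 56), noise_sd = 2) {
  if (n < 2) stop_t1qc("cohort size must be >= 2", "cohort")
  if (usable_fraction <= 0 || usable_fraction >= 1)
    stop_t1qc("usable_fraction must lie strictly inside (0, 1)", "cohort")
  n_usable <- round(n * usable_fraction)
  usable <- c(rep(TRUE, n_usable), rep(FALSE, n - n_usable))
  draws <- with_seed(seed, {
    amps <- t(vapply(usable, function(u) {
      if (u) stats::runif(3, 0, 0.45)
      else {
        a <- stats::runif(3, 0, 0.45)
        high <- sample.int(3, sample(1:2, 1))
        a[high] <- stats::runif(length(high), 0.55, 1)
        a
      }
    }, numeric(3)))
    list(amps = amps,
         csf = stats::runif(n, 35, 45),
         gm = stats::runif(n, 62, 78),
         wm = stats::runif(n, 92, 108),
         soften = stats::runif(n, 0.02, 0.08))
  })
  amps <- draws$amps
  colnames(amps) <- c("eye", "ring", "alias")
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(shape = shape,
                       intensities = c(background = 0, csf = draws$csf[i],
                                       gm = draws$gm[i], wm = draws$wm[i],
                                       skull = 110, fat = 120),
                       noise_sd = noise_sd, soften = draws$soften[i],
                       seed = child_seed(seed, 1000 + i))
    ph <- generate_head_phantom(sp)
    vol <- inject_eye_movement(ph$volume, ph$maps, amps[i, "eye"],
                               seed = child_seed(seed, 2000 + i))
    vol <- inject_ringing(vol, ph$maps, amps[i, "ring"],
                          seed = child_seed(seed, 3000 + i))
    vol <- inject_aliasing(vol, amps[i, "alias"], overlay = TRUE)
    sev <- amp_to_severity(amps[i, ])
    names(sev) <- c("eye_movement", "ringing", "aliasing")
    color <- if (all(sev == "none")) "green"
             else if (any(sev == "heavy")) "red" else "yellow"
    final <- if (usable[i]) "usable" else "not-usable"
    if (color == "yellow" && final == "not-usable") color <- "red"
    list(volume = vol, maps = ph$maps, transform = ph$transform,
         label = quality_label(sprintf("sub%03d", i), color, sev, final),
         amplitudes = amps[i, ])
  })
}
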