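# Artifact-specific features. Each feature reads artifact energy out of a
# dedicated background region: ASF1 sums ghost signal in front of the eyes,
# ASF2 differentiates the background noise profile near the top of the
# head, and ASF3 measures whether wrapped facial anatomy bridges the air
# gap behind the head.

#' Per-slice noise vector
#'
#' For a fixed axial slice, the median of the non-zero in-mask voxel
#' intensities of each coronal column, giving a stable 1D noise profile
#' along the sagittal axis. Columns with no non-zero in-mask voxel yield 0
#' (the no-noise neutral element); an even count of values yields the
#' midpoint of the two central values.
#'
#' @param vol [volume_grid()] or 3D array.
#' @param mask an eye or ring [binary_mask()].
#' @param z0 axial slice index.
#' @return An object of class `noise_vector`: list with `values` (length
#'   nx) and `slice_index`.
#' @export
noise_vector <- function(vol, mask, z0) {
  v <- vg_data(vol)
  d <- dim(v)
  if (!mask$kind %in% c("eye", "ring"))
    stop_t1qc("noise vectors are defined for eye or ring masks", "mask")
  if (z0 < 1 || z0 > d[3])
    stop_t1qc(sprintf("axial index z0 = %d out of range [1, %d]", z0, d[3]),
              "index_range")
  structure(list(values = .nv_slice(v[, , z0], mask$data[, , z0]),
                 slice_index = z0),
            class = "noise_vector")
}

# Median of non-zero in-mask values per sagittal column of one slice.
.nv_slice <- function(slice_v, slice_m) {
  vapply(seq_len(nrow(slice_v)), function(x) {
    vals <- slice_v[x, slice_m[x, ] & slice_v[x, ] > 0]
    if (length(vals)) stats::median(vals) else 0
  }, numeric(1))
}

#' Eye-movement feature (ASF1)
#'
#' For every axial slice intersecting the eye-mask, sums the noise vector
#' over the sagittal axis; ASF1 is the maximum of those sums over slices.
#' Zero on a noise-free, artifact-free volume.
#'
#' @param vol [volume_grid()] or 3D array.
#' @param eye_mask an eye [binary_mask()], non-empty.
#' @return Non-negative scalar.
#' @export
asf1_eye <- function(vol, eye_mask) {
  v <- vg_data(vol)
  if (eye_mask$kind != "eye") stop_t1qc("mask kind must be 'eye'", "mask")
  zs <- which(apply(eye_mask$data, 3, any))
  if (!length(zs)) stop_t1qc("empty eye-mask", "empty_mask")
  max(vapply(zs, function(z)
    sum(.nv_slice(v[, , z], eye_mask$data[, , z])), numeric(1)))
}

#' Windowed noise-vector difference
#'
#' `|nv[x + window] - nv[x]| / window` for every sagittal position where
#' the window fits; the output is shorter than the input by `window`.
#' Sensitive to wave-like structure in the background profile and blind to
#' a flat noise floor.
#'
#' @param nv a [noise_vector()] or numeric vector.
#' @param window sagittal offset in voxels (default 20).
#' @return Non-negative numeric vector of length `length(nv) - window`.
#' @export
noise_vector_difference <- function(nv, window = 20) {
  x <- if (inherits(nv, "noise_vector")) nv$values else nv
  n <- length(x)
  if (n <= window)
    stop_t1qc(sprintf("noise vector length %d must exceed window %d",
                      n, window), "window")
  abs(x[(window + 1):n] - x[1:(n - window)]) / window
}

#' Ringing feature (ASF2)
#'
#' For every axial slice intersecting the ring-mask, sums the windowed
#' noise-vector difference over the sagittal axis; ASF2 is the maximum of
#' those sums over slices.
#'
#' @param vol [volume_grid()] or 3D array.
#' @param ring_mask a ring [binary_mask()], non-empty.
#' @param window sagittal differencing window (default 20).
#' @return Non-negative scalar.
#' @export
asf2_ring <- function(vol, ring_mask, window = 20) {
  v <- vg_data(vol)
  if (ring_mask$kind != "ring") stop_t1qc("mask kind must be 'ring'", "mask")
  if (dim(v)[1] <= window)
    stop_t1qc("sagittal extent must exceed the differencing window",
              "window")
  zs <- which(apply(ring_mask$data, 3, any))
  if (!length(zs)) stop_t1qc("empty ring-mask", "empty_mask")
  max(vapply(zs, function(z) {
    nv <- .nv_slice(v[, , z], ring_mask$data[, , z])
    sum(noise_vector_difference(nv, window))
  }, numeric(1)))
}

#' Aliasing feature (ASF3)
#'
#' For each sagittal slice in a band centered on the midline, sums the
#' volume along the axial axis into a raw vector over the coronal axis,
#' takes that vector's minimum over the full coronal range, and returns
#' the maximum of those minima over the band. A clear air plane anywhere
#' along y keeps the value near the background level; wrapped facial
#' anatomy overlaid on the back of the head removes every such plane and
#' raises the value toward tissue intensity.
#'
#' @param vol [volume_grid()] or 3D array.
#' @param midline sagittal index of the band center, or `"auto"` for
#'   `round(nx / 2)`.
#' @param half_width half the band width; `2 * half_width` slices are
#'   scanned (default 15, i.e. 30 slices).
#' @return Non-negative scalar.
#' @export
asf3_alias <- function(vol, midline = "auto", half_width = 15) {
  v <- vg_data(vol)
  nx <- dim(v)[1]
  m <- if (identical(midline, "auto")) round(nx / 2) else as.integer(midline)
  xs <- (m - half_width + 1):(m + half_width)
  if (xs[1] < 1 || xs[length(xs)] > nx)
    stop_t1qc(sprintf("sagittal band [%d, %d] exceeds the volume (nx = %d)",
                      xs[1], xs[length(xs)], nx), "index_range")
  max(vapply(xs, function(x1) min(rowSums(v[x1, , ])), numeric(1)))
}
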