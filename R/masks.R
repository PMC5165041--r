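# Background, eye and ring masks. The background-mask marks air voxels
# entirely outside the head; the eye-mask restricts it to the region
# directly in front of the eyes (where eye-movement ghosts land) and the
# ring-mask to a slab around the top of the head (where motion ringing of
# the bright skull fat lands), bounded below to avoid eye-movement
# interference and above to avoid axial aliasing.

#' Binary mask on a volume grid
#'
#' @param data 3D logical array.
#' @param kind one of `"background"`, `"eye"`, `"ring"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, kind = c("background", "eye", "ring")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop_t1qc("mask data must be a 3D logical array", "mask")
  structure(list(data = data, kind = kind), class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> kind = %s, %d of %d voxels set\n",
              x$kind, sum(x$data), length(x$data)))
  invisible(x)
}

#' Write a binary mask as a 0/1 NIfTI volume
#' @param mask a [binary_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  write_volume(volume_grid(array(as.numeric(mask$data), dim = dim(mask))),
               path)
}

#' Spatially normalize a probability map
#'
#' Resamples a native-space map onto the normalized grid through the
#' forward transform, with trilinear interpolation (values stay in
#' \[0, 1\]). The identity transform short-circuits to a copy.
#'
#' @param map [volume_grid()] or 3D array with values in \[0, 1\].
#' @param t a [transform_pair()].
#' @return 3D array on the normalized grid.
#' @export
normalize_map <- function(map, t) {
  m <- vg_data(map)
  if (any(m < 0) || any(m > 1))
    stop_t1qc("probability map values must lie in [0, 1]", "map_range")
  if (is_identity_transform(t)) return(m)
  out <- resample_affine(m, t$inverse, t$target_shape, mode = "linear")
  pmin(pmax(out, 0), 1)
}

#' Average normalized background maps across subjects
#'
#' Voxelwise arithmetic mean of the spatially normalized per-subject
#' background maps, yielding the group background region of interest.
#'
#' @param normalized_maps list of 3D arrays (or `volume_grid`s) on a common
#'   normalized grid.
#' @return 3D array of the voxelwise mean.
#' @export
average_background <- function(normalized_maps) {
  if (length(normalized_maps) < 1L)
    stop_t1qc("need at least one normalized map", "empty_input")
  ms <- lapply(normalized_maps, vg_data)
  d <- dim(ms[[1]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), logical(1))))
    stop_t1qc("normalized maps must share a common shape", "map_shape")
  Reduce(`+`, ms) / length(ms)
}

#' Build the subject background-mask
#'
#' Transforms the group-average background map back to the subject's native
#' space through the inverse transform and thresholds it. The comparison is
#' closed (`>= threshold`) so the boundary case is deterministic.
#'
#' @param avg 3D array on the normalized grid (group background average).
#' @param t the subject's [transform_pair()].
#' @param threshold probability cutoff, default 0.5.
#' @return A [binary_mask()] of kind `"background"`.
#' @export
background_mask <- function(avg, t, threshold = 0.5) {
  avg <- vg_data(avg)
  native <- if (is_identity_transform(t)) avg
            else resample_affine(avg, t$forward, t$native_shape,
                                 mode = "linear")
  binary_mask(native >= threshold, kind = "background")
}

# 6-neighborhood binary dilation / erosion on 3D logical arrays.
.dilate6 <- function(m) {
  s <- function(...) shift3d(m, ...) > 0
  m | s(dx = 1) | s(dx = -1) | s(dy = 1) | s(dy = -1) | s(dz = 1) |
    s(dz = -1)
}
.erode6 <- function(m) !.dilate6(!m)

#' Estimate a background map from intensities alone
#'
#' Morphological fallback for volumes without segmentation: Otsu threshold
#' on the intensity histogram, one binary closing step to seal the head
#' surface, then a border-connected flood fill so interior cavities (e.g.
#' ventricles) stay part of the head. The complement of the filled head is
#' returned as a 0/1 pseudo-probability map.
#'
#' Only valid for the usual T1 contrast (head brighter than air); inverted
#' contrast triggers a warning and an unspecified result.
#'
#' @param vol [volume_grid()] or 3D array.
#' @return A [volume_grid()] with values in \{0, 1\}.
#' @export
estimate_background_map <- function(vol) {
  v <- vg_data(vol)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop_t1qc("cannot estimate background of an all-constant volume",
              "constant_volume")
  v01 <- (v - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(matrix(v01, nrow = dim(v)[1])),
                      range = c(0, 1))
  head <- array(v01 > th, dim = dim(v))
  if (mean(head) > 0.5)
    warning("more than half of the volume is above the Otsu threshold; ",
            "contrast may be inverted and the background estimate invalid")
  head <- .erode6(.dilate6(head))            # closing
  air <- !head
  d <- dim(v)
  reach <- array(FALSE, dim = d)             # flood from the grid border
  reach[c(1, d[1]), , ] <- air[c(1, d[1]), , ]
  reach[, c(1, d[2]), ] <- reach[, c(1, d[2]), ] | air[, c(1, d[2]), ]
  reach[, , c(1, d[3])] <- reach[, , c(1, d[3])] | air[, , c(1, d[3])]
  repeat {
    grown <- .dilate6(reach) & air
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  volume_grid(array(as.numeric(reach), dim = d))
}

#' Eye-socket box specification
#'
#' Normalized-space bounding boxes for the two eye sockets. See
#' [default_eye_boxes()] for boxes matching the phantom geometry; boxes
#' for scanner data are estimated manually on the template once and passed
#' through the configuration.
#'
#' @param left,right lists with integer `x`, `y`, `z` ranges (length-2).
#' @return An object of class `eye_box_spec`.
#' @export
eye_box_spec <- function(left, right) {
  chk <- function(b) {
    stopifnot(is.list(b), all(c("x", "y", "z") %in% names(b)))
    for (ax in c("x", "y", "z"))
      if (length(b[[ax]]) != 2L || b[[ax]][1] > b[[ax]][2])
        stop_t1qc("eye box ranges must be non-empty length-2", "eye_box")
    b
  }
  structure(list(left = chk(left), right = chk(right)),
            class = "eye_box_spec")
}

# Warp a box through an affine by transforming its 8 corners and taking
# the integer bounding box, clipped to `shape`. Returns NULL if the box
# falls entirely outside the grid.
.warp_box <- function(box, affine, shape) {
  corners <- as.matrix(expand.grid(box$x, box$y, box$z))
  w <- cbind(corners, 1) %*% t(affine)
  lo <- floor(apply(w[, 1:3, drop = FALSE], 2, min))
  hi <- ceiling(apply(w[, 1:3, drop = FALSE], 2, max))
  lo2 <- pmax(lo, 1); hi2 <- pmin(hi, shape)
  if (any(lo2 > hi2)) return(NULL)
  list(x = c(lo2[1], hi2[1]), y = c(lo2[2], hi2[2]), z = c(lo2[3], hi2[3]))
}

#' Build the eye-mask
#'
#' Warps the normalized-space eye boxes to native space, takes the (x, z)
#' footprint of their union, extends it along the coronal axis but only
#' anterior to the first head voxel in each column, and intersects with
#' the background-mask. The result is background air directly in front of
#' the eyes, where eye-movement ghosts accumulate.
#'
#' @param bg a background [binary_mask()].
#' @param boxes an [eye_box_spec()].
#' @param t the subject's [transform_pair()].
#' @return A [binary_mask()] of kind `"eye"`.
#' @export
build_eye_mask <- function(bg, boxes, t) {
  if (bg$kind != "background")
    stop_t1qc("`bg` must be a background-mask", "mask")
  shape <- dim(bg)
  wb <- Filter(Negate(is.null),
               lapply(boxes[c("left", "right")], .warp_box,
                      affine = t$inverse, shape = shape))
  if (!length(wb))
    stop_t1qc("eye boxes warp entirely outside the native grid", "eye_box")
  head <- !bg$data
  out <- array(FALSE, dim = shape)
  fallback <- NA_integer_
  cols <- unique(do.call(rbind, lapply(wb, function(b)
    as.matrix(expand.grid(x = b$x[1]:b$x[2], z = b$z[1]:b$z[2])))))
  ymins <- apply(cols, 1, function(cc) {
    i <- which(head[cc[1], , cc[2]])
    if (length(i)) i[1] else NA_integer_
  })
  fallback <- if (all(is.na(ymins))) shape[2] + 1L else min(ymins,
                                                            na.rm = TRUE)
  for (j in seq_len(nrow(cols))) {
    y0 <- if (is.na(ymins[j])) fallback else ymins[j]
    if (y0 > 1) out[cols[j, 1], seq_len(y0 - 1), cols[j, 2]] <- TRUE
  }
  binary_mask(out & bg$data, kind = "eye")
}

#' Build the ring-mask
#'
#' Restricts the background-mask to an axial slab near the top of the
#' head: slices from `z_min + lower_frac * extent` up to `z_max -
#' top_margin`, where `[z_min, z_max]` is the head's axial extent. The
#' lower bound keeps eye-movement ghosts out; the top margin avoids axial
#' wrap-around.
#'
#' @param bg a background [binary_mask()].
#' @param head_extent numeric length-2, the head's `c(z_min, z_max)`.
#' @param lower_frac fraction of the head extent below the slab (default
#'   0.6).
#' @param top_margin axial slices trimmed from the top (default 5).
#' @return A [binary_mask()] of kind `"ring"`.
#' @export
build_ring_mask <- function(bg, head_extent, lower_frac = 0.6,
                            top_margin = 5) {
  if (bg$kind != "background")
    stop_t1qc("`bg` must be a background-mask", "mask")
  zmin <- head_extent[1]; zmax <- head_extent[2]
  zlo <- ceiling(zmin + lower_frac * (zmax - zmin))
  zhi <- floor(zmax - top_margin)
  if (zlo > zhi)
    stop_t1qc("ring slab is empty for these bounds", "empty_slab")
  d <- dim(bg)
  zs <- max(1, zlo):min(d[3], zhi)
  out <- array(FALSE, dim = d)
  out[, , zs] <- bg$data[, , zs]
  if (!any(out))
    stop_t1qc("ring-mask is empty", "empty_slab")
  binary_mask(out, kind = "ring")
}

#' Axial extent of the head from tissue maps
#'
#' @param maps a [tissue_map_set()]; the head is where total head-tissue
#'   probability (1 - background) exceeds 0.5.
#' @return Integer `c(z_min, z_max)`.
#' @export
head_extent_z <- function(maps) {
  head <- maps$background < 0.5
  zs <- which(apply(head, 3, any))
  if (!length(zs)) stop_t1qc("no head voxels found", "empty_input")
  range(zs)
}
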