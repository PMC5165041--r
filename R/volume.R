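#' 3D scalar brain volume
#'
#' A `volume_grid` stores a 3D image on the package's canonical voxel axes:
#' x runs sagittally (left to right), y coronally (anterior to posterior)
#' and z axially (inferior to superior). Intensities are in arbitrary
#' scanner units and must be finite and non-negative.
#'
#' @param data 3D numeric array of intensities (finite, >= 0).
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An object of class `volume_grid` with elements `data` and
#'   `voxel_size`.
#' @export
#' @examples
#' v <- volume_grid(array(1, dim = c(4, 4, 4)))
#' dim(v)
volume_grid <- function(data, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_t1qc("`data` must be a 3D array", "non3d")
  if (any(!is.finite(data)))
    stop_t1qc("volume intensities must be finite", "invalid_volume")
  if (any(data < 0))
    stop_t1qc("volume intensities must be >= 0 (clamp on read)",
              "invalid_volume")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, intensity range [%g, %g]\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
as.array.volume_grid <- function(x, ...) x$data

#' Coerce to a volume_grid
#' @param x a 3D array or `volume_grid`.
#' @param ... passed on to [volume_grid()].
#' @export
as_volume_grid <- function(x, ...) {
  if (inherits(x, "volume_grid")) x else volume_grid(x, ...)
}

# Canonical orientation: x -> Right, y -> Posterior, z -> Superior.
.canonical_orientation <- "RPS"

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzipped), reorients it to the canonical
#' axis convention when the header carries a usable orientation, and clamps
#' small negative interpolation overshoots to zero with a warning.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param reorient reorient to the canonical x = sagittal, y = coronal
#'   (anterior to posterior), z = axial convention when the header allows.
#' @return A [volume_grid()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, reorient = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_t1qc(sprintf("file not found: %s", path), "missing_file")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_t1qc(sprintf("unreadable NIfTI header in %s: %s",
                                      path, conditionMessage(e)),
                              "unreadable_header"))
  if (length(dim(img)) != 3L)
    stop_t1qc(sprintf("non-3D image: %s has %d dimensions",
                      path, length(dim(img))), "non3d")
  if (isTRUE(reorient)) {
    ok <- tryCatch({
      cur <- RNifti::orientation(img)
      nzchar(cur) && cur != .canonical_orientation
    }, error = function(e) FALSE)
    if (isTRUE(ok))
      img <- tryCatch({ RNifti::orientation(img) <- .canonical_orientation
                        img },
                      warning = function(w) img, error = function(e) img)
  }
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (any(a < 0)) {
    warning(sprintf("%d negative voxel(s) clamped to 0 in %s",
                    sum(a < 0), path))
    a[a < 0] <- 0
  }
  pd <- tryCatch(RNifti::pixdim(img)[seq_len(3)],
                 error = function(e) c(1, 1, 1))
  volume_grid(a, voxel_size = pd)
}

#' Write a 3D volume as NIfTI
#'
#' The canonical axis convention is recorded in the sform so that
#' [read_volume()] restores the same array layout.
#'
#' @param vol a [volume_grid()] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume_grid(vol)
  img <- RNifti::asNifti(vol$data)
  m <- diag(c(vol$voxel_size[1], -vol$voxel_size[2], vol$voxel_size[3], 1))
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Per-subject tissue probability maps
#'
#' One probability map per tissue class (gray matter, white matter, CSF,
#' skull, fat, background), each on the same grid as the parent volume with
#' voxel values in \[0, 1\].
#'
#' @param gm,wm,csf,skull,fat,background 3D arrays (or `volume_grid`s) of
#'   class probabilities.
#' @return An object of class `tissue_map_set`: a named list of 3D arrays.
#' @export
tissue_map_set <- function(gm, wm, csf, skull, fat, background) {
  maps <- lapply(list(gm = gm, wm = wm, csf = csf, skull = skull,
                      fat = fat, background = background), vg_data)
  d <- dim(maps[[1]])
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!is.array(m) || length(dim(m)) != 3L || !identical(dim(m), d))
      stop_t1qc("tissue maps must be 3D arrays of identical shape",
                "map_shape")
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
      stop_t1qc(sprintf("tissue map '%s' has values outside [0, 1]", nm),
                "map_range")
  }
  structure(maps, class = "tissue_map_set")
}

#' @export
dim.tissue_map_set <- function(x) dim(x[[1]])

#' @export
print.tissue_map_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<tissue_map_set> 6 classes on a %d x %d x %d grid\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Forward/inverse affine transform pair
#'
#' Affine maps between native voxel space and normalized voxel space,
#' expressed as 4x4 matrices acting on homogeneous 1-based voxel indices.
#' `forward` maps native -> normalized; `inverse` maps back.
#'
#' @param forward 4x4 affine matrix (native to normalized voxel indices).
#' @param inverse 4x4 affine matrix; defaults to `solve(forward)`.
#' @param native_shape,target_shape integer length-3 grid dimensions of the
#'   native and normalized spaces.
#' @return An object of class `transform_pair`.
#' @export
transform_pair <- function(forward = diag(4), inverse = solve(forward),
                           native_shape, target_shape = native_shape) {
  if (!is.matrix(forward) || !identical(dim(forward), c(4L, 4L)))
    stop_t1qc("`forward` must be a 4x4 matrix", "transform")
  if (abs(det(forward)) < 1e-12)
    stop_t1qc("degenerate transform (determinant ~ 0)", "degenerate_transform")
  structure(list(forward = forward, inverse = inverse,
                 native_shape = as.integer(native_shape),
                 target_shape = as.integer(target_shape)),
            class = "transform_pair")
}

#' Identity transform pair for a given grid
#' @param shape integer length-3 grid dimensions.
#' @export
identity_transform <- function(shape) {
  transform_pair(diag(4), diag(4), native_shape = shape,
                 target_shape = shape)
}

is_identity_transform <- function(t) {
  isTRUE(all.equal(t$forward, diag(4), tolerance = 1e-12)) &&
    identical(t$native_shape, t$target_shape)
}

#' Resample a 3D array through an affine voxel map
#'
#' `affine` maps output voxel indices (1-based, homogeneous) to input voxel
#' indices; voxels that map outside the input grid are filled with 0.
#'
#' @param data 3D array.
#' @param affine 4x4 matrix, output index -> input index.
#' @param out_shape integer length-3 output grid.
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @return 3D array of dimension `out_shape`.
#' @keywords internal
resample_affine <- function(data, affine, out_shape,
                            mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (abs(det(affine)) < 1e-12)
    stop_t1qc("degenerate transform (determinant ~ 0)", "degenerate_transform")
  d <- dim(data)
  nx <- out_shape[1]; ny <- out_shape[2]; nz <- out_shape[3]
  n <- nx * ny * nz
  co <- cbind(rep.int(seq_len(nx), ny * nz),
              rep.int(rep(seq_len(ny), each = nx), nz),
              rep(seq_len(nz), each = nx * ny),
              1)
  src <- co %*% t(affine)
  out <- numeric(n)
  if (mode == "nearest") {
    ix <- round(src[, 1]); iy <- round(src[, 2]); iz <- round(src[, 3])
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    out[ok] <- data[cbind(ix[ok], iy[ok], iz[ok])]
  } else {
    fx <- floor(src[, 1]); fy <- floor(src[, 2]); fz <- floor(src[, 3])
    tx <- src[, 1] - fx; ty <- src[, 2] - fy; tz <- src[, 3] - fz
    corner <- function(ox, oy, oz) {
      ix <- fx + ox; iy <- fy + oy; iz <- fz + oz
      w <- (if (ox) tx else 1 - tx) *
           (if (oy) ty else 1 - ty) *
           (if (oz) tz else 1 - tz)
      ok <- w > 0 & ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] &
        iz >= 1 & iz <= d[3]
      v <- numeric(n)
      v[ok] <- w[ok] * data[cbind(ix[ok], iy[ok], iz[ok])]
      v
    }
    out <- corner(0, 0, 0) + corner(1, 0, 0) + corner(0, 1, 0) +
      corner(0, 0, 1) + corner(1, 1, 0) + corner(1, 0, 1) +
      corner(0, 1, 1) + corner(1, 1, 1)
  }
  array(out, dim = out_shape)
}
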