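# Voxelized scalar fields (CT number, ED, EAN, SPR, dose) with spacing and
# origin metadata; the common currency of all pipeline stages.

#' Create a scalar volume
#'
#' A 3D array plus isotropic-or-not voxel spacing (mm) and world origin (mm,
#' the center of voxel \[1,1,1\]).
#'
#' @param data Numeric 3D array.
#' @param spacing Voxel spacing in mm, length 3.
#' @param origin World coordinates (mm) of the first voxel center, length 3.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Same-grid copy with new voxel data
#'
#' @param vol A `scalar_volume` supplying grid metadata.
#' @param data New array (must match dimensions).
#' @return A `scalar_volume`.
#' @export
vol_like <- function(vol, data) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (!identical(dim(data), dim(vol$data))) {
    stopifnot(length(data) == length(vol$data))
    dim(data) <- dim(vol$data)
  }
  scalar_volume(data, vol$spacing, vol$origin)
}

#' Do two volumes share a grid?
#'
#' @param a,b `scalar_volume` objects.
#' @param tol Metadata tolerance in mm.
#' @return Logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel-center world coordinates along each axis
#'
#' @param vol A `scalar_volume`.
#' @return List of numeric vectors `x`, `y`, `z` (mm).
#' @export
vol_axes <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}

#' World coordinates of every voxel center
#'
#' @param vol A `scalar_volume`.
#' @return N x 3 matrix (mm), N = number of voxels, in array order.
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  ax <- vol_axes(vol)
  cbind(rep(ax$x, times = d[2] * d[3]),
        rep(rep(ax$y, each = d[1]), times = d[3]),
        rep(ax$z, each = d[1] * d[2]))
}

#' Trilinear interpolation of a volume at world points
#'
#' @param vol A `scalar_volume`.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @param outside Value returned for points outside the voxel-center hull
#'   (default `NA_real_`; use 0 for e.g. SPR of surrounding air).
#' @return Numeric vector of length N.
#' @export
interp_trilinear <- function(vol, pts, outside = NA_real_) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- dim(vol$data)
  # continuous voxel index, 1-based
  fx <- (pts[, 1] - vol$origin[1]) / vol$spacing[1] + 1
  fy <- (pts[, 2] - vol$origin[2]) / vol$spacing[2] + 1
  fz <- (pts[, 3] - vol$origin[3]) / vol$spacing[3] + 1
  # inside the voxel bounding box (half a voxel beyond the center hull the
  # nearest voxel value applies)
  ok <- fx >= 0.5 & fx <= d[1] + 0.5 & fy >= 0.5 & fy <= d[2] + 0.5 &
    fz >= 0.5 & fz <= d[3] + 0.5 &
    !is.na(fx) & !is.na(fy) & !is.na(fz)
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  fx <- pmin(pmax(fx[ok], 1), d[1]); fy <- pmin(pmax(fy[ok], 1), d[2])
  fz <- pmin(pmax(fz[ok], 1), d[3])
  i0 <- pmin(floor(fx), d[1] - 1L); j0 <- pmin(floor(fy), d[2] - 1L)
  k0 <- pmin(floor(fz), d[3] - 1L)
  i0 <- pmax(i0, 1L); j0 <- pmax(j0, 1L); k0 <- pmax(k0, 1L)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  arr <- vol$data
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  v000 <- idx(i0, j0, k0);     v100 <- idx(i0 + 1, j0, k0)
  v010 <- idx(i0, j0 + 1, k0); v110 <- idx(i0 + 1, j0 + 1, k0)
  v001 <- idx(i0, j0, k0 + 1); v101 <- idx(i0 + 1, j0, k0 + 1)
  v011 <- idx(i0, j0 + 1, k0 + 1); v111 <- idx(i0 + 1, j0 + 1, k0 + 1)
  c00 <- v000 * (1 - tx) + v100 * tx
  c10 <- v010 * (1 - tx) + v110 * tx
  c01 <- v001 * (1 - tx) + v101 * tx
  c11 <- v011 * (1 - tx) + v111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  out[ok] <- c0 * (1 - tz) + c1 * tz
  out
}

#' Write a volume as NIfTI
#'
#' Float data are written as float32; integer label volumes keep integer
#' type. Spacing is stored in the NIfTI pixdim.
#'
#' @param vol A `scalar_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path,
                     datatype = if (is.integer(vol$data)) "int16" else "float")
  invisible(path)
}

#' Read a NIfTI file as a scalar volume
#'
#' @param path NIfTI path.
#' @param origin World origin to assign (mm); NIfTI orientation matrices are
#'   not interpreted beyond voxel spacing.
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  scalar_volume(array(as.numeric(img), dim = dim(img)[1:3]), sp, origin)
}
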