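#' 3-D image volume with world-coordinate geometry
#'
#' A `vol3d` is a 3-D numeric array plus a voxel-to-world affine (RAS world
#' coordinates, mm). Voxel indices are 0-based in the affine convention:
#' world = A %*% c(i, j, k, 1) for voxel (i, j, k), i in 0..dim-1, matching
#' the NIfTI sform convention.
#'
#' @param data 3-D numeric array.
#' @param spacing voxel spacing in mm (length 3), used when `affine` is NULL.
#' @param affine 4x4 voxel-to-world matrix; when NULL, an axis-aligned affine
#'   with the given spacing is built, centred so the volume midpoint is at
#'   world origin.
#' @return object of class `vol3d` with fields `data`, `affine`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    # centre of the grid at world origin
    affine[1:3, 4] <- -spacing * (dim(data) - 1) / 2
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(data = data, affine = affine), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("vol3d %s, spacing [%s] mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(vol_spacing(x), 4), collapse = ", "),
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' Voxel spacing (mm) of a volume
#' @param vol a `vol3d`.
#' @export
vol_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Check two volumes share a grid
#' @param a,b `vol3d` objects.
#' @export
vol_same_grid <- function(a, b) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) < 1e-8
}

#' World coordinates of all voxel centres
#' @param vol a `vol3d`.
#' @return N x 3 matrix, voxels in array (column-major) order.
#' @export
vol_grid_points <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(vol, ijk)
}

#' Convert voxel indices (0-based) to world mm
#' @param vol a `vol3d`.
#' @param ijk N x 3 matrix of 0-based voxel coordinates (may be fractional).
#' @export
voxel_to_world <- function(vol, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  sweep(ijk %*% t(vol$affine[1:3, 1:3]), 2, vol$affine[1:3, 4], "+")
}

#' Convert world mm to voxel indices (0-based, fractional)
#' @param vol a `vol3d`.
#' @param xyz N x 3 matrix of world points.
#' @export
world_to_voxel <- function(vol, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  inv <- solve(vol$affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

#' Trilinear interpolation at world points
#'
#' Samples the volume at arbitrary world coordinates by trilinear
#' interpolation. Points outside the grid return NA.
#' @param vol a `vol3d`.
#' @param xyz N x 3 matrix of world points (mm).
#' @return numeric vector of length N; NA where out of volume.
#' @export
vol_sample <- function(vol, xyz) {
  v <- world_to_voxel(vol, xyz)
  interp_trilinear(vol$data, v)
}

# Trilinear interpolation at fractional 0-based voxel coordinates.
interp_trilinear <- function(arr, v) {
  d <- dim(arr)
  n <- nrow(v)
  out <- rep(NA_real_, n)
  ok <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
        v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
        v[, 3] >= 0 & v[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  v <- v[ok, , drop = FALSE]
  i0 <- pmin(floor(v[, 1]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(v[, 2]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(v[, 3]), d[3] - 2); k0 <- pmax(k0, 0)
  fx <- v[, 1] - i0; fy <- v[, 2] - j0; fz <- v[, 3] - k0
  # 1-based linear index of corner (i0, j0, k0)
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  a <- arr
  c000 <- a[base];            c100 <- a[base + sx]
  c010 <- a[base + sy];       c110 <- a[base + sx + sy]
  c001 <- a[base + sz];       c101 <- a[base + sx + sz]
  c011 <- a[base + sy + sz];  c111 <- a[base + sx + sy + sz]
  w <- c000 * (1 - fx) * (1 - fy) * (1 - fz) +
       c100 * fx       * (1 - fy) * (1 - fz) +
       c010 * (1 - fx) * fy       * (1 - fz) +
       c110 * fx       * fy       * (1 - fz) +
       c001 * (1 - fx) * (1 - fy) * fz +
       c101 * fx       * (1 - fy) * fz +
       c011 * (1 - fx) * fy       * fz +
       c111 * fx       * fy       * fz
  out[ok] <- w
  out
}

#' Build an empty volume on a given grid
#' @param dim_ voxel counts per axis.
#' @param spacing mm per axis.
#' @param affine optional explicit affine.
#' @param value fill value.
#' @export
vol_empty <- function(dim_, spacing = c(1, 1, 1), affine = NULL, value = 0) {
  vol3d(array(value, dim = dim_), spacing = spacing, affine = affine)
}

#' Write a volume as NIfTI-1
#' @param vol a `vol3d`.
#' @param path output path (`.nii` / `.nii.gz`).
#' @export
vol_write_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#' @param path path to a NIfTI file.
#' @return `vol3d` with the file's sform/qform as affine.
#' @export
vol_read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  vol3d(array(as.numeric(img), dim = dim(img)[1:3]), affine = aff)
}
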