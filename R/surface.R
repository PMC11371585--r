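#' Project a volumetric CBF map to the boundary surface
#'
#' Each boundary vertex is displaced by `projection_offset` mm along its
#' outward normal (into mid-GM for the default +1 mm), mapped from fixed
#' (T1w) world coordinates into the CBF image's space through the inverse of
#' the registration transform, and sampled with trilinear interpolation.
#' Vertices whose sample falls outside the volume are marked invalid.
#'
#' @param cbf `cbf_map` or `vol3d` (the moving mean-CBF image).
#' @param transform registration transform (moving -> T1w world);
#'   `rigid_transform` or 4x4 matrix.
#' @param boundary `boundary_surface` in T1w world coordinates.
#' @param projection_offset sampling offset along the outward normal, mm.
#' @param method,id optional labels stored on the result.
#' @return list of class `surface_map`: `values` (per vertex, NA where
#'   invalid), `valid` (logical), `method`, `id`.
#' @export
project_to_surface <- function(cbf, transform, boundary,
                               projection_offset = 1, method = NULL,
                               id = NULL) {
  vol <- if (inherits(cbf, "cbf_map")) cbf$volume else cbf
  m <- if (is.matrix(transform)) transform else rt_matrix(transform)
  pts <- boundary$vertices + projection_offset * boundary$normals
  vals <- vol_sample(vol, rt_apply(solve(m), pts))
  valid <- !is.na(vals)
  if (!any(valid)) stop("no boundary vertex samples inside the CBF volume")
  structure(list(values = vals, valid = valid, method = method, id = id),
            class = "surface_map")
}

#' Partition the boundary surface into parcels
#'
#' Deterministic seeded partition standing in for an anatomical atlas:
#' farthest-point seeding in chord (3-D Euclidean) distance followed by
#' nearest-seed assignment. Every parcel is nonempty (each seed is its own
#' nearest vertex), every vertex is labeled, and ids are contiguous
#' `1..n_parcels`.
#'
#' @param boundary `boundary_surface`.
#' @param n_parcels number of parcels (default 219).
#' @param seed integer seed choosing the first farthest-point seed.
#' @return list of class `parcellation`: `labels` (per vertex), `n_parcels`,
#'   `names`, `seed_vertices`.
#' @export
build_parcellation <- function(boundary, n_parcels = 219, seed = 1L) {
  v <- boundary$vertices
  n <- nrow(v)
  if (n_parcels > n) stop("more parcels than vertices")
  set.seed(as.integer(seed))
  seeds <- integer(n_parcels)
  seeds[1] <- sample.int(n, 1)
  mind <- colSums((t(v) - v[seeds[1], ])^2)
  if (n_parcels > 1) {
    for (k in 2:n_parcels) {
      seeds[k] <- which.max(mind)
      mind <- pmin(mind, colSums((t(v) - v[seeds[k], ])^2))
    }
  }
  labels <- nearest_vertex(v, v[seeds, , drop = FALSE])
  structure(list(labels = labels, n_parcels = as.integer(n_parcels),
                 names = sprintf("parcel_%03d", seq_len(n_parcels)),
                 seed_vertices = seeds),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels over %d vertices (size %d-%d)\n",
              x$n_parcels, length(x$labels), min(table(x$labels)),
              max(table(x$labels))))
  invisible(x)
}

#' Per-parcel mean CBF of a surface map
#'
#' Mean over valid vertices in each parcel; parcels with no valid vertex are
#' reported with NA.
#' @param surface_map a `surface_map`.
#' @param parcellation a `parcellation`.
#' @return data.frame: `parcel`, `mean_cbf`, `n_vertices` (valid count);
#'   one row per parcel.
#' @export
roi_mean_cbf <- function(surface_map, parcellation) {
  stopifnot(length(surface_map$values) == length(parcellation$labels))
  out <- data.frame(parcel = seq_len(parcellation$n_parcels),
                    mean_cbf = NA_real_, n_vertices = 0L)
  ok <- surface_map$valid
  if (any(ok)) {
    m <- tapply(surface_map$values[ok], parcellation$labels[ok], mean)
    cnt <- tapply(rep(1L, sum(ok)), parcellation$labels[ok], sum)
    idx <- as.integer(names(m))
    out$mean_cbf[idx] <- as.numeric(m)
    out$n_vertices[idx] <- as.integer(cnt)
  }
  out
}

#' Per-parcel GM volume
#'
#' Assigns every GM voxel to the parcel of its nearest boundary vertex and
#' reports `count x voxel volume` in mm^3. The sum over parcels equals the
#' total GM volume by construction.
#'
#' @param tissue_labels tissue label volume (2 = GM).
#' @param parcellation a `parcellation`.
#' @param boundary the `boundary_surface` the parcellation lives on.
#' @param voxel_parcels optional precomputed parcel id per GM voxel (in
#'   `which(tissue_labels == 2)` order), bypassing the nearest-vertex
#'   search.
#' @return data.frame: `parcel`, `volume_mm3`, `n_voxels`; one row per
#'   parcel.
#' @export
roi_volume <- function(tissue_labels, parcellation, boundary,
                       voxel_parcels = NULL) {
  gm_idx <- which(tissue_labels$data == 2L)
  if (!length(gm_idx)) stop("empty GM mask")
  parc <- if (is.null(voxel_parcels)) {
    pts <- voxel_to_world(tissue_labels, arrayInd(gm_idx, dim(tissue_labels$data)) - 1)
    parcellation$labels[nearest_vertex(pts, boundary$vertices)]
  } else {
    stopifnot(length(voxel_parcels) == length(gm_idx))
    voxel_parcels
  }
  voxvol <- prod(vol_spacing(tissue_labels))
  out <- data.frame(parcel = seq_len(parcellation$n_parcels),
                    volume_mm3 = 0, n_voxels = 0L)
  cnt <- table(factor(parc, levels = seq_len(parcellation$n_parcels)))
  out$n_voxels <- as.integer(cnt)
  out$volume_mm3 <- out$n_voxels * voxvol
  out
}

#' Write / read a surface map as TSV
#' @param surface_map a `surface_map`.
#' @param path file path.
#' @export
surface_map_write <- function(surface_map, path) {
  utils::write.table(data.frame(vertex = seq_along(surface_map$values),
                                value = surface_map$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
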