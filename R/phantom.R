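#' Phantom specification
#'
#' Describes the synthetic head phantom and its acquisition grids. The
#' anatomy is a set of nested shells around a common centre: a white-matter
#' (WM) core bounded by a rippled ellipsoid, a gray-matter (GM) ribbon of
#' fixed radial thickness, and a CSF shell. The GM-WM interface is defined
#' analytically as the radius function
#' \deqn{R(\theta, \phi) = r_{ell}(\theta, \phi)\,(1 + A\,g(\theta, \phi))}
#' where `r_ell` is the ellipsoid radius along the direction and `g` a fixed
#' low-order angular harmonic. The ripple is the phantom's stand-in for
#' cortical folding: it breaks rotational symmetry so that boundary-driven
#' registration can identify rotations. Both the boundary surface and its
#' outward normals are available in closed form.
#'
#' True GM perfusion additionally carries a smooth angular texture shared by
#' all participants (`cbf_texture`), the phantom's stand-in for the common
#' topography of cortical perfusion; it is what makes well-registered
#' participants correlate with each other.
#'
#' The ASL grid defaults reproduce a 64 x 64 in-plane matrix of 34 slices at
#' 3.75 mm isotropic voxels; the structural grid is a T1w-like grid.
#'
#' @param structural_shape voxel counts of the structural (T1w-like) grid.
#' @param structural_spacing structural voxel size, mm (isotropic scalar or
#'   length 3).
#' @param asl_shape voxel counts of the ASL grid (default `c(64, 64, 34)`).
#' @param asl_spacing ASL voxel size in mm (default 3.75 isotropic).
#' @param tissue_intensities named vector of T1w-like mean intensities; must
#'   satisfy WM > GM > CSF.
#' @param gm_cbf_baseline,wm_cbf_baseline baseline perfusion, mL/100g/min;
#'   GM must exceed WM.
#' @param noise_sd additive Gaussian noise SD on each simulated ASL volume,
#'   in raw signal intensity units.
#' @param ringing_amplitude amplitude in `[0, 1]` of the multiplicative
#'   radial sinusoid applied to the static tissue signal of individual ASL
#'   volumes (cancels in control - label subtraction).
#' @param m0_value equilibrium magnetisation inside the head.
#' @param wm_semiaxes WM-core ellipsoid semi-axes, mm.
#' @param gm_thickness,csf_thickness radial thickness of the GM ribbon and
#'   CSF shell, mm.
#' @param boundary_ripple relative amplitude of the angular ripple on the
#'   GM-WM boundary (0 gives a pure ellipsoid).
#' @param cbf_texture relative amplitude of the shared angular GM perfusion
#'   texture.
#' @param mesh_rings,mesh_segments latitude / longitude resolution of the
#'   boundary mesh.
#' @param seed integer seed governing all random draws tied to this spec.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(structural_shape = c(64, 64, 64),
                         structural_spacing = 3,
                         asl_shape = c(64, 64, 34),
                         asl_spacing = 3.75,
                         tissue_intensities = c(wm = 1000, gm = 600, csf = 200),
                         gm_cbf_baseline = 60,
                         wm_cbf_baseline = 20,
                         noise_sd = 1,
                         ringing_amplitude = 0.1,
                         m0_value = 1000,
                         wm_semiaxes = c(56, 66, 44),
                         gm_thickness = 9,
                         csf_thickness = 5,
                         boundary_ripple = 0.08,
                         cbf_texture = 0.15,
                         mesh_rings = 40,
                         mesh_segments = 80,
                         seed = 1L) {
  if (length(structural_spacing) == 1) structural_spacing <- rep(structural_spacing, 3)
  if (length(asl_spacing) == 1) asl_spacing <- rep(asl_spacing, 3)
  stopifnot(all(structural_spacing > 0), all(asl_spacing > 0),
            gm_cbf_baseline > wm_cbf_baseline, wm_cbf_baseline >= 0,
            ringing_amplitude >= 0, ringing_amplitude <= 1,
            boundary_ripple >= 0, boundary_ripple < 0.2,
            cbf_texture >= 0, cbf_texture < 0.5,
            all(c("wm", "gm", "csf") %in% names(tissue_intensities)))
  if (!(tissue_intensities["wm"] > tissue_intensities["gm"] &&
        tissue_intensities["gm"] > tissue_intensities["csf"]))
    stop("tissue intensities must satisfy WM > GM > CSF (T1w-like contrast)")
  if (any(structural_shape < 16) || any(asl_shape < 16))
    stop("degenerate grid: every axis needs at least 16 voxels")
  structure(list(structural_shape = as.integer(structural_shape),
                 structural_spacing = structural_spacing,
                 asl_shape = as.integer(asl_shape),
                 asl_spacing = asl_spacing,
                 tissue_intensities = tissue_intensities,
                 gm_cbf_baseline = gm_cbf_baseline,
                 wm_cbf_baseline = wm_cbf_baseline,
                 noise_sd = noise_sd,
                 ringing_amplitude = ringing_amplitude,
                 m0_value = m0_value,
                 wm_semiaxes = wm_semiaxes,
                 gm_thickness = gm_thickness,
                 csf_thickness = csf_thickness,
                 boundary_ripple = boundary_ripple,
                 cbf_texture = cbf_texture,
                 mesh_rings = as.integer(mesh_rings),
                 mesh_segments = as.integer(mesh_segments),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Radius of the pure ellipsoid along unit directions (rows of d).
ellipsoid_radius <- function(d, semiaxes) {
  1 / sqrt((d[, 1] / semiaxes[1])^2 + (d[, 2] / semiaxes[2])^2 +
           (d[, 3] / semiaxes[3])^2)
}

# Fixed angular harmonics. Both vanish at the poles to at least second
# order, keeping the surface smooth there. `which` selects the boundary
# ripple shape or the independent perfusion-texture shape.
angular_pattern <- function(theta, phi, which = c("ripple", "texture")) {
  which <- match.arg(which)
  st <- sin(theta); ct <- cos(theta)
  if (which == "ripple")
    st^2 * ct * cos(2 * phi) + 0.7 * st^3 * sin(3 * phi) +
      0.5 * st^4 * cos(4 * phi)
  else
    st^2 * ct * sin(2 * phi) + 0.7 * st^3 * cos(3 * phi)
}

# d(pattern)/d(theta), d(pattern)/d(phi) for the ripple harmonic.
ripple_gradient <- function(theta, phi) {
  st <- sin(theta); ct <- cos(theta)
  g_t <- (2 * st * ct^2 - st^3) * cos(2 * phi) + 2.1 * st^2 * ct * sin(3 * phi) +
    2 * st^3 * ct * cos(4 * phi)
  g_p <- -2 * st^2 * ct * sin(2 * phi) + 2.1 * st^3 * cos(3 * phi) -
    2 * st^4 * sin(4 * phi)
  list(theta = g_t, phi = g_p)
}

# Spherical angles of unit directions.
dir_angles <- function(d) {
  list(theta = acos(pmax(-1, pmin(1, d[, 3]))), phi = atan2(d[, 2], d[, 1]))
}

#' GM-WM boundary radius along directions
#'
#' The analytic interface radius `r_ell(d) (1 + A g(d))` used both to
#' classify voxels and to place boundary vertices.
#' @param d N x 3 matrix of unit directions.
#' @param spec a [phantom_spec()] (or list with `wm_semiaxes`,
#'   `boundary_ripple`).
#' @return numeric vector of radii, mm.
#' @export
boundary_radius <- function(d, spec) {
  ang <- dir_angles(d)
  ellipsoid_radius(d, spec$wm_semiaxes) *
    (1 + spec$boundary_ripple * angular_pattern(ang$theta, ang$phi, "ripple"))
}

# Radial coordinate machinery: for points x (N x 3, world mm centred on the
# phantom), the radius, unit direction, and local boundary radius. Tissue is
# decided by |x| against R_wm, R_wm + gm_thickness, R_wm + gm_thickness +
# csf_thickness.
radial_coords <- function(pts, spec) {
  r <- sqrt(rowSums(pts^2))
  d <- pts / pmax(r, 1e-12)
  list(r = r, dir = d, r_wm = boundary_radius(d, spec))
}

#' Generate the structural phantom, tissue labels, and boundary surface
#'
#' Renders the nested-shell anatomy on the structural grid and builds the
#' GM-WM boundary as a UV-sphere mesh warped onto the analytic interface;
#' vertex normals are the closed-form surface normals, oriented outward
#' (from WM into GM).
#'
#' @param spec a [phantom_spec()].
#' @param thinning_mm optional per-vertex GM thinning (mm) emulating regional
#'   atrophy: the GM outer radius is reduced by the thinning of the nearest
#'   boundary vertex. A scalar applies globally.
#' @return list with `structural` (vol3d), `tissue_labels` (vol3d; 0 =
#'   background, 1 = CSF, 2 = GM, 3 = WM), `boundary` (class
#'   `boundary_surface`: `vertices`, `normals`, `faces`).
#' @export
generate_phantom <- function(spec, thinning_mm = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  boundary <- boundary_mesh(spec)
  labels <- render_tissue_labels(spec, boundary, thinning_mm,
                                 dim_ = spec$structural_shape,
                                 spacing = spec$structural_spacing)
  ti <- spec$tissue_intensities
  lut <- c(0, ti["csf"], ti["gm"], ti["wm"])
  structural <- labels
  structural$data <- array(lut[labels$data + 1], dim = dim(labels$data))
  list(structural = structural, tissue_labels = labels, boundary = boundary)
}

# Render tissue labels on an arbitrary grid (optionally through a rigid
# transform mapping grid world coords into phantom/T1w world coords).
# Per-vertex thinning only reclassifies GM voxels in the outer-GM shell, so
# the nearest-vertex lookup runs on that shell alone.
render_tissue_labels <- function(spec, boundary, thinning_mm, dim_, spacing,
                                 affine = NULL, world_map = NULL) {
  vol <- vol_empty(dim_, spacing = spacing, affine = affine)
  pts <- vol_grid_points(vol)
  if (!is.null(world_map)) pts <- rt_apply(world_map, pts)
  rc <- radial_coords(pts, spec)
  csf_outer <- rc$r_wm + spec$gm_thickness + spec$csf_thickness
  lab <- integer(nrow(pts))
  lab[rc$r <= csf_outer] <- 1L
  lab[rc$r <= rc$r_wm + spec$gm_thickness] <- 2L
  lab[rc$r <= rc$r_wm] <- 3L
  maxthin <- max(thinning_mm)
  if (maxthin > 0) {
    shell <- which(lab == 2L & rc$r > rc$r_wm + spec$gm_thickness - maxthin)
    if (length(shell)) {
      thin <- local_thinning(rc$dir[shell, , drop = FALSE] * rc$r_wm[shell],
                             boundary, thinning_mm)
      drop_ <- rc$r[shell] > rc$r_wm[shell] + pmax(spec$gm_thickness - thin, 0)
      lab[shell[drop_]] <- 1L
    }
  }
  vol$data <- array(lab, dim = dim_)
  vol
}

# Per-point thinning (mm) given per-vertex thinning on the boundary mesh:
# nearest-vertex lookup on the interface. Scalar thinning short-circuits.
local_thinning <- function(surface_pts, boundary, thinning_mm) {
  if (length(thinning_mm) == 1) return(rep(thinning_mm, nrow(surface_pts)))
  stopifnot(length(thinning_mm) == nrow(boundary$vertices))
  idx <- nearest_vertex(surface_pts, boundary$vertices)
  thinning_mm[idx]
}

# Nearest boundary vertex for each query point (chunked brute force).
nearest_vertex <- function(pts, vertices, chunk = 4096L) {
  n <- nrow(pts)
  out <- integer(n)
  v2 <- rowSums(vertices^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    block <- pts[s:e, , drop = FALSE]
    # squared distance = |p|^2 - 2 p.v + |v|^2; |p|^2 constant per row
    cross <- block %*% t(vertices)
    d2 <- sweep(-2 * cross, 2, v2, "+")
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Boundary mesh on the analytic GM-WM interface
#'
#' UV-sphere mesh warped onto the rippled-ellipsoid interface. Vertices lie
#' exactly on the analytic surface; normals are the closed-form surface
#' normals from the parametric derivatives (the poles, where the ripple
#' vanishes to second order, use the ellipsoid gradient).
#'
#' @param spec a [phantom_spec()] (fields `wm_semiaxes`, `boundary_ripple`,
#'   `mesh_rings`, `mesh_segments`).
#' @return `boundary_surface` with `vertices` (N x 3), `normals` (N x 3,
#'   unit, outward), `faces` (M x 3, 1-based).
#' @export
boundary_mesh <- function(spec) {
  rings <- spec$mesh_rings
  segments <- spec$mesh_segments
  a <- spec$wm_semiaxes
  A <- spec$boundary_ripple
  theta <- pi * seq_len(rings - 1) / rings
  phi <- 2 * pi * (seq_len(segments) - 1) / segments
  th <- rep(theta, times = segments)
  ph <- rep(phi, each = rings - 1)
  st <- sin(th); ct <- cos(th); sp <- sin(ph); cp <- cos(ph)
  u <- cbind(st * cp, st * sp, ct)
  u_t <- cbind(ct * cp, ct * sp, -st)
  u_p <- cbind(-st * sp, st * cp, 0)

  W <- (u[, 1] / a[1])^2 + (u[, 2] / a[2])^2 + (u[, 3] / a[3])^2
  re <- 1 / sqrt(W)
  dW_t <- 2 * (u[, 1] * u_t[, 1] / a[1]^2 + u[, 2] * u_t[, 2] / a[2]^2 +
               u[, 3] * u_t[, 3] / a[3]^2)
  dW_p <- 2 * (u[, 1] * u_p[, 1] / a[1]^2 + u[, 2] * u_p[, 2] / a[2]^2)
  re_t <- -0.5 * re^3 * dW_t
  re_p <- -0.5 * re^3 * dW_p

  g <- angular_pattern(th, ph, "ripple")
  gg <- ripple_gradient(th, ph)
  R <- re * (1 + A * g)
  R_t <- re_t * (1 + A * g) + re * A * gg$theta
  R_p <- re_p * (1 + A * g) + re * A * gg$phi

  v <- R * u
  v_t <- R_t * u + R * u_t
  v_p <- R_p * u + R * u_p
  n <- cbind(v_t[, 2] * v_p[, 3] - v_t[, 3] * v_p[, 2],
             v_t[, 3] * v_p[, 1] - v_t[, 1] * v_p[, 3],
             v_t[, 1] * v_p[, 2] - v_t[, 2] * v_p[, 1])
  n <- n / sqrt(rowSums(n^2))
  flip <- rowSums(n * u) < 0
  n[flip, ] <- -n[flip, ]

  poles <- rbind(c(0, 0, a[3]), c(0, 0, -a[3]))
  pole_n <- rbind(c(0, 0, 1), c(0, 0, -1))
  vertices <- rbind(poles[1, ], v, poles[2, ])
  normals <- rbind(pole_n[1, ], n, pole_n[2, ])
  dimnames(vertices) <- dimnames(normals) <- NULL
  faces <- uv_sphere_faces(rings, segments)
  structure(list(vertices = vertices, normals = normals, faces = faces,
                 spec_geometry = list(wm_semiaxes = a, boundary_ripple = A)),
            class = "boundary_surface")
}

# Triangulation of the UV sphere: pole fans plus quad strips split in two.
# Vertex layout: north pole, then (rings - 1) x segments grid stored
# ring-fastest, then south pole.
uv_sphere_faces <- function(rings, segments) {
  idx <- function(i, j) 1L + (((j - 1L) %% segments) * (rings - 1L)) + i
  jj <- seq_len(segments)
  top <- cbind(1L, idx(1L, jj), idx(1L, jj + 1L))
  south <- 1L + (rings - 1L) * segments + 1L
  bot <- cbind(south, idx(rings - 1L, jj + 1L), idx(rings - 1L, jj))
  quads <- vector("list", rings - 2L)
  for (i in seq_len(rings - 2L)) {
    a <- idx(i, jj); b <- idx(i, jj + 1L)
    c_ <- idx(i + 1L, jj); d <- idx(i + 1L, jj + 1L)
    quads[[i]] <- rbind(cbind(a, b, c_), cbind(b, d, c_))
  }
  faces <- rbind(top, do.call(rbind, quads), bot)
  dimnames(faces) <- NULL
  storage.mode(faces) <- "integer"
  faces
}

#' @export
print.boundary_surface <- function(x, ...) {
  cat(sprintf("boundary_surface: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write / read a boundary surface as plain-text TSV
#'
#' Vertex rows (`v x y z nx ny nz`) followed by face rows (`f i j k`,
#' 1-based).
#' @param surface a `boundary_surface`.
#' @param path file path.
#' @export
surface_write <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vb <- cbind("v", formatC(cbind(surface$vertices, surface$normals),
                           format = "g", digits = 17))
  fb <- cbind("f", surface$faces)
  writeLines(c(apply(vb, 1, paste, collapse = "\t"),
               apply(fb, 1, paste, collapse = "\t")), con)
  invisible(path)
}

#' @rdname surface_write
#' @export
surface_read <- function(path) {
  lines <- readLines(path)
  tag <- substr(lines, 1, 1)
  vparts <- do.call(rbind, strsplit(lines[tag == "v"], "\t", fixed = TRUE))
  fparts <- do.call(rbind, strsplit(lines[tag == "f"], "\t", fixed = TRUE))
  vnum <- apply(vparts[, -1, drop = FALSE], 2, as.numeric)
  structure(list(vertices = vnum[, 1:3, drop = FALSE],
                 normals = vnum[, 4:6, drop = FALSE],
                 faces = apply(fparts[, -1, drop = FALSE], 2, as.integer)),
            class = "boundary_surface")
}
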