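## Registration engines: rigid intensity-based alignment (correlation-ratio
## cost over a multi-resolution point pyramid, deterministic pattern-search
## optimizer) and boundary-based refinement along the GM-WM surface.

# --- deterministic compass / pattern-search optimizer -----------------------
# Greedy coordinate moves with step halving. Every accepted move strictly
# decreases the objective, so the returned value never exceeds fn(par0).
pattern_search <- function(par, fn, steps, step_tol = 0.02, max_iter = 200) {
  value <- fn(par)
  iter <- 0L
  evals <- 1L
  while (iter < max_iter && any(steps > step_tol)) {
    iter <- iter + 1L
    best_par <- NULL
    best_val <- value
    for (i in seq_along(par)) {
      for (s in c(steps[i], -steps[i])) {
        cand <- par
        cand[i] <- cand[i] + s
        v <- fn(cand)
        evals <- evals + 1L
        if (v < best_val - 1e-15) {
          best_val <- v
          best_par <- cand
        }
      }
    }
    if (is.null(best_par)) {
      steps <- steps / 2
    } else {
      par <- best_par
      value <- best_val
    }
  }
  list(par = par, value = value, iterations = iter, evals = evals)
}

# --- correlation ratio ------------------------------------------------------
# eta^2-style cost: sum_k n_k Var_k(moving) / (N Var(moving)) with bins taken
# from the fixed image's intensities. 0 for a perfect functional
# relationship, 1 for none.
correlation_ratio_cost <- function(moving_samples, bin_index, n_bins) {
  ok <- !is.na(moving_samples)
  m <- moving_samples[ok]
  b <- bin_index[ok]
  n <- length(m)
  if (n < 10) return(1.5)
  v_tot <- stats::var(m)
  if (!is.finite(v_tot) || v_tot <= 0) return(1)
  s1 <- rowsum(m, b)
  s2 <- rowsum(m^2, b)
  nk <- rowsum(rep(1, n), b)
  within <- sum(pmax(s2 - s1^2 / nk, 0))
  within / ((n - 1) * v_tot)
}

#' Rigid 6-DOF intensity-based registration
#'
#' Aligns `moving` to `fixed` by minimising the correlation-ratio cost over a
#' multi-resolution pyramid of fixed-image sample points, using a
#' deterministic compass (pattern) search whose accepted steps never increase
#' the cost. This is the engine behind both ASL-to-T1w alignment and
#' within-series motion correction.
#'
#' @param moving,fixed `vol3d` volumes with valid world affines.
#' @param init initial `rigid_transform` (moving -> fixed world mapping).
#' @param control list of engine settings: `strides` (point subsampling per
#'   pyramid level, coarse to fine), `steps` (initial step in mm / degrees
#'   per level), `step_tol` (convergence step size), `n_bins`, `max_iter`,
#'   `max_points`, `min_overlap` (minimum fraction of sample points that must
#'   land inside the moving volume), `mask_quantile` (fixed-intensity
#'   threshold quantile for the sampling mask).
#' @return list of class `registration_result`: `transform`, `final_cost`,
#'   `init_cost`, `iterations`, `converged`, `method`.
#' @export
rigid_register <- function(moving, fixed, init = rigid_transform(),
                           control = list()) {
  ctl <- utils::modifyList(list(strides = c(3, 2, 1), steps = c(4, 1, 0.25),
                                step_tol = 0.02, n_bins = 32, max_iter = 100,
                                max_points = 8000, min_overlap = 0.25,
                                mask_quantile = 0), control)
  d <- dim(fixed$data)
  thr <- max(fixed$data, na.rm = TRUE) * 0.05
  mask <- which(fixed$data > thr)
  if (length(mask) < 50) stop("fixed image mask is (nearly) empty")
  ijk <- arrayInd(mask, d) - 1
  pts_all <- voxel_to_world(fixed, ijk)
  f_all <- fixed$data[mask]
  center <- colMeans(pts_all)

  # re-express init about the optimisation centre (mask centroid)
  init_c <- rt_from_matrix(rt_matrix(init), center = center)
  par <- c(init_c$rotation, init_c$translation)

  make_cost <- function(pts, f) {
    rng <- range(f)
    bw <- diff(rng) / ctl$n_bins
    if (bw <= 0) bw <- 1
    bins <- pmin(ctl$n_bins, 1 + floor((f - rng[1]) / bw))
    minv <- solve(moving$affine)
    function(p) {
      tf <- rigid_transform(p[1:3], p[4:6], center)
      mpts <- rt_apply(solve(rt_matrix(tf)), pts)
      v <- sweep(mpts %*% t(minv[1:3, 1:3]), 2, minv[1:3, 4], "+")
      s <- interp_trilinear(moving$data, v)
      if (mean(!is.na(s)) < ctl$min_overlap) return(1.5)
      correlation_ratio_cost(s, bins, ctl$n_bins)
    }
  }

  total_iter <- 0L
  init_cost <- NA_real_
  value <- NA_real_
  for (lev in seq_along(ctl$strides)) {
    keep <- seq(1, length(f_all), by = ctl$strides[lev])
    if (length(keep) > ctl$max_points)
      keep <- keep[seq(1, length(keep), length.out = ctl$max_points)]
    cost <- make_cost(pts_all[keep, , drop = FALSE], f_all[keep])
    if (lev == 1) init_cost <- cost(par)
    res <- pattern_search(par, cost,
                          steps = rep(ctl$steps[lev], 6),
                          step_tol = ctl$step_tol, max_iter = ctl$max_iter)
    par <- res$par
    value <- res$value
    total_iter <- total_iter + res$iterations
  }
  tf <- rigid_transform(par[1:3], par[4:6], center)
  converged <- is.finite(value) && value <= init_cost + 1e-12 && value < 1.4
  structure(list(transform = tf, final_cost = value, init_cost = init_cost,
                 iterations = total_iter, converged = converged,
                 method = "flirt_init"),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s]: cost %.6g (init %.6g), %d iterations, %s\n",
              x$method, x$final_cost, x$init_cost, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Emulated manual registration
#'
#' Stands in for interactive manual alignment: the participant's true
#' transform perturbed by seeded Gaussian operator error, independently per
#' rotation axis (degrees) and translation axis (mm).
#'
#' @param true_transform ground-truth `rigid_transform`.
#' @param operator_sd length-2 numeric `c(mm, degrees)` operator error SD
#'   per axis; default 1 mm / 1 degree.
#' @param seed integer seed.
#' @return `rigid_transform`.
#' @export
emulate_manual <- function(true_transform, operator_sd = c(1, 1), seed = 1L) {
  stopifnot(all(operator_sd >= 0))
  set.seed(as.integer(seed))
  rt_perturb(true_transform,
             d_rot = stats::rnorm(3, 0, operator_sd[2]),
             d_trans = stats::rnorm(3, 0, operator_sd[1]))
}

#' Boundary-based registration settings
#'
#' @param offset_distance sampling distance (mm) inward/outward along each
#'   vertex normal.
#' @param contrast_sign expected sign of (outside - inside) contrast in the
#'   moving image; +1 because GM CBF exceeds WM CBF.
#' @param slope steepness of the tanh saturation applied to the percent
#'   contrast.
#' @param max_iter optimizer iteration cap.
#' @param tol step-size convergence tolerance (mm / degrees).
#' @param dof 6 (rigid) or 12 (full affine).
#' @param epsilon guard added to the mean intensity in the percent-contrast
#'   denominator.
#' @param n_vertices optional cap on the number of boundary vertices used
#'   (deterministic stride subsample).
#' @export
bbr_config <- function(offset_distance = 3, contrast_sign = 1, slope = 0.01,
                       max_iter = 200, tol = 0.005, dof = 6,
                       epsilon = 1e-6, n_vertices = NULL) {
  stopifnot(offset_distance > 0, dof %in% c(6, 12))
  structure(list(offset_distance = offset_distance,
                 contrast_sign = contrast_sign, slope = slope,
                 max_iter = max_iter, tol = tol, dof = dof,
                 epsilon = epsilon, n_vertices = n_vertices),
            class = "bbr_config")
}

# Internal: BBR cost that reports validity instead of erroring (for use
# inside the optimizer). `matrix_inv` is the inverse of the moving->fixed
# map (fixed world -> moving world).
bbr_cost_eval <- function(matrix_inv, moving, vertices, normals, cfg) {
  out_pts <- vertices + cfg$offset_distance * normals
  in_pts <- vertices - cfg$offset_distance * normals
  i_out <- vol_sample(moving, rt_apply(matrix_inv, out_pts))
  i_in <- vol_sample(moving, rt_apply(matrix_inv, in_pts))
  ok <- !is.na(i_out) & !is.na(i_in)
  valid_frac <- mean(ok)
  if (!any(ok)) return(list(cost = Inf, valid_frac = 0))
  q <- 100 * (i_out[ok] - i_in[ok]) /
    (0.5 * (i_out[ok] + i_in[ok]) + cfg$epsilon)
  list(cost = mean(1 - tanh(cfg$slope * cfg$contrast_sign * q)),
       valid_frac = valid_frac,
       n_excluded = sum(!ok))
}

#' Boundary-based registration cost
#'
#' For each boundary vertex v with unit outward normal n, samples the moving
#' image at `transform^-1(v + d n)` and `transform^-1(v - d n)` (trilinear),
#' forms the percent contrast
#' `Q = 100 (I_out - I_in) / (0.5 (I_out + I_in) + eps)`, and scores
#' `1 - tanh(slope * sign * Q)`. The total cost is the mean over vertices
#' whose two samples both fall inside the moving volume; vertices sampling
#' outside are excluded and counted. Errors if more than half the vertices
#' are out of volume.
#'
#' @param transform `rigid_transform` (or 4x4 affine matrix) mapping moving
#'   world coordinates into the fixed (T1w) world.
#' @param moving the moving volume (mean CBF map).
#' @param boundary `boundary_surface` in fixed world coordinates.
#' @param cfg [bbr_config()].
#' @return nonnegative scalar cost with attributes `valid_frac`,
#'   `n_excluded`.
#' @export
bbr_cost <- function(transform, moving, boundary, cfg = bbr_config()) {
  vs <- bbr_vertex_subset(boundary, cfg)
  m <- if (is.matrix(transform)) transform else rt_matrix(transform)
  ev <- bbr_cost_eval(solve(m), moving, vs$vertices, vs$normals, cfg)
  if (ev$valid_frac < 0.5)
    stop(sprintf("BBR cost invalid: only %.0f%% of boundary vertices sample inside the moving volume",
                 100 * ev$valid_frac))
  structure(ev$cost, valid_frac = ev$valid_frac, n_excluded = ev$n_excluded)
}

bbr_vertex_subset <- function(boundary, cfg) {
  v <- boundary$vertices
  n <- boundary$normals
  if (!is.null(cfg$n_vertices) && cfg$n_vertices < nrow(v)) {
    keep <- unique(round(seq(1, nrow(v), length.out = cfg$n_vertices)))
    v <- v[keep, , drop = FALSE]
    n <- n[keep, , drop = FALSE]
  }
  list(vertices = v, normals = n)
}

# Build a 4x4 affine from 12 parameters about a centre: rotation (deg),
# translation (mm), log-scales, shears.
affine_from_params <- function(p, center) {
  R <- rot_matrix_deg(p[1:3])
  S <- diag(exp(p[7:9]))
  H <- diag(3)
  H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
  A <- R %*% S %*% H
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- center + p[4:6] - A %*% center
  m
}

#' Boundary-based refinement of an initial registration
#'
#' Minimises [bbr_cost()] starting from `init` with the deterministic
#' pattern-search optimizer, over 6 rigid parameters (default) or 12 affine
#' parameters. The moving image is the mean CBF map; the boundary is the
#' GM-WM surface in fixed (T1w) world coordinates.
#'
#' @param init initial `rigid_transform` (e.g. the emulated-manual or the
#'   rigid intensity-based result).
#' @param moving mean CBF `vol3d`.
#' @param boundary `boundary_surface`.
#' @param cfg [bbr_config()].
#' @param method method label recorded on the result (e.g. `"manual+BBR"`
#'   or `"FLIRT+BBR"`).
#' @return `registration_result`; `transform` is a `rigid_transform` for
#'   `dof = 6` and a 4x4 affine matrix for `dof = 12`.
#' @export
bbr_refine <- function(init, moving, boundary, cfg = bbr_config(),
                       method = "FLIRT+BBR") {
  vs <- bbr_vertex_subset(boundary, cfg)
  center <- colMeans(vs$vertices)
  init_c <- rt_from_matrix(rt_matrix(init), center = center)
  p0 <- c(init_c$rotation, init_c$translation)
  if (cfg$dof == 12) p0 <- c(p0, rep(0, 6))

  fn <- function(p) {
    m <- if (cfg$dof == 12) affine_from_params(p, center)
         else rt_matrix(rigid_transform(p[1:3], p[4:6], center))
    ev <- bbr_cost_eval(solve(m), moving, vs$vertices, vs$normals, cfg)
    if (ev$valid_frac < 0.5) return(Inf)
    ev$cost
  }
  init_cost <- fn(p0)
  if (!is.finite(init_cost))
    stop("invalid BBR initialization: fewer than 50% of boundary vertices sample inside the moving volume")
  steps <- c(rep(0.5, 6), rep(0.02, 6))[seq_along(p0)]
  res <- pattern_search(p0, fn, steps = steps, step_tol = cfg$tol,
                        max_iter = cfg$max_iter)
  tf <- if (cfg$dof == 12) affine_from_params(res$par, center)
        else rigid_transform(res$par[1:3], res$par[4:6], center)
  structure(list(transform = tf, final_cost = res$value,
                 init_cost = init_cost, iterations = res$iterations,
                 converged = res$value <= init_cost + 1e-12,
                 method = method),
            class = "registration_result")
}

#' Resample a volume (or map points) through a transform
#'
#' World-coordinate mapping: a point in the moving image maps to the fixed
#' world as `y = T(x)`. Resampling onto `target`'s grid therefore samples the
#' source at `T^-1(voxel centre)` with trilinear interpolation.
#'
#' @param volume source `vol3d`.
#' @param transform `rigid_transform` or 4x4 affine matrix (moving -> target
#'   world).
#' @param target `vol3d` (or list with `dim`/`affine`) defining the output
#'   grid.
#' @param fill value for out-of-volume voxels.
#' @return resampled `vol3d` on the target grid.
#' @export
apply_transform <- function(volume, transform, target, fill = 0) {
  d <- dim(target$data)
  if (prod(d) == 0) stop("empty target grid")
  out <- vol_empty(d, affine = target$affine)
  m <- if (is.matrix(transform)) transform else rt_matrix(transform)
  pts <- vol_grid_points(out)
  src <- rt_apply(solve(m), pts)
  vals <- vol_sample(volume, src)
  vals[is.na(vals)] <- fill
  out$data <- array(vals, dim = d)
  out
}
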