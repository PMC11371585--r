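#' pCASL acquisition / kinetic-model parameters
#'
#' Constants of the single-compartment pCASL kinetic model. Defaults follow
#' the acquisition emulated by the synthetic cohort: labeling duration and
#' post-labeling delay of 1.8 s and labeling efficiency 0.72. Blood T1
#' (1.65 s) and the blood-brain partition coefficient (0.9 mL/g) are the
#' consensus single-compartment values.
#'
#' @param tau labeling duration, s.
#' @param pld post-labeling delay, s.
#' @param alpha labeling efficiency, in (0, 1].
#' @param t1_blood longitudinal relaxation time of arterial blood, s.
#' @param lambda_partition blood-brain partition coefficient, mL/g.
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(tau = 1.8, pld = 1.8, alpha = 0.72,
                               t1_blood = 1.65, lambda_partition = 0.9) {
  stopifnot(tau > 0, pld > 0, alpha > 0, alpha <= 1, t1_blood > 0,
            lambda_partition > 0)
  structure(list(tau = tau, pld = pld, alpha = alpha, t1_blood = t1_blood,
                 lambda_partition = lambda_partition),
            class = "acquisition_params")
}

# Forward kinetic model: labeled signal difference per unit M0-normalised
# perfusion. delta_m = cbf * m0 * kinetic_factor(params).
kinetic_factor <- function(params) {
  with(params,
       2 * alpha * t1_blood * (1 - exp(-tau / t1_blood)) *
         exp(-pld / t1_blood) / (6000 * lambda_partition))
}

#' Quantify CBF from a label-control difference image
#'
#' Single-compartment pCASL closed form:
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\,e^{PLD/T_{1b}}}
#'                  {2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})}}
#' in mL/100g/min. Voxels with non-positive M0 are set to NA (masked).
#'
#' @param delta_m control-minus-label difference volume.
#' @param m0 equilibrium magnetisation volume on the same grid.
#' @param params [acquisition_params()].
#' @return `vol3d` of CBF in mL/100g/min.
#' @export
quantify_cbf <- function(delta_m, m0, params = acquisition_params()) {
  stopifnot(inherits(params, "acquisition_params"))
  if (!vol_same_grid(delta_m, m0)) stop("delta_m and m0 grids differ")
  denom_ok <- m0$data > 0
  cbf <- delta_m
  cbf$data <- with(params,
                   6000 * lambda_partition * delta_m$data * exp(pld / t1_blood) /
                     (2 * alpha * t1_blood * m0$data * (1 - exp(-tau / t1_blood))))
  cbf$data[!denom_ok] <- NA_real_
  cbf
}

#' Pairwise control - label subtraction
#'
#' @param series list of volumes, alternating control/label.
#' @param control_first logical; if TRUE (default) odd positions are control
#'   volumes. The interleaving is data provenance, not an assumption, so it
#'   is an explicit argument.
#' @return list of `length(series) / 2` difference volumes.
#' @export
subtract_pairs <- function(series, control_first = TRUE) {
  n <- length(series)
  if (n %% 2 != 0) stop("series length must be even (label-control pairs)")
  idx_c <- seq(1, n, by = 2)
  idx_l <- seq(2, n, by = 2)
  if (!control_first) { tmp <- idx_c; idx_c <- idx_l; idx_l <- tmp }
  lapply(seq_len(n / 2), function(i) {
    dm <- series[[idx_c[i]]]
    if (!vol_same_grid(dm, series[[idx_l[i]]])) stop("pair grids differ")
    dm$data <- dm$data - series[[idx_l[i]]]$data
    dm
  })
}

#' Average a CBF time series
#'
#' Voxelwise arithmetic mean over surviving label-control pairs.
#' @param cbf_series list of CBF volumes.
#' @param params params used for quantification (stored as provenance).
#' @return list of class `cbf_map`: `volume`, `params_used`, `n_pairs`.
#' @export
mean_cbf <- function(cbf_series, params = acquisition_params()) {
  if (length(cbf_series) < 1) stop("empty CBF series")
  out <- cbf_series[[1]]
  if (length(cbf_series) > 1) {
    acc <- out$data
    for (i in seq_along(cbf_series)[-1]) {
      if (!vol_same_grid(out, cbf_series[[i]])) stop("series grids differ")
      acc <- acc + cbf_series[[i]]$data
    }
    out$data <- acc / length(cbf_series)
  }
  structure(list(volume = out, params_used = params,
                 n_pairs = length(cbf_series)),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  cat(sprintf("cbf_map over %d pairs; ", x$n_pairs)); print(x$volume)
  invisible(x)
}

#' Rigid head-motion correction of an ASL series
#'
#' Registers every volume to the reference volume with the package's rigid
#' 6-DOF intensity engine and resamples it once (trilinear). Volumes whose
#' registration fails (cost not reduced while the recovered displacement
#' exceeds half the field of view) are dropped and reported.
#'
#' @param series list of volumes on a common grid.
#' @param reference_index index of the reference volume.
#' @param control control list for the rigid engine (see [rigid_register()]);
#'   the default uses a light two-level pyramid suited to within-series
#'   motion.
#' @return list with `series` (corrected volumes), `transforms` (one
#'   `rigid_transform` per input volume; dropped volumes keep theirs),
#'   `dropped` (integer indices), `log` (character).
#' @export
motion_correct <- function(series, reference_index = 1,
                           control = list(strides = c(2, 1),
                                          steps = c(2, 0.5),
                                          step_tol = 0.02)) {
  if (length(series) < 2) stop("need at least 2 volumes")
  ref <- series[[reference_index]]
  fov <- max(dim(ref$data) * vol_spacing(ref))
  out <- series
  transforms <- vector("list", length(series))
  dropped <- integer(0)
  log <- character(0)
  for (i in seq_along(series)) {
    if (i == reference_index) {
      transforms[[i]] <- rigid_transform()
      next
    }
    if (!vol_same_grid(series[[i]], ref)) stop("series volumes on different grids")
    res <- rigid_register(series[[i]], ref, control = control)
    transforms[[i]] <- res$transform
    disp <- rt_error(res$transform, rigid_transform())[["trans_mm"]]
    if (!res$converged && disp > 0.5 * fov) {
      dropped <- c(dropped, i)
      log <- c(log, sprintf("volume %d dropped: cost not reduced, displacement %.1f mm", i, disp))
      next
    }
    # skip resampling when the recovered motion is negligible
    err <- rt_error(res$transform, rigid_transform())
    if (err[["trans_mm"]] > 1e-6 || err[["rot_deg"]] > 1e-6)
      out[[i]] <- apply_transform(series[[i]], res$transform, target = ref)
  }
  if (length(dropped)) out <- out[-dropped]
  list(series = out, transforms = transforms, dropped = dropped, log = log)
}

#' Full quantification of an ASL series
#'
#' Convenience wrapper: optional motion correction, control - label
#' subtraction, voxelwise kinetic quantification per pair, and time-series
#' averaging.
#' @param series list of 2n volumes, alternating control/label.
#' @param m0 M0 volume on the series grid.
#' @param params [acquisition_params()].
#' @param control_first interleaving flag passed to [subtract_pairs()].
#' @param motion_correct logical; run rigid motion correction first.
#' @return `cbf_map`.
#' @export
quantify_series <- function(series, m0, params = acquisition_params(),
                            control_first = TRUE, motion_correct = FALSE) {
  if (motion_correct) {
    mc <- motion_correct(series)
    series <- mc$series
    if (length(series) %% 2 != 0)
      series <- series[seq_len(length(series) - 1)]
  }
  dm <- subtract_pairs(series, control_first = control_first)
  cbf <- lapply(dm, quantify_cbf, m0 = m0, params = params)
  mean_cbf(cbf, params = params)
}
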