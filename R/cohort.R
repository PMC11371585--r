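#' Group effect specification
#'
#' Describes how a participant group deviates from the control phantom:
#' a multiplicative CBF reduction and an atrophic GM thinning in a set of
#' affected parcels, plus a linear coupling between a severity score and
#' CBF in those parcels. Controls must have no affected parcels and severity
#' fixed at 0.
#'
#' @param group one of `"control"`, `"tau_like"`, `"tdp_like"`.
#' @param affected_rois integer parcel ids carrying the effect.
#' @param cbf_reduction_fraction fraction in `[0, 1)` removed from baseline
#'   GM CBF in affected parcels.
#' @param atrophy_thinning_mm GM ribbon thinning (mm, >= 0) in affected
#'   parcels.
#' @param severity_slope CBF change per severity unit (mL/100g/min per
#'   FTLD-CDR-like point; negative for an inverse association).
#' @param severity_noise_sd SD of the additive noise on the severity-coupled
#'   CBF shift (per participant per affected parcel).
#' @param severity_range range the severity score is drawn from (uniform)
#'   for non-control groups.
#' @return list of class `group_effect_spec`.
#' @export
group_effect_spec <- function(group = c("control", "tau_like", "tdp_like"),
                              affected_rois = integer(0),
                              cbf_reduction_fraction = 0,
                              atrophy_thinning_mm = 0,
                              severity_slope = 0,
                              severity_noise_sd = 0,
                              severity_range = c(1, 12)) {
  group <- match.arg(group)
  stopifnot(cbf_reduction_fraction >= 0, cbf_reduction_fraction < 1,
            atrophy_thinning_mm >= 0, severity_noise_sd >= 0)
  if (group == "control" && length(affected_rois) > 0)
    stop("controls must have no affected ROIs")
  structure(list(group = group,
                 affected_rois = as.integer(affected_rois),
                 cbf_reduction_fraction = cbf_reduction_fraction,
                 atrophy_thinning_mm = atrophy_thinning_mm,
                 severity_slope = severity_slope,
                 severity_noise_sd = severity_noise_sd,
                 severity_range = severity_range),
            class = "group_effect_spec")
}

# Deterministic seed stream: master seed -> participant -> stage, kept below
# 2^31 so downstream set.seed() calls stay valid R integers.
derive_seed <- function(master, participant = 0L, stage = 0L) {
  as.integer((as.numeric(master) * 7919 + participant * 104729 + stage * 1299709) %% 2147483647)
}

#' Ground-truth CBF map with group effects applied
#'
#' Builds the voxelwise true CBF map on the structural grid: GM/WM baselines
#' with, in affected parcels, a multiplicative reduction plus the linear
#' severity coupling (`baseline * (1 - reduction) + slope * severity +
#' noise`). GM voxels are attributed to parcels through the nearest boundary
#' vertex.
#'
#' @param tissue_labels structural-grid tissue label volume.
#' @param boundary `boundary_surface`.
#' @param parcellation [build_parcellation()] output (or NULL for no
#'   regional effects).
#' @param spec [phantom_spec()].
#' @param effect [group_effect_spec()].
#' @param severity participant severity score.
#' @param seed seed for the per-parcel severity-coupling noise.
#' @param gm_parcel_idx optional precomputed parcel id per GM voxel (in the
#'   order of `which(tissue_labels == 2)`); avoids recomputing the
#'   nearest-vertex assignment for every participant sharing a geometry.
#' @return list: `cbf` (vol3d), `roi_effect_table` (data.frame parcel /
#'   applied_reduction / severity_shift).
#' @export
make_true_cbf <- function(tissue_labels, boundary, parcellation = NULL,
                          spec, effect = group_effect_spec("control"),
                          severity = 0, seed = 1L, gm_parcel_idx = NULL) {
  cbf <- tissue_labels
  cbf$data <- array(0, dim = dim(tissue_labels$data))
  gm_idx <- which(tissue_labels$data == 2L)
  gm_pts <- voxel_to_world(tissue_labels, arrayInd(gm_idx, dim(tissue_labels$data)) - 1)
  gm_dir <- gm_pts / pmax(sqrt(rowSums(gm_pts^2)), 1e-12)
  ang <- dir_angles(gm_dir)
  # shared angular perfusion texture: identical across participants
  tex <- 1 + spec$cbf_texture * angular_pattern(ang$theta, ang$phi, "texture")
  cbf$data[gm_idx] <- spec$gm_cbf_baseline * tex
  cbf$data[tissue_labels$data == 3L] <- spec$wm_cbf_baseline
  rois <- effect$affected_rois
  tab <- data.frame(parcel = integer(0), applied_reduction = numeric(0),
                    severity_shift = numeric(0))
  if (length(rois) > 0) {
    if (is.null(parcellation)) stop("regional effects need a parcellation")
    if (!all(rois %in% seq_len(parcellation$n_parcels)))
      stop("affected ROIs outside the parcellation label range")
    set.seed(derive_seed(seed, stage = 3L))
    vparc <- if (is.null(gm_parcel_idx))
      parcellation$labels[nearest_vertex(gm_pts, boundary$vertices)]
    else gm_parcel_idx
    shifts <- effect$severity_slope * severity +
      stats::rnorm(length(rois), 0, effect$severity_noise_sd)
    for (j in seq_along(rois)) {
      sel <- gm_idx[vparc == rois[j]]
      cbf$data[sel] <- pmax(0, cbf$data[sel] * (1 - effect$cbf_reduction_fraction) + shifts[j])
    }
    tab <- data.frame(parcel = rois,
                      applied_reduction = effect$cbf_reduction_fraction,
                      severity_shift = shifts)
  }
  list(cbf = cbf, roi_effect_table = tab)
}

#' Simulate a pCASL label/control series plus M0
#'
#' Forward model of the acquisition: the true CBF map (T1w space) is carried
#' into the participant's ASL space through the inverse of the true ASL->T1w
#' transform, converted to a label-control difference with the closed-form
#' kinetic model (the exact inverse of [quantify_cbf()]), and emitted as 14
#' control/label pairs (28 volumes). Each volume carries the static tissue
#' signal modulated by a per-volume multiplicative radial sinusoid (the
#' "ringing" artifact, which cancels exactly in control - label subtraction)
#' plus additive Gaussian noise. The M0 volume is noise-free.
#'
#' @param tissue_labels structural-grid tissue labels (for the head mask).
#' @param true_cbf true CBF `vol3d` on the structural grid (T1w space).
#' @param params [acquisition_params()].
#' @param spec [phantom_spec()].
#' @param true_transform rigid ASL->T1w ground-truth transform.
#' @param n_pairs number of label-control pairs (default 14).
#' @param seed integer seed.
#' @return list: `series` (list of 2 * n_pairs volumes, control first),
#'   `m0`, `cbf_true_asl` (ground-truth CBF resampled onto the ASL grid),
#'   `tissue_labels_asl` (analytic labels on the ASL grid),
#'   `is_control` (logical per volume).
#' @export
generate_asl_series <- function(tissue_labels, true_cbf,
                                params = acquisition_params(),
                                spec, true_transform = rigid_transform(),
                                n_pairs = 14, seed = 1L) {
  if (!vol_same_grid(tissue_labels, true_cbf))
    stop("tissue labels and true CBF map are on different grids")
  set.seed(derive_seed(seed, stage = 1L))
  labels_asl <- render_tissue_labels(spec, NULL, 0,
                                     dim_ = spec$asl_shape,
                                     spacing = spec$asl_spacing,
                                     world_map = true_transform)
  head_asl <- labels_asl$data > 0L
  cbf_asl <- apply_transform(true_cbf, rt_invert(true_transform), labels_asl)
  cbf_asl$data[!head_asl] <- 0

  m0 <- labels_asl
  m0$data <- array(ifelse(head_asl, spec$m0_value, 0), dim = dim(labels_asl$data))
  dm <- cbf_asl$data * m0$data * kinetic_factor(params)
  static <- 0.8 * m0$data

  r <- sqrt(rowSums(vol_grid_points(labels_asl)^2))
  r <- array(r, dim = dim(labels_asl$data))
  series <- vector("list", 2 * n_pairs)
  is_control <- rep(c(TRUE, FALSE), n_pairs)
  for (p in seq_len(n_pairs)) {
    # the ringing field is an acquisition-state artifact: identical within a
    # label-control pair, so it cancels exactly in the subtraction
    phase <- stats::runif(1, 0, 2 * pi)
    wavelength <- stats::runif(1, 30, 60)
    ringing <- 1 + spec$ringing_amplitude * sin(2 * pi * r / wavelength + phase)
    for (k in 1:2) {
      i <- 2 * (p - 1) + k
      sig <- static * ringing + (if (is_control[i]) 0.5 else -0.5) * dm
      if (spec$noise_sd > 0)
        sig <- sig + array(stats::rnorm(length(sig), 0, spec$noise_sd), dim = dim(sig))
      v <- labels_asl
      v$data <- sig
      series[[i]] <- v
    }
  }
  list(series = series, m0 = m0, cbf_true_asl = cbf_asl,
       tissue_labels_asl = labels_asl, is_control = is_control)
}

#' Generate a phantom cohort with ground truth
#'
#' Draws one participant after another from a seeded hierarchy (master seed
#' -> participant stream -> stage stream, so adding a participant never
#' perturbs the others): a random true rigid ASL->T1w transform within
#' `+/- max_trans` mm and `+/- max_rot` degrees, group effects applied to the
#' true CBF map, a severity score coupled to affected-parcel CBF, the
#' simulated ASL series, and demographic covariates.
#'
#' @param n_per_group named integer vector, e.g.
#'   `c(control = 50, tau_like = 21, tdp_like = 14)`.
#' @param effects list of [group_effect_spec()], one per group present.
#' @param spec [phantom_spec()].
#' @param parcellation [build_parcellation()] output on the phantom boundary
#'   (built automatically when NULL and any effect is regional).
#' @param seed master integer seed.
#' @param max_trans,max_rot half-ranges of the true transform draw (mm, deg).
#' @param keep_images logical; when FALSE the ASL series/volumes are not
#'   retained (ground truth and metadata only), for combinatorial or
#'   statistical uses that never touch voxel data.
#' @return list of class `cohort`: `records` (one list per participant with
#'   fields id, group, true_transform, severity, age, sex, education,
#'   roi_effect_table, and when kept: series, m0, tissue_labels, true_cbf,
#'   cbf_true_asl), plus shared `boundary`, `parcellation`, `spec`,
#'   `effects`.
#' @export
generate_cohort <- function(n_per_group, effects, spec = phantom_spec(),
                            parcellation = NULL, seed = 1L,
                            max_trans = 5, max_rot = 5,
                            keep_images = TRUE) {
  stopifnot(length(n_per_group) > 0, !is.null(names(n_per_group)))
  eff_by_group <- stats::setNames(effects, vapply(effects, `[[`, "", "group"))
  missing_eff <- setdiff(names(n_per_group), names(eff_by_group))
  if (length(missing_eff))
    stop("no group_effect_spec for group(s): ", paste(missing_eff, collapse = ", "))

  base <- generate_phantom(spec)
  if (is.null(parcellation))
    parcellation <- build_parcellation(base$boundary, seed = derive_seed(seed, stage = 9L))
  for (e in effects)
    if (length(e$affected_rois) &&
        !all(e$affected_rois %in% seq_len(parcellation$n_parcels)))
      stop("affected ROIs not present in the parcellation")

  # GM-voxel -> parcel assignment on the base (unthinned) geometry; thinned
  # GM voxel sets are subsets of it, so per-participant assignments are
  # index lookups rather than fresh nearest-vertex searches.
  gm_idx_base <- which(base$tissue_labels$data == 2L)
  gm_pts_base <- voxel_to_world(base$tissue_labels,
                                arrayInd(gm_idx_base, dim(base$tissue_labels$data)) - 1)
  vparc_base <- parcellation$labels[nearest_vertex(gm_pts_base, base$boundary$vertices)]

  records <- list()
  pid <- 0L
  for (g in names(n_per_group)) {
    e <- eff_by_group[[g]]
    for (k in seq_len(n_per_group[[g]])) {
      pid <- pid + 1L
      pseed <- derive_seed(seed, participant = pid)
      set.seed(pseed)
      tf <- rt_random(max_trans, max_rot)
      severity <- if (g == "control") 0 else stats::runif(1, e$severity_range[1], e$severity_range[2])
      age <- stats::rnorm(1, 65, 8)
      education <- stats::rnorm(1, 15, 2.5)
      sex <- sample(c("M", "F"), 1)
      if (e$atrophy_thinning_mm > 0 && length(e$affected_rois)) {
        # per-participant atrophy severity around the group's mean thinning
        thin_mult <- stats::runif(1, 0.7, 1.3)
        thin <- numeric(nrow(base$boundary$vertices))
        thin[parcellation$labels %in% e$affected_rois] <-
          e$atrophy_thinning_mm * thin_mult
        labels_i <- render_tissue_labels(spec, base$boundary, thin,
                                         dim_ = spec$structural_shape,
                                         spacing = spec$structural_spacing)
      } else {
        labels_i <- base$tissue_labels
      }
      gm_idx_i <- which(labels_i$data == 2L)
      vparc_i <- vparc_base[match(gm_idx_i, gm_idx_base)]
      truth <- make_true_cbf(labels_i, base$boundary, parcellation,
                             spec, e, severity, seed = pseed,
                             gm_parcel_idx = vparc_i)
      rec <- list(id = sprintf("sub-%03d", pid), group = g,
                  true_transform = tf, severity = severity, age = age,
                  sex = sex, education = education,
                  roi_effect_table = truth$roi_effect_table,
                  gm_parcels = vparc_i)
      if (keep_images) {
        acq <- generate_asl_series(labels_i, truth$cbf,
                                   spec = spec, true_transform = tf,
                                   seed = pseed)
        rec <- c(rec, list(series = acq$series, m0 = acq$m0,
                           is_control = acq$is_control,
                           tissue_labels = labels_i,
                           tissue_labels_asl = acq$tissue_labels_asl,
                           true_cbf = truth$cbf,
                           cbf_true_asl = acq$cbf_true_asl))
      }
      records[[pid]] <- rec
    }
  }
  structure(list(records = records, boundary = base$boundary,
                 structural = base$structural,
                 tissue_labels = base$tissue_labels,
                 parcellation = parcellation, spec = spec,
                 effects = eff_by_group),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- table(vapply(x$records, `[[`, "", "group"))
  cat(sprintf("cohort of %d participants (%s)\n", length(x$records),
              paste(sprintf("%s: %d", names(g), g), collapse = ", ")))
  invisible(x)
}

#' Cohort manifest as a data frame
#' @param cohort a `cohort`.
#' @return data.frame: id, group, severity, age, sex, education.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort$records, function(r)
    data.frame(id = r$id, group = r$group, severity = r$severity,
               age = r$age, sex = r$sex, education = r$education,
               stringsAsFactors = FALSE)))
}

#' Draw per-participant ROI-mean CBF tables from the effect model
#'
#' Lightweight generative path for statistical calibration: instead of
#' rendering images, parcel means are drawn directly from the same effect
#' structure used by the voxel pipeline (`baseline * (1 - reduction) +
#' slope * severity + noise` in affected parcels; `baseline + noise`
#' elsewhere). Used for replicate-heavy null / power / regression studies
#' where the imaging stages are irrelevant.
#'
#' @param n_per_group named counts per group.
#' @param effects list of [group_effect_spec()].
#' @param n_parcels number of parcels.
#' @param baseline GM baseline CBF.
#' @param roi_noise_sd between-participant SD of a parcel mean.
#' @param seed integer seed.
#' @return list: `roi_cbf` (participants x parcels matrix),
#'   `manifest` (data.frame id, group, severity).
#' @export
generate_roi_cohort <- function(n_per_group, effects, n_parcels = 219,
                                baseline = 60, roi_noise_sd = 9, seed = 1L) {
  eff_by_group <- stats::setNames(effects, vapply(effects, `[[`, "", "group"))
  set.seed(derive_seed(seed, stage = 5L))
  n_tot <- sum(unlist(n_per_group))
  roi <- matrix(NA_real_, n_tot, n_parcels)
  man <- data.frame(id = character(n_tot), group = character(n_tot),
                    severity = numeric(n_tot), stringsAsFactors = FALSE)
  i <- 0L
  for (g in names(n_per_group)) {
    e <- eff_by_group[[g]]
    for (k in seq_len(n_per_group[[g]])) {
      i <- i + 1L
      severity <- if (g == "control") 0 else stats::runif(1, e$severity_range[1], e$severity_range[2])
      mu <- rep(baseline, n_parcels)
      if (length(e$affected_rois)) {
        mu[e$affected_rois] <- baseline * (1 - e$cbf_reduction_fraction) +
          e$severity_slope * severity +
          stats::rnorm(length(e$affected_rois), 0, e$severity_noise_sd)
      }
      roi[i, ] <- mu + stats::rnorm(n_parcels, 0, roi_noise_sd)
      man$id[i] <- sprintf("sub-%03d", i)
      man$group[i] <- g
      man$severity[i] <- severity
    }
  }
  colnames(roi) <- paste0("parcel_", seq_len(n_parcels))
  list(roi_cbf = roi, manifest = man)
}
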