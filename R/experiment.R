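## End-to-end experiment orchestration: simulate -> quantify -> QC ->
## register (3 methods) -> project -> consistency -> group statistics.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Experiment configuration
#'
#' Bundles every tunable of the end-to-end experiment; a config plus its
#' master seed determines all outputs.
#'
#' @param spec [phantom_spec()].
#' @param params [acquisition_params()].
#' @param n_per_group named participant counts.
#' @param effects list of [group_effect_spec()] (defaults: frontal-pattern
#'   hypoperfusion for `tau_like`, a broader temporal-pattern reduction with
#'   inverse severity coupling for `tdp_like`).
#' @param operator_sd manual-registration operator error, `c(mm, degrees)`.
#' @param bbr [bbr_config()] for the boundary-based refinement.
#' @param rigid_control control list for [rigid_register()].
#' @param qei_threshold QEI exclusion threshold (strict >).
#' @param cc_test `"paired"` or `"two_sample_pooled"` for method
#'   comparisons.
#' @param n_tests Bonferroni family size for ROI tests.
#' @param projection_offset surface sampling offset, mm.
#' @param motion_correction run rigid motion correction on each series. The
#'   simulated series has no inter-volume motion, so this is off by default
#'   and exercised separately.
#' @param n_parcels parcel count of the synthetic parcellation.
#' @param out_dir output directory (NULL for no file output).
#' @param seed master seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(spec = phantom_spec(),
                              params = acquisition_params(),
                              n_per_group = c(control = 6, tau_like = 4,
                                              tdp_like = 4),
                              effects = NULL,
                              operator_sd = c(1, 1),
                              bbr = bbr_config(),
                              rigid_control = list(),
                              qei_threshold = 0.4,
                              cc_test = "paired",
                              n_tests = NULL,
                              projection_offset = 1,
                              motion_correction = FALSE,
                              n_parcels = 219,
                              out_dir = NULL,
                              seed = 1L) {
  if (is.null(effects)) {
    effects <- list(
      group_effect_spec("control"),
      group_effect_spec("tau_like", affected_rois = 1:5,
                        cbf_reduction_fraction = 0.2,
                        atrophy_thinning_mm = 0.5,
                        severity_slope = -1, severity_noise_sd = 2),
      group_effect_spec("tdp_like", affected_rois = 10:17,
                        cbf_reduction_fraction = 0.3,
                        atrophy_thinning_mm = 1,
                        severity_slope = -1.5, severity_noise_sd = 2))
  }
  if (is.null(n_tests)) n_tests <- n_parcels
  structure(list(spec = spec, params = params, n_per_group = n_per_group,
                 effects = effects, operator_sd = operator_sd, bbr = bbr,
                 rigid_control = rigid_control,
                 qei_threshold = qei_threshold, cc_test = cc_test,
                 n_tests = n_tests, projection_offset = projection_offset,
                 motion_correction = motion_correction,
                 n_parcels = n_parcels, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Process one participant through quantification, QC and registration
#'
#' Quantifies the ASL series to a mean CBF map, scores it with the QEI,
#' and produces the three registration-method transforms: emulated-manual,
#' manual+BBR, and FLIRT+BBR (rigid intensity-based initialization refined
#' on the GM-WM boundary). Surface projections and ROI tables are computed
#' per method.
#'
#' @param record a participant record from [generate_cohort()].
#' @param cohort the `cohort` the record belongs to (for the shared boundary
#'   and parcellation).
#' @param config [experiment_config()].
#' @param pid participant index used for seed derivation.
#' @param roi_volume_table optional precomputed ROI volume table (shared by
#'   all participants with the same tissue geometry).
#' @return the record augmented with `cbf`, `quality`, `transforms`
#'   (named list), `registration` (results / failure flags), `surface_maps`,
#'   `roi_cbf` (per method), `roi_volume`.
#' @export
process_participant <- function(record, cohort, config, pid = 1L,
                                roi_volume_table = NULL) {
  cbf <- quantify_series(record$series, record$m0, config$params,
                         motion_correct = config$motion_correction)
  quality <- compute_qei(cbf, record$tissue_labels_asl,
                         threshold = config$qei_threshold)

  manual <- emulate_manual(record$true_transform, config$operator_sd,
                           seed = derive_seed(config$seed, pid, 11L))
  failures <- character(0)
  flirt <- tryCatch(
    rigid_register(cbf$volume, cohort$structural, control = config$rigid_control),
    error = function(e) NULL)
  if (is.null(flirt) || !flirt$converged)
    failures <- c(failures, "flirt")
  refine <- function(init, label) {
    tryCatch(bbr_refine(init, cbf$volume, cohort$boundary, config$bbr,
                        method = label),
             error = function(e) NULL)
  }
  manual_bbr <- refine(manual, "manual+BBR")
  flirt_bbr <- if (!is.null(flirt)) refine(flirt$transform, "FLIRT+BBR") else NULL
  if (is.null(manual_bbr)) failures <- c(failures, "manual+BBR")
  if (is.null(flirt_bbr)) failures <- c(failures, "FLIRT+BBR")

  transforms <- list(manual = manual)
  if (!is.null(manual_bbr)) transforms[["manual+BBR"]] <- manual_bbr$transform
  if (!is.null(flirt_bbr)) transforms[["FLIRT+BBR"]] <- flirt_bbr$transform

  surface_maps <- list()
  roi_cbf <- list()
  for (m in names(transforms)) {
    sm <- project_to_surface(cbf, transforms[[m]], cohort$boundary,
                             projection_offset = config$projection_offset,
                             method = m, id = record$id)
    surface_maps[[m]] <- sm
    roi_cbf[[m]] <- roi_mean_cbf(sm, cohort$parcellation)
  }
  record$cbf <- cbf
  record$quality <- quality
  record$qei <- quality$qei
  record$transforms <- transforms
  record$registration <- list(flirt = flirt, manual_bbr = manual_bbr,
                              flirt_bbr = flirt_bbr, failures = failures)
  record$surface_maps <- surface_maps
  record$roi_cbf <- roi_cbf
  record$roi_volume <- if (!is.null(roi_volume_table)) roi_volume_table
    else roi_volume(record$tissue_labels, cohort$parcellation,
                    cohort$boundary, voxel_parcels = record$gm_parcels)
  record
}

# Stack per-participant ROI tables into a participants x parcels matrix.
roi_matrix <- function(records, method, field = "roi_cbf") {
  vals <- lapply(records, function(r) {
    tab <- if (field == "roi_cbf") r$roi_cbf[[method]] else r$roi_volume
    if (field == "roi_cbf") tab$mean_cbf else tab$volume_mm3
  })
  m <- do.call(rbind, vals)
  rownames(m) <- vapply(records, `[[`, "", "id")
  m
}

#' Run the full registration-evaluation experiment
#'
#' Simulates a cohort, quantifies and quality-gates each participant,
#' registers every mean-CBF map to the structural phantom with the three
#' methods, projects CBF to the boundary surface, evaluates registration
#' consistency (pairwise CC, mean participant CC, method and group
#' comparisons), and runs the ROI group statistics (hypoperfusion and
#' atrophy t-tests with Bonferroni control, severity regression,
#' demographics). When `config$out_dir` is set, stage outputs are written as
#' TSV plus a JSON run report.
#'
#' @param config [experiment_config()].
#' @return list of class `experiment_report`; see elements `cohort`,
#'   `records` (processed, QEI-kept), `excluded`, `failed_registration`,
#'   `cc_sets`, `participant_cc`, `method_comparisons`,
#'   `group_cc_comparisons`, `roi_tests`, `volume_tests`,
#'   `severity_fits`, `demographics`, `log`.
#' @export
run_experiment <- function(config = experiment_config()) {
  log <- character(0)
  cohort <- generate_cohort(config$n_per_group, config$effects, config$spec,
                            seed = config$seed)
  if (config$n_parcels != cohort$parcellation$n_parcels)
    cohort$parcellation <- build_parcellation(cohort$boundary,
                                              n_parcels = config$n_parcels,
                                              seed = derive_seed(config$seed, stage = 9L))
  processed <- vector("list", length(cohort$records))
  for (i in seq_along(cohort$records)) {
    processed[[i]] <- process_participant(cohort$records[[i]], cohort,
                                          config, pid = i)
    # free the raw series once quantified
    processed[[i]]$series <- NULL
  }

  flt <- filter_by_qei(processed, config$qei_threshold)
  log <- c(log, flt$log)
  kept <- flt$kept
  reg_ok <- vapply(kept, function(r) length(r$registration$failures) == 0,
                   logical(1))
  for (r in kept[!reg_ok])
    log <- c(log, sprintf("excluded %s: registration failed (%s)", r$id,
                          paste(r$registration$failures, collapse = ", ")))
  n_reg_failed <- sum(!reg_ok)
  kept <- kept[reg_ok]
  groups <- vapply(kept, `[[`, "", "group")
  methods <- Reduce(intersect, lapply(kept, function(r) names(r$surface_maps)))

  cc_sets <- list()
  participant_cc <- list()
  for (m in methods) {
    for (g in unique(groups)) {
      sel <- kept[groups == g]
      if (length(sel) < 2) next
      key <- paste(g, m, sep = "/")
      cc_sets[[key]] <- pairwise_cc(lapply(sel, function(r) r$surface_maps[[m]]),
                                    group = g, method = m)
      participant_cc[[key]] <- mean_participant_cc(cc_sets[[key]])
    }
    if (!is.null(cc_sets[[paste("tau_like", m, sep = "/")]]) &&
        !is.null(cc_sets[[paste("tdp_like", m, sep = "/")]])) {
      key <- paste("patients", m, sep = "/")
      cc_sets[[key]] <- combine_patient_groups(
        cc_sets[[paste("tau_like", m, sep = "/")]],
        cc_sets[[paste("tdp_like", m, sep = "/")]])
      participant_cc[[key]] <- mean_participant_cc(cc_sets[[key]])
    }
  }

  method_comparisons <- list()
  if (length(methods) >= 2) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    for (g in unique(c(groups, "patients"))) {
      for (pr in pairs) {
        a <- cc_sets[[paste(g, pr[1], sep = "/")]]
        b <- cc_sets[[paste(g, pr[2], sep = "/")]]
        if (is.null(a) || is.null(b)) next
        cmp <- compare_methods(a, b, test_kind = config$cc_test)
        cmp$group <- g
        method_comparisons[[paste(g, pr[1], pr[2], sep = "/")]] <- cmp
      }
    }
  }

  group_cc_comparisons <- list()
  group_pairs <- list(c("control", "patients"), c("control", "tau_like"),
                      c("control", "tdp_like"), c("tau_like", "tdp_like"))
  for (m in methods) {
    for (gp in group_pairs) {
      a <- participant_cc[[paste(gp[1], m, sep = "/")]]
      b <- participant_cc[[paste(gp[2], m, sep = "/")]]
      if (is.null(a) || is.null(b) || nrow(a) < 2 || nrow(b) < 2) next
      cmp <- compare_groups_mean_cc(a, b)
      cmp$method_a <- gp[1]; cmp$method_b <- gp[2]
      group_cc_comparisons[[paste(m, gp[1], gp[2], sep = "/")]] <- cmp
    }
  }

  contrasts <- list(tau_vs_control = c("tau_like", "control"),
                    tdp_vs_control = c("tdp_like", "control"),
                    tdp_vs_tau = c("tdp_like", "tau_like"))
  roi_tests <- list()
  for (m in methods) {
    for (cn in names(contrasts)) {
      ga <- contrasts[[cn]][1]; gb <- contrasts[[cn]][2]
      if (sum(groups == ga) < 2 || sum(groups == gb) < 2) next
      roi_tests[[paste(cn, m, sep = "/")]] <-
        roi_group_ttest(roi_matrix(kept[groups == ga], m),
                        roi_matrix(kept[groups == gb], m),
                        n_tests = config$n_tests)
    }
  }
  volume_tests <- list()
  for (cn in names(contrasts)) {
    ga <- contrasts[[cn]][1]; gb <- contrasts[[cn]][2]
    if (sum(groups == ga) < 2 || sum(groups == gb) < 2) next
    volume_tests[[cn]] <-
      roi_group_ttest(roi_matrix(kept[groups == ga], NULL, "roi_volume"),
                      roi_matrix(kept[groups == gb], NULL, "roi_volume"),
                      n_tests = config$n_tests)
  }

  severity_fits <- list()
  sev_method <- if ("FLIRT+BBR" %in% methods) "FLIRT+BBR" else methods[1]
  for (g in c("tau_like", "tdp_like")) {
    sel <- kept[groups == g]
    if (length(sel) < 3) next
    sev <- vapply(sel, `[[`, numeric(1), "severity")
    if (stats::var(sev) == 0) next
    severity_fits[[g]] <- severity_regression(roi_matrix(sel, sev_method), sev)
  }

  manifest <- cohort_manifest(cohort)
  demographics <- tryCatch(compare_demographics(manifest),
                           error = function(e) NULL)

  report <- structure(list(cohort = cohort, records = kept,
                           excluded = flt$excluded,
                           n_registration_failed = n_reg_failed,
                           cc_sets = cc_sets,
                           participant_cc = participant_cc,
                           method_comparisons = method_comparisons,
                           group_cc_comparisons = group_cc_comparisons,
                           roi_tests = roi_tests,
                           volume_tests = volume_tests,
                           severity_fits = severity_fits,
                           demographics = demographics,
                           manifest = manifest,
                           methods = methods,
                           config = config, log = log),
                      class = "experiment_report")
  if (!is.null(config$out_dir)) write_experiment_outputs(report, config$out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: %d kept / %d excluded by QEI / %d registration failures\n",
              length(x$records), length(x$excluded), x$n_registration_failed))
  for (m in x$methods) {
    cc <- unlist(lapply(x$participant_cc[paste(unique(x$manifest$group), m, sep = "/")],
                        function(p) if (!is.null(p)) p$mean_cc))
    if (length(cc))
      cat(sprintf("  %-12s mean participant CC %.4f\n", m, mean(cc)))
  }
  invisible(x)
}

# Flatten and write the report's tables plus a JSON summary.
write_experiment_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$manifest, file.path(out_dir, "manifest.tsv"))
  qual <- do.call(rbind, lapply(report$records, function(r)
    data.frame(id = r$id, qei = r$quality$qei,
               structural_correlation = r$quality$structural_correlation,
               spatial_cv = r$quality$spatial_cv,
               negative_gm_fraction = r$quality$negative_gm_fraction,
               passed = r$quality$passed)))
  write_tsv(qual, file.path(out_dir, "quality.tsv"))
  cc_long <- do.call(rbind, lapply(report$cc_sets, function(s)
    cbind(group = s$group, method = s$method, s$pairs)))
  if (!is.null(cc_long)) write_tsv(cc_long, file.path(out_dir, "pairwise_cc.tsv"))
  pcc <- do.call(rbind, report$participant_cc)
  if (!is.null(pcc)) write_tsv(pcc, file.path(out_dir, "participant_cc.tsv"))
  mc <- do.call(rbind, lapply(report$method_comparisons, function(x)
    data.frame(group = x$group, method_a = x$method_a, method_b = x$method_b,
               t = x$t_statistic, df = x$df, p = x$p_value, d = x$cohens_d,
               test = x$test_kind)))
  if (!is.null(mc)) write_tsv(mc, file.path(out_dir, "method_comparisons.tsv"))
  for (key in names(report$roi_tests))
    write_tsv(report$roi_tests[[key]]$table,
              file.path(out_dir, paste0("roi_cbf_", gsub("[/+]", "_", key), ".tsv")))
  for (key in names(report$volume_tests))
    write_tsv(report$volume_tests[[key]]$table,
              file.path(out_dir, paste0("roi_volume_", key, ".tsv")))
  for (g in names(report$severity_fits))
    write_tsv(report$severity_fits[[g]],
              file.path(out_dir, paste0("severity_regression_", g, ".tsv")))
  if (!is.null(report$demographics))
    write_tsv(report$demographics, file.path(out_dir, "demographics.tsv"))
  tf_dir <- file.path(out_dir, "transforms")
  dir.create(tf_dir, showWarnings = FALSE)
  for (r in report$records)
    for (m in names(r$transforms)) {
      tf <- r$transforms[[m]]
      mat <- if (is.matrix(tf)) tf else rt_matrix(tf)
      writeLines(apply(mat, 1, function(x) paste(formatC(x, format = "g", digits = 17),
                                                 collapse = " ")),
                 file.path(tf_dir, sprintf("%s_%s.txt", r$id, gsub("[+]", "-", m))))
    }
  summary <- list(
    n_kept = length(report$records),
    n_excluded_qei = length(report$excluded),
    n_registration_failed = report$n_registration_failed,
    mean_participant_cc = lapply(stats::setNames(report$methods, report$methods),
      function(m) {
        keys <- names(report$participant_cc)[endsWith(names(report$participant_cc),
                                                      paste0("/", m))]
        vals <- unlist(lapply(report$participant_cc[keys], `[[`, "mean_cc"))
        if (length(vals)) mean(vals) else NA_real_
      }),
    significant_rois = lapply(report$roi_tests, function(t)
      sum(t$table$significant_fwe, na.rm = TRUE)),
    log = report$log)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a miniature single-participant dataset
#'
#' Generates one small phantom participant (structural and tissue volumes,
#' 28-volume ASL series, M0, boundary surface, ground-truth JSON, manifest)
#' for demonstrations and quick pipeline checks. Volumes are written as
#' NIfTI-1, the surface as plain-text TSV, the truth as a JSON sidecar.
#'
#' @param seed integer seed.
#' @param dir output directory (created; default a temporary directory).
#' @return invisibly, a list with the paths and the in-memory objects.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("aslregsim_fixture_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- phantom_spec(structural_shape = c(28, 28, 28), structural_spacing = 4,
                       asl_shape = c(20, 20, 18), asl_spacing = 5,
                       wm_semiaxes = c(28, 32, 24), gm_thickness = 7,
                       csf_thickness = 4, mesh_rings = 16, mesh_segments = 32,
                       noise_sd = 0, ringing_amplitude = 0, seed = seed)
  ph <- generate_phantom(spec)
  set.seed(derive_seed(seed, stage = 2L))
  truth_tf <- rt_random(3, 3)
  truth <- make_true_cbf(ph$tissue_labels, ph$boundary, NULL, spec,
                         group_effect_spec("control"), seed = seed)
  acq <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec,
                             true_transform = truth_tf, seed = seed)
  vol_write_nifti(ph$structural, file.path(dir, "structural.nii.gz"))
  vol_write_nifti(ph$tissue_labels, file.path(dir, "tissue_labels.nii.gz"))
  vol_write_nifti(acq$m0, file.path(dir, "m0.nii.gz"))
  for (i in seq_along(acq$series))
    vol_write_nifti(acq$series[[i]], file.path(dir, sprintf("asl_%02d.nii.gz", i)))
  surface_write(ph$boundary, file.path(dir, "boundary.tsv"))
  jsonlite::write_json(list(rotation = truth_tf$rotation,
                            translation = truth_tf$translation,
                            center = truth_tf$center,
                            is_control = acq$is_control,
                            gm_cbf = spec$gm_cbf_baseline,
                            wm_cbf = spec$wm_cbf_baseline),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  write_tsv(data.frame(volume = sprintf("asl_%02d.nii.gz", seq_along(acq$series)),
                       type = ifelse(acq$is_control, "control", "label")),
            file.path(dir, "series_manifest.tsv"))
  invisible(list(dir = dir, spec = spec, phantom = ph, truth_transform = truth_tf,
                 true_cbf = truth$cbf, cbf_true_asl = acq$cbf_true_asl,
                 series = acq$series, m0 = acq$m0,
                 is_control = acq$is_control))
}
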