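test_that("the simulated series has 14 label-control pairs (28 volumes)", {
  acq <- tiny_noiseless_acq()
  expect_length(acq$series, 28)
  expect_identical(acq$is_control, rep(c(TRUE, FALSE), 14))
  expect_length(subtract_pairs(acq$series), 14)
})

test_that("series generation is bit-identical under the same seed", {
  spec <- tiny_spec()
  ph <- tiny_phantom()
  truth <- make_true_cbf(ph$tissue_labels, ph$boundary, NULL, spec,
                         group_effect_spec("control"))
  a <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec, seed = 5)
  b <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec, seed = 5)
  for (i in seq_along(a$series))
    expect_identical(a$series[[i]]$data, b$series[[i]]$data)
  expect_identical(a$m0$data, b$m0$data)
})

test_that("zero-noise forward simulation quantifies back to the true CBF map", {
  acq <- tiny_noiseless_acq()
  cm <- quantify_series(acq$series, acq$m0)
  mask <- acq$m0$data > 0
  rel <- max(abs(cm$volume$data[mask] - acq$cbf_true_asl$data[mask])) /
    max(acq$cbf_true_asl$data)
  expect_lt(rel, 1e-6)
})

test_that("ringing modulates raw volumes but cancels in the subtraction", {
  spec <- tiny_spec(noise_sd = 0.5, ringing_amplitude = 0.2)
  ph <- tiny_phantom()
  truth <- make_true_cbf(ph$tissue_labels, ph$boundary, NULL, spec,
                         group_effect_spec("control"))
  acq <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec, seed = 9)
  # raw control volumes differ between pairs by far more than noise
  d_raw <- max(abs(acq$series[[1]]$data - acq$series[[3]]$data))
  expect_gt(d_raw, 20 * spec$noise_sd)
  # after subtraction the residual from the true difference signal is
  # noise-only: bounded by 5 noise SDs (per-volume noise enters twice)
  dm <- subtract_pairs(acq$series)
  dm_true <- acq$cbf_true_asl$data * acq$m0$data *
    aslregsim:::kinetic_factor(acquisition_params())
  for (i in c(1, 7, 14))
    expect_lt(max(abs(dm[[i]]$data - dm_true)), 5 * sqrt(2) * spec$noise_sd)
})

test_that("noisy cohorts recover the GM baseline on average", {
  # default ASL acquisition geometry (3.75 mm, 14 pairs) at study noise;
  # the core of the GM ribbon (3 mm margin) avoids partial-volume dilution
  spec <- std_spec()
  ph <- std_phantom()
  truth <- make_true_cbf(ph$tissue_labels, ph$boundary, NULL, spec,
                         group_effect_spec("control"))
  stats_ <- vapply(1:20, function(k) {
    tf <- { set.seed(1000 + k); rt_random(5, 5) }
    acq <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec,
                               true_transform = tf, seed = 1000 + k)
    cm <- quantify_series(acq$series, acq$m0)
    pts_t1 <- rt_apply(tf, vol_grid_points(cm$volume))
    r <- sqrt(rowSums(pts_t1^2))
    rb <- boundary_radius(pts_t1 / pmax(r, 1e-9), spec)
    core <- r > rb + 3 & r < rb + spec$gm_thickness - 3
    c(mean(cm$volume$data[core]), mean(acq$cbf_true_asl$data[core]))
  }, numeric(2))
  # cohort-mean recovered GM CBF sits within 2 mL/100g/min of the 60
  # baseline, and quantification adds no bias beyond the forward model
  expect_lt(abs(mean(stats_[1, ]) - spec$gm_cbf_baseline), 2)
  expect_lt(abs(mean(stats_[1, ] - stats_[2, ])), 0.5)
})

test_that("cohort generation respects group sizes and reproducibility", {
  spec <- tiny_spec()
  effects <- list(group_effect_spec("control"),
                  group_effect_spec("tau_like", affected_rois = 1:3,
                                    cbf_reduction_fraction = 0.2),
                  group_effect_spec("tdp_like", affected_rois = 5:7,
                                    cbf_reduction_fraction = 0.3))
  co <- generate_cohort(c(control = 50, tau_like = 21, tdp_like = 14),
                        effects, spec, seed = 3, keep_images = FALSE)
  expect_length(co$records, 85)
  counts <- table(vapply(co$records, `[[`, "", "group"))
  expect_identical(as.integer(counts[c("control", "tau_like", "tdp_like")]),
                   c(50L, 21L, 14L))
  # controls carry zero severity, patients positive scores
  sev <- cohort_manifest(co)
  expect_true(all(sev$severity[sev$group == "control"] == 0))
  expect_true(all(sev$severity[sev$group != "control"] > 0))
  co2 <- generate_cohort(c(control = 50, tau_like = 21, tdp_like = 14),
                         effects, spec, seed = 3, keep_images = FALSE)
  expect_identical(cohort_manifest(co2), sev)
  expect_identical(co2$records[[60]]$roi_effect_table,
                   co$records[[60]]$roi_effect_table)
})

test_that("injected ROI reductions are realised in the true CBF maps", {
  spec <- tiny_spec()
  ph <- tiny_phantom()
  parc <- tiny_parcellation()
  eff <- group_effect_spec("tdp_like", affected_rois = c(5, 6, 7),
                           cbf_reduction_fraction = 0.3)
  gm_idx <- which(ph$tissue_labels$data == 2L)
  gm_pts <- voxel_to_world(ph$tissue_labels,
                           arrayInd(gm_idx, dim(ph$tissue_labels$data)) - 1)
  vparc <- parc$labels[aslregsim:::nearest_vertex(gm_pts, ph$boundary$vertices)]
  ctrl <- make_true_cbf(ph$tissue_labels, ph$boundary, parc, spec,
                        group_effect_spec("control"))
  pat <- make_true_cbf(ph$tissue_labels, ph$boundary, parc, spec, eff,
                       severity = 0, gm_parcel_idx = vparc)
  sel <- gm_idx[vparc %in% c(5, 6, 7)]
  ratio <- mean(pat$cbf$data[sel]) / mean(ctrl$cbf$data[sel])
  expect_equal(ratio, 0.7, tolerance = 1e-9)
  other <- gm_idx[!vparc %in% c(5, 6, 7)]
  expect_equal(pat$cbf$data[other], ctrl$cbf$data[other])
})

test_that("mismatched grids and bad ROI sets are rejected", {
  spec <- tiny_spec()
  ph <- tiny_phantom()
  wrong <- vol_empty(c(16, 16, 16), spacing = 4)
  expect_error(generate_asl_series(ph$tissue_labels, wrong, spec = spec),
               "different grids")
  parc <- tiny_parcellation()
  expect_error(
    generate_cohort(c(control = 2, tau_like = 2),
                    list(group_effect_spec("control"),
                         group_effect_spec("tau_like", affected_rois = 5000L,
                                           cbf_reduction_fraction = 0.2)),
                    spec, parcellation = parc, seed = 1, keep_images = FALSE),
    "parcellation")
})
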