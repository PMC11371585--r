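test_that("projection of a constant volume yields that constant at every valid vertex", {
  ph <- tiny_phantom()
  vol <- vol_empty(c(40, 40, 40), spacing = 4, value = 17.5)
  sm <- project_to_surface(vol, rigid_transform(), ph$boundary)
  expect_equal(sm$values[sm$valid], rep(17.5, sum(sm$valid)),
               tolerance = 1e-12)
})

test_that("projection samples the offset vertex positions exactly (linear ramp)", {
  ph <- tiny_phantom()
  vol <- vol_empty(c(40, 40, 40), spacing = 4)
  pts <- vol_grid_points(vol)
  vol$data <- array(pts[, 1], dim = dim(vol$data))  # f(x, y, z) = x
  off <- 1
  sm <- project_to_surface(vol, rigid_transform(), ph$boundary,
                           projection_offset = off)
  expected <- ph$boundary$vertices[, 1] + off * ph$boundary$normals[, 1]
  expect_lt(max(abs(sm$values[sm$valid] - expected[sm$valid])), 1e-6)

  # through a rigid transform the sampled point is transform^-1(vertex+offset)
  tf <- rigid_transform(c(0, 0, 10), c(5, -3, 2))
  sm2 <- project_to_surface(vol, tf, ph$boundary, projection_offset = off)
  mapped <- rt_apply(rt_invert(tf),
                     ph$boundary$vertices + off * ph$boundary$normals)
  expect_lt(max(abs(sm2$values[sm2$valid] - mapped[sm2$valid, 1])), 1e-6)
})

test_that("projection equivariance: moving both volume and transform together", {
  case <- std_case()
  sm_a <- project_to_surface(case$cbf, case$true_transform,
                             case$phantom$boundary)
  # resample the CBF map into T1w space and project with the identity;
  # the mid-GM sampling point sits in the partial-volume gradient zone, so
  # the extra trilinear pass shifts values by a within-voxel-blur amount
  vol <- case$cbf$volume
  vol$data[is.na(vol$data)] <- 0
  moved <- apply_transform(vol, case$true_transform,
                           target = case$phantom$structural)
  sm_b <- project_to_surface(moved, rigid_transform(), case$phantom$boundary)
  ok <- sm_a$valid & sm_b$valid
  expect_lt(stats::median(abs(sm_a$values[ok] - sm_b$values[ok])), 2)
  expect_gt(stats::cor(sm_a$values[ok], sm_b$values[ok]), 0.9)
})

test_that("the parcellation is a deterministic partition into 219 nonempty parcels", {
  parc <- build_parcellation(tiny_phantom()$boundary, n_parcels = 219,
                             seed = 42)
  expect_identical(parc$n_parcels, 219L)
  expect_length(parc$labels, nrow(tiny_phantom()$boundary$vertices))
  tab <- table(factor(parc$labels, levels = 1:219))
  expect_true(all(tab >= 1))                      # nonempty
  expect_identical(sum(tab), length(parc$labels)) # partition
  parc2 <- build_parcellation(tiny_phantom()$boundary, n_parcels = 219,
                              seed = 42)
  expect_identical(parc$labels, parc2$labels)
  parc3 <- build_parcellation(tiny_phantom()$boundary, n_parcels = 219,
                              seed = 43)
  expect_false(identical(parc$labels, parc3$labels))
  expect_error(build_parcellation(tiny_phantom()$boundary,
                                  n_parcels = 1e6), "vertices")
})

test_that("ROI means equal a brute-force per-parcel average", {
  ph <- tiny_phantom()
  parc <- tiny_parcellation()
  set.seed(13)
  sm <- structure(list(values = rnorm(nrow(ph$boundary$vertices), 50, 10),
                       valid = runif(nrow(ph$boundary$vertices)) > 0.05),
                  class = "surface_map")
  tab <- roi_mean_cbf(sm, parc)
  expect_identical(nrow(tab), 219L)
  for (p in sample(219, 12)) {
    sel <- parc$labels == p & sm$valid
    if (any(sel))
      expect_equal(tab$mean_cbf[p], mean(sm$values[sel]), tolerance = 1e-12)
    else
      expect_true(is.na(tab$mean_cbf[p]))
  }
  # constant map: every ROI mean is the constant
  smc <- structure(list(values = rep(3.25, length(sm$values)),
                        valid = rep(TRUE, length(sm$values))),
                   class = "surface_map")
  expect_true(all(roi_mean_cbf(smc, parc)$mean_cbf == 3.25))
})

test_that("ROI volumes conserve total GM volume and respond to thinning", {
  spec <- tiny_spec()
  ph <- tiny_phantom()
  parc <- tiny_parcellation()
  tab <- roi_volume(ph$tissue_labels, parc, ph$boundary)
  expect_identical(nrow(tab), 219L)
  gm_total <- sum(ph$tissue_labels$data == 2L) *
    prod(vol_spacing(ph$tissue_labels))
  expect_equal(sum(tab$volume_mm3), gm_total, tolerance = 1e-9)

  thin <- generate_phantom(spec, thinning_mm = 1)
  tab_thin <- roi_volume(thin$tissue_labels, parc, thin$boundary)
  expect_lt(sum(tab_thin$volume_mm3), sum(tab$volume_mm3))
})
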