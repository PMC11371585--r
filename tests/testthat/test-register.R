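test_that("self-registration recovers the identity", {
  ph <- tiny_phantom()
  res <- rigid_register(ph$structural, ph$structural)
  expect_true(res$converged)
  expect_transform_close(res$transform, rigid_transform(), 0.05, 0.05)
})

test_that("rigid registration recovers a known offset and never increases cost", {
  case <- std_case()
  res <- rigid_register(case$cbf$volume, case$phantom$structural)
  expect_true(res$converged)
  expect_lte(res$final_cost, res$init_cost)
  expect_transform_close(res$transform, case$true_transform, 0.5, 0.5)
})

test_that("registration with no overlap is flagged as failed", {
  ph <- tiny_phantom()
  far <- ph$structural
  far$affine[1:3, 4] <- far$affine[1:3, 4] + 1e4  # moving image 10 m away
  res <- rigid_register(far, ph$structural)
  expect_false(res$converged)
})

test_that("emulated manual registration reproduces truth at zero operator error", {
  tf <- rigid_transform(c(2, -1, 3), c(4, 0, -2))
  expect_identical(emulate_manual(tf, c(0, 0), seed = 1)$rotation, tf$rotation)
  expect_identical(emulate_manual(tf, c(0, 0), seed = 1)$translation, tf$translation)
  a <- emulate_manual(tf, c(1, 1), seed = 5)
  b <- emulate_manual(tf, c(1, 1), seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, emulate_manual(tf, c(1, 1), seed = 6)))
})

test_that("operator-error displacement matches closed-form error propagation", {
  tf <- rigid_transform()
  sd_mm <- 1; sd_deg <- 1
  p <- matrix(c(80, 0, 0), 1)  # head-surface point 80 mm from centre
  disp2 <- vapply(1:1000, function(i) {
    m <- emulate_manual(tf, c(sd_mm, sd_deg), seed = 10000 + i)
    sum((rt_apply(m, p) - p)^2)
  }, numeric(1))
  rms <- sqrt(mean(disp2))
  # E|d|^2 = 3 sd_t^2 + 2 sd_w^2 |r|^2 with sd_w in radians
  expected <- sqrt(3 * sd_mm^2 + 2 * (sd_deg * pi / 180)^2 * 80^2)
  expect_lt(abs(rms - expected) / expected, 0.05)
})

test_that("BBR cost attains its analytic value on a pure two-level contrast", {
  spec <- tiny_spec()
  ph <- tiny_phantom()
  # step image rendered analytically on a fine grid: 60 outside the
  # boundary, 20 inside; a 6 mm normal offset keeps every interpolation
  # corner in pure tissue
  vol <- vol_empty(c(64, 64, 64), spacing = 2)
  pts <- vol_grid_points(vol)
  r <- sqrt(rowSums(pts^2))
  rb <- boundary_radius(pts / pmax(r, 1e-12), spec)
  vol$data <- array(ifelse(r > rb, 60, 20), dim = dim(vol$data))
  cfg <- bbr_config(offset_distance = 6, slope = 0.01)
  got <- as.numeric(bbr_cost(rigid_transform(), vol, ph$boundary, cfg))
  q <- 100 * (60 - 20) / (0.5 * (60 + 20) + cfg$epsilon)
  expect_equal(got, 1 - tanh(cfg$slope * q), tolerance = 1e-6)
  # misalignment strictly increases the cost
  off <- bbr_cost(rigid_transform(translation = c(5, 0, 0)), vol,
                  ph$boundary, cfg)
  expect_gt(as.numeric(off), got)
})

test_that("per-vertex BBR terms match an independent brute-force sampler", {
  case <- tiny_noisy_case()
  cfg <- bbr_config()
  tf <- case$true_transform
  boundary <- case$phantom$boundary
  vol <- case$cbf$volume
  set.seed(12)
  picks <- sample(nrow(boundary$vertices), 10)
  minv <- solve(rt_matrix(tf))
  ainv <- solve(vol$affine)
  manual_sample <- function(world) {
    v <- (ainv %*% c(world, 1))[1:3]
    i0 <- floor(v); f <- v - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * vol$data[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  }
  for (vi in picks) {
    vv <- boundary$vertices[vi, ]
    nn <- boundary$normals[vi, ]
    io <- manual_sample((minv %*% c(vv + cfg$offset_distance * nn, 1))[1:3])
    ii <- manual_sample((minv %*% c(vv - cfg$offset_distance * nn, 1))[1:3])
    q <- 100 * (io - ii) / (0.5 * (io + ii) + cfg$epsilon)
    expected <- 1 - tanh(cfg$slope * cfg$contrast_sign * q)
    sub <- boundary
    sub$vertices <- boundary$vertices[vi, , drop = FALSE]
    sub$normals <- boundary$normals[vi, , drop = FALSE]
    got <- as.numeric(bbr_cost(tf, vol, sub, cfg))
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("BBR refinement stays put at truth and improves a perturbed init", {
  case <- std_case()
  ph <- case$phantom
  at_truth <- bbr_refine(case$true_transform, case$cbf$volume, ph$boundary)
  # translation holds to 0.2 mm; rotation carries the intrinsic
  # curvature bias of symmetric-offset boundary sampling (~0.3 deg at this
  # geometry), so it is bounded at 0.5 deg
  expect_transform_close(at_truth$transform, case$true_transform, 0.2, 0.5)
  expect_lte(at_truth$final_cost, at_truth$init_cost)

  pert <- rt_perturb(case$true_transform, d_rot = c(2, 0, 0),
                     d_trans = c(2, 0, 0))
  init_err <- rt_error(pert, case$true_transform)
  ref <- bbr_refine(pert, case$cbf$volume, ph$boundary)
  fin_err <- rt_error(ref$transform, case$true_transform)
  expect_lt(fin_err[["trans_mm"]], init_err[["trans_mm"]])
  expect_lt(fin_err[["rot_deg"]], init_err[["rot_deg"]])
})

test_that("BBR converges to the same optimum from manual and intensity inits", {
  case <- std_case()
  manual <- emulate_manual(case$true_transform, c(1, 1), seed = 31)
  rigid <- rigid_register(case$cbf$volume, case$phantom$structural)
  a <- bbr_refine(manual, case$cbf$volume, case$phantom$boundary,
                  method = "manual+BBR")
  b <- bbr_refine(rigid$transform, case$cbf$volume, case$phantom$boundary,
                  method = "FLIRT+BBR")
  expect_transform_close(a$transform, b$transform, 0.5, 0.5)
  expect_identical(a$method, "manual+BBR")
  expect_identical(b$method, "FLIRT+BBR")
})

test_that("a far-off BBR initialization is rejected with a named failure", {
  case <- tiny_noisy_case()
  bad <- rigid_transform(translation = c(500, 0, 0))
  expect_error(bbr_refine(bad, case$cbf$volume, case$phantom$boundary),
               "initialization")
})

test_that("volume resampling is exact for identity and grid-aligned shifts", {
  case <- tiny_noisy_case()
  vol <- case$m0  # mask-free volume: no NA voxels
  same <- apply_transform(vol, rigid_transform(), target = vol)
  expect_equal(same$data, vol$data, tolerance = 1e-12)

  sp <- vol_spacing(vol)[1]
  shifted <- apply_transform(vol, rigid_transform(translation = c(sp, 0, 0)),
                             target = vol)
  d <- dim(vol$data)[1]
  expect_equal(shifted$data[2:d, , ], vol$data[1:(d - 1), , ],
               tolerance = 1e-9)
  expect_error(apply_transform(vol, rigid_transform(),
                               target = list(data = array(0, c(0, 0, 0)),
                                             affine = diag(4))),
               "empty")
})

test_that("point mapping through T then T^-1 is the identity", {
  set.seed(9)
  tf <- rt_random(5, 5)
  pts <- matrix(rnorm(300, 0, 70), 100)
  back <- rt_apply(rt_invert(tf), rt_apply(tf, pts))
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 1e-9)
})
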