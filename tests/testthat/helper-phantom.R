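# Shared small-scale fixtures, memoised so expensive objects are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Down-scaled phantom used throughout the unit tests: a smaller head on
# coarser grids so geometry, simulation and registration stay fast.
tiny_spec <- function(...) {
  phantom_spec(structural_shape = c(32, 32, 32), structural_spacing = 5,
               asl_shape = c(32, 32, 20), asl_spacing = 6,
               wm_semiaxes = c(40, 48, 34), gm_thickness = 8,
               csf_thickness = 4, mesh_rings = 20, mesh_segments = 40,
               ...)
}

tiny_phantom <- function() memo("tiny_phantom", generate_phantom(tiny_spec()))

tiny_parcellation <- function(n_parcels = 219) {
  memo(paste0("parc_", n_parcels),
       build_parcellation(tiny_phantom()$boundary, n_parcels = n_parcels,
                          seed = 42))
}

# One noiseless participant (identity transform) for exact round trips.
tiny_noiseless_acq <- function() {
  memo("noiseless_acq", {
    spec <- tiny_spec(noise_sd = 0, ringing_amplitude = 0)
    ph <- tiny_phantom()
    truth <- make_true_cbf(ph$tissue_labels, ph$boundary, NULL, spec,
                           group_effect_spec("control"))
    acq <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec,
                               true_transform = rigid_transform(), seed = 11)
    c(acq, list(spec = spec, truth = truth, phantom = ph))
  })
}

# One noisy participant with a known true transform, quantified; used by the
# registration and QC tests.
tiny_noisy_case <- function() {
  memo("noisy_case", {
    spec <- tiny_spec()
    ph <- tiny_phantom()
    truth <- make_true_cbf(ph$tissue_labels, ph$boundary, NULL, spec,
                           group_effect_spec("control"))
    tf <- rigid_transform(c(3, -2, 4), c(2, -3, 3))
    acq <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec,
                               true_transform = tf, seed = 21)
    cm <- quantify_series(acq$series, acq$m0)
    c(acq, list(spec = spec, truth = truth, phantom = ph,
                true_transform = tf, cbf = cm))
  })
}

# Standard scale: the default ASL acquisition geometry over a 48^3
# structural grid and the full-resolution boundary mesh; used for
# precision-sensitive checks.
std_spec <- function(...) {
  phantom_spec(structural_shape = c(48, 48, 48), structural_spacing = 4, ...)
}

std_phantom <- function() memo("std_phantom", generate_phantom(std_spec()))

# Noiseless case with a known transform.
std_case <- function() {
  memo("std_case", {
    spec <- std_spec(noise_sd = 0, ringing_amplitude = 0)
    ph <- std_phantom()
    truth <- make_true_cbf(ph$tissue_labels, ph$boundary, NULL, spec,
                           group_effect_spec("control"))
    tf <- rigid_transform(c(-2, 3, -1), c(3, 2, -4))
    acq <- generate_asl_series(ph$tissue_labels, truth$cbf, spec = spec,
                               true_transform = tf, seed = 22)
    cm <- quantify_series(acq$series, acq$m0)
    c(acq, list(spec = spec, truth = truth, phantom = ph,
                true_transform = tf, cbf = cm))
  })
}

expect_transform_close <- function(a, b, tol_mm, tol_deg) {
  err <- rt_error(a, b)
  expect_lt(err[["trans_mm"]], tol_mm)
  expect_lt(err[["rot_deg"]], tol_deg)
}
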