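test_that("noiseless N-step retrieval is exact for arbitrary sinusoids", {
  set.seed(11)
  n <- 48
  for (rep_i in 1:5) {
    ph <- matrix(runif(n^2, -pi, pi), n)
    amp <- matrix(0.2 + runif(n^2), n)
    fld <- complex_field(amp * exp(1i * ph), 0.5, 1)
    n_steps <- sample(3:8, 1)
    st <- acquire_stack(fld, reference_spec(tilt_angle = 0),
                        camera_spec(n, n), n_steps)
    ret <- retrieve_phase_shifting(st)
    expect_lt(circular_rms(ret$phase - ph), 1e-9)
  }
})

test_that("retrieval needs at least 3 well-spaced frames", {
  n <- 16
  fld <- complex_field(matrix(1 + 0i, n, n), 0.5, 1)
  st <- acquire_stack(fld, reference_spec(), camera_spec(n, n), 4)
  expect_error(retrieve_phase_shifting(st[1:2]),
               class = "anlcsim_config_error")
  # degenerate spacing: phases not covering the cycle uniformly
  bad <- st
  bad[[3]]$phase_offset <- bad[[2]]$phase_offset + 1e-4
  bad[[4]]$phase_offset <- bad[[2]]$phase_offset + 2e-4
  expect_error(retrieve_phase_shifting(bad),
               class = "anlcsim_config_error")
})

test_that("a tilt-only stack retrieves the carrier ramp exactly", {
  n <- 64; pitch <- 1; lam <- 0.5
  flat <- complex_field(matrix(1 + 0i, n, n), lam, pitch)
  st <- acquire_stack(flat, reference_spec(tilt_angle = 2),
                      camera_spec(n, n), 4)
  ret <- retrieve_phase_shifting(st)
  fc <- sin(2 * pi / 180) / lam
  x <- (seq_len(n) - (n %/% 2 + 1)) * pitch
  carrier <- -2 * pi * fc * matrix(x, n, n)   # sample minus reference phase
  expect_lt(circular_rms(ret$phase - carrier), 1e-9)
})

test_that("retrieval is invariant to global exposure scaling", {
  n <- 48
  bump <- phase_bump(n, peak = 2)
  fld <- field_from_phase(bump)
  st <- acquire_stack(fld, reference_spec(tilt_angle = 0),
                      camera_spec(n, n), 4)
  scaled <- st
  for (k in seq_along(scaled)) {
    scaled[[k]]$intensity <- scaled[[k]]$intensity * 7.3
  }
  r1 <- retrieve_phase_shifting(st)
  r2 <- retrieve_phase_shifting(scaled)
  expect_equal(r1$phase, r2$phase, tolerance = 1e-12)
})

test_that("off-axis retrieval of a flat field is constant", {
  n <- 128
  flat <- complex_field(matrix(1 + 0i, n, n), 0.5, 1)
  ig <- interfere(flat, reference_spec(tilt_angle = 2), camera_spec(n, n))
  off <- retrieve_offaxis(ig)
  inner <- matrix(FALSE, n, n); inner[25:104, 25:104] <- TRUE
  expect_lt(circular_rms(off$phase, inner), 1e-3)
})

test_that("off-axis and phase-shifting agree on band-limited samples", {
  n <- 128
  bump <- phase_bump(n, peak = 1, sigma = 20)
  fld <- field_from_phase(bump)
  psi <- retrieve_phase_shifting(
    acquire_stack(fld, reference_spec(tilt_angle = 0), camera_spec(n, n), 4))
  off <- retrieve_offaxis(
    interfere(fld, reference_spec(tilt_angle = 2), camera_spec(n, n)))
  inner <- matrix(FALSE, n, n); inner[17:112, 17:112] <- TRUE
  expect_lt(circular_rms(off$phase - psi$phase, inner), 1e-2)
})

test_that("a one-bin carrier error leaves a ramp that plane-fit removes", {
  n <- 128; pitch <- 1; lam <- 0.5
  bump <- phase_bump(n, peak = 0.8, sigma = 18)
  fld <- field_from_phase(bump, lam, pitch)
  ig <- interfere(fld, reference_spec(tilt_angle = 2), camera_spec(n, n))
  fc <- sin(2 * pi / 180) / lam
  off_bin <- 1 / (n * pitch)
  mis <- retrieve_offaxis(ig, carrier = c(fc + off_bin, 0), plane_fit = FALSE)
  fixed <- retrieve_offaxis(ig, carrier = c(fc + off_bin, 0), plane_fit = TRUE)
  inner <- matrix(FALSE, n, n); inner[17:112, 17:112] <- TRUE
  err_mis <- circular_rms(mis$phase - bump, inner)
  err_fixed <- circular_rms(fixed$phase - bump, inner)
  # the uncorrected ramp spans ~2 pi over the frame
  expect_gt(err_mis, 0.5)
  expect_lt(err_fixed, 0.1)
})

test_that("unwrapping round-trips a 5-rad Gaussian bump", {
  n <- 128
  bump <- phase_bump(n, peak = 5, sigma = 20)
  wrapped <- phase_map(wrap_to_pi(bump), 0.5, 1, wrapped = TRUE)
  uw <- unwrap(wrapped)
  expect_false(uw$wrapped)
  expect_lt(sqrt(mean((uw$phase - bump)^2)), 1e-6)
})

test_that("unwrapping is the identity on wrap-free input", {
  n <- 64
  bump <- phase_bump(n, peak = 2)
  pm <- phase_map(bump - median(bump), 0.5, 1, wrapped = TRUE)
  expect_equal(unwrap(pm)$phase, pm$phase)
})

test_that("a fragmented mask unwraps per component with a warning", {
  n <- 64
  bump <- phase_bump(n, peak = 5, sigma = 10)
  mask <- matrix(TRUE, n, n)
  mask[, 32:33] <- FALSE   # split the domain in two
  pm <- phase_map(wrap_to_pi(bump), 0.5, 1, mask = mask, wrapped = TRUE)
  expect_warning(uw <- unwrap(pm), "component")
  d <- (uw$phase - bump)[mask]
  # each component may carry its own 2 pi k offset; both must be flat
  expect_lt(sd(d - 2 * pi * round(d / (2 * pi))), 1e-6)
})

test_that("the default phantom needs no unwrapping at 0.5 um wavelength", {
  g <- voxel_grid(64, 64, 16, dx = 0.25, dz = 0.5)
  ph <- small_phantom(tail_length = 4, position = c(-3, 0, 4))
  vol <- build_sperm(ph, g, 1.33)
  peak_phase <- 2 * pi * max(ground_truth_opd(vol)) / 0.5
  expect_equal(peak_phase, 2 * pi * 0.06 / 0.5, tolerance = 1e-9) # 0.754 rad
  expect_lt(peak_phase, pi)
})

test_that("reference subtraction removes the common-path phase", {
  n <- 48
  bump <- phase_bump(n, peak = 1)
  pm <- phase_map(bump, 0.5, 1, wrapped = FALSE)
  zero <- subtract_reference(pm, pm)
  expect_equal(max(abs(zero$phase)), 0)
  # projection additivity: (ANLC + cell) - ANLC = cell
  g <- voxel_grid(96, 96, 28, dx = 1, dz = 4)
  d <- anlc_design("cylinder_flat", lateral_dim = 80, strict = FALSE)
  anlc <- build_anlc(d, g)
  cell <- build_sperm(small_phantom(position = c(-5, 0, NA)), g, 1.33)
  comp <- compose_volumes(anlc, cell)
  pw <- complex_field(matrix(1 + 0i, 96, 96), 0.5, 1)
  ps <- function(vol) {
    retrieve_phase_shifting(acquire_stack(
      transmit_sample(pw, vol, "projection"),
      reference_spec(tilt_angle = 0), camera_spec(96, 96), 4))
  }
  resid <- subtract_reference(ps(comp), ps(anlc))
  cell_phase <- 2 * pi * ground_truth_opd(cell) / 0.5
  expect_lt(circular_rms(resid$phase - cell_phase), 1e-9)
  # mismatched grids are rejected
  pm_small <- phase_map(bump[1:32, 1:32], 0.5, 1, wrapped = FALSE)
  expect_error(subtract_reference(pm, pm_small),
               class = "anlcsim_dimension_error")
})

test_that("phase map OPD is consistent with phase and wavelength", {
  bump <- phase_bump(32, peak = 1)
  pm <- phase_map(bump, 0.64, 1, wrapped = FALSE)
  expect_equal(opd_map(pm), bump * 0.64 / (2 * pi))
  expect_error(phase_map(matrix(10, 4, 4), 0.5, 1, wrapped = TRUE),
               class = "anlcsim_config_error")
})
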