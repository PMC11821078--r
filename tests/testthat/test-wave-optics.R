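test_that("Gaussian source has the configured waist, profile and unit energy", {
  f <- make_gaussian(512, 512, 0.5, 0.5, 60)
  expect_equal(2 * beam_radius(f), 60, tolerance = 0.5 / 60) # within 1 px
  expect_equal(field_energy(f), 1, tolerance = 1e-12)
  # intensity at r = w0 relative to the axis is e^-2
  inten <- Mod(f$amplitude)^2
  i0 <- inten[257, 257]
  iw <- inten[257 + 60, 257]   # 60 px * 0.5 um = 30 um = w0
  expect_equal(iw / i0, exp(-2), tolerance = 1e-10)
  # undersized grid is rejected
  expect_error(make_gaussian(64, 64, 0.5, 0.5, 60),
               class = "anlcsim_config_error")
  expect_error(make_gaussian(512, 512, 0.5, 0.3, 60),
               class = "anlcsim_config_error")
})

test_that("free-space propagation follows the analytic Gaussian beam law", {
  w0 <- 30; lam <- 0.5
  f <- make_gaussian(512, 512, 1.0, lam, 2 * w0)   # 512 um field of view
  zr <- pi * w0^2 / lam
  for (zf in c(0.25, 0.5, 1, 2, 3)) {
    p <- propagate(f, zf * zr)
    expect_equal(beam_radius(p), w0 * sqrt(1 + zf^2),
                 tolerance = 0.01)
    expect_equal(field_energy(p), 1, tolerance = 1e-6)
  }
})

test_that("propagation is the identity at zero distance and invertible", {
  # the beam must sit deep inside the window so the crop after the
  # forward step discards no measurable energy
  f <- make_gaussian(512, 512, 1.0, 0.5, 60)
  expect_identical(propagate(f, 0)$amplitude, f$amplitude)
  back <- propagate(propagate(f, 80), -80)
  rel <- sqrt(sum(Mod(back$amplitude - f$amplitude)^2) /
                sum(Mod(f$amplitude)^2))
  expect_lt(rel, 1e-9)
})

test_that("a thin lens is a pure phase element and focuses a plane wave", {
  f <- make_gaussian(256, 256, 1.0, 0.5, 60)
  expect_equal(field_energy(apply_lens(f, 5000)), field_energy(f),
               tolerance = 1e-12)
  expect_identical(apply_lens(f, Inf)$amplitude, f$amplitude)
  expect_error(apply_lens(f, 0), class = "anlcsim_config_error")
  # plane wave -> lens f -> propagate f: peak lands on the axis
  pw <- complex_field(matrix(1 + 0i, 256, 256), 0.5, 1.0)
  foc <- propagate(apply_lens(pw, 20000), 20000)
  inten <- Mod(foc$amplitude)^2
  pk <- arrayInd(which.max(inten), dim(inten))
  expect_equal(as.integer(pk), c(129L, 129L))
  expect_gt(inten[129, 129], 30 * mean(inten))
})

test_that("transmission and propagation are linear in the field", {
  g <- voxel_grid(64, 64, 8, dx = 1, dz = 1)
  arr <- array(1.33, dim = c(64, 64, 8))
  arr[30:36, 30:36, 4] <- 1.40
  vol <- sample_volume(g, arr, 1.33)
  mk_point <- function(i, j) {
    a <- matrix(0 + 0i, 64, 64); a[i, j] <- 1
    complex_field(a, 0.5, 1)
  }
  f1 <- mk_point(20, 33); f2 <- mk_point(45, 33)
  both <- complex_field(f1$amplitude + f2$amplitude, 0.5, 1)
  t_sum <- transmit_sample(both, vol, "multislice")
  t_parts <- transmit_sample(f1, vol, "multislice")$amplitude +
    transmit_sample(f2, vol, "multislice")$amplitude
  expect_equal(t_sum$amplitude, t_parts, tolerance = 1e-12)
  p_sum <- propagate(both, 40)
  p_parts <- propagate(f1, 40)$amplitude + propagate(f2, 40)$amplitude
  expect_equal(p_sum$amplitude, p_parts, tolerance = 1e-12)
})

test_that("projection transmission applies the closed-form slab phase", {
  # slab 10 um, dn = 0.05, lambda 0.5: phase 2 pi, wraps to 0
  vol <- slab_volume(n = 32, nz = 10, dn = 0.05, dz = 1)
  pw <- complex_field(matrix(1 + 0i, 32, 32), 0.5, 1)
  out <- transmit_sample(pw, vol, "projection")
  expect_equal(max(Mod(out$amplitude - pw$amplitude)), 0, tolerance = 1e-10)
  # index-matched sample leaves the field unchanged
  vol0 <- slab_volume(n = 32, nz = 10, dn = 0, dz = 1)
  expect_equal(transmit_sample(pw, vol0, "projection")$amplitude,
               pw$amplitude)
  expect_equal(transmit_sample(pw, vol0, "multislice",
                               pad_factor = 1)$amplitude,
               pw$amplitude, tolerance = 1e-12)
})

test_that("projection and multislice agree on laterally uniform samples", {
  # plane-wave illumination without padding keeps the field an exact
  # eigenmode, so the two forward models must coincide
  vol <- slab_volume(n = 32, nz = 10, dn = 0.03, dz = 1)
  pw <- complex_field(matrix(exp(0.3i), 32, 32), 0.5, 1)
  pr <- transmit_sample(pw, vol, "projection")
  ms <- transmit_sample(pw, vol, "multislice", pad_factor = 1)
  expect_lt(max(Mod(pr$amplitude - ms$amplitude)), 1e-9)
})

test_that("field transmission checks lateral registration", {
  vol <- slab_volume(n = 32, nz = 10)
  bad_pitch <- complex_field(matrix(1 + 0i, 32, 32), 0.5, 0.7)
  expect_error(transmit_sample(bad_pitch, vol),
               class = "anlcsim_dimension_error")
  bad_size <- complex_field(matrix(1 + 0i, 16, 16), 0.5, 1)
  expect_error(transmit_sample(bad_size, vol),
               class = "anlcsim_dimension_error")
})
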