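# Shared helpers for the test suite. All fixtures are generated in code.

# RMS of a wrapped phase difference after circular piston removal.
circular_rms <- function(d, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(d), ncol(d))
  d0 <- Arg(exp(1i * d) / mean(exp(1i * d[mask])))
  sqrt(mean(d0[mask]^2))
}

wrap_to_pi <- function(x) Arg(exp(1i * x))

# Smooth Gaussian phase bump on an n x n grid (radians at peak).
phase_bump <- function(n, peak = 1, sigma = n / 8, pitch = 1) {
  x <- (seq_len(n) - (n %/% 2 + 1)) * pitch
  peak * exp(-outer(x^2, x^2, `+`) / (2 * (sigma * pitch)^2))
}

# Flat-amplitude field carrying a given phase.
field_from_phase <- function(phase, wavelength = 0.5, pitch = 1) {
  complex_field(exp(1i * phase), wavelength, pitch)
}

# Uniform-index slab volume filling the whole grid axially.
slab_volume <- function(n = 32, nz = 10, dn = 0.05, dz = 1, dx = 1,
                        medium = 1.33) {
  g <- voxel_grid(n, n, nz, dx = dx, dz = dz)
  sample_volume(g, array(medium + dn, dim = c(n, n, nz)), medium)
}

# A short-tailed phantom that fits small grids.
small_phantom <- function(tail_length = 12, ...) {
  sperm_phantom(tail_length = tail_length, ...)
}

# Reduced pipeline settings shared by integration tests.
small_grid <- function() voxel_grid(128, 128, 56, dx = 1, dz = 2)
small_optics <- function(...) {
  optics_config(waist_diameter = 25, ...)
}
small_design <- function(kind, ...) anlc_design(kind, lateral_dim = 100, ...)
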