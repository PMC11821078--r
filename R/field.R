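#' Sampled complex optical field
#'
#' A scalar monochromatic field on a regular 2D grid. Energy is defined as
#' `sum(|amplitude|^2) * pixel_pitch^2`.
#'
#' @param amplitude Complex matrix `[nx, ny]`.
#' @param wavelength Vacuum wavelength in micrometres; the simulated range
#'   is 0.4--0.8 um.
#' @param pixel_pitch Sample spacing in micrometres.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(amplitude, wavelength, pixel_pitch) {
  if (!is.matrix(amplitude)) abort_dimension("amplitude must be a matrix")
  check_wavelength(wavelength)
  if (pixel_pitch <= 0) abort_config("pixel_pitch must be positive")
  amplitude <- amplitude + 0i
  e <- sum(Mod(amplitude)^2) * pixel_pitch^2
  if (!is.finite(e) || e <= 0) abort_config("field energy must be finite and positive")
  structure(
    list(amplitude = amplitude, wavelength = wavelength,
         pixel_pitch = pixel_pitch),
    class = "complex_field"
  )
}

check_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) != 1 ||
      wavelength < 0.4 || wavelength > 0.8) {
    abort_config("wavelength must lie in the simulated range [0.4, 0.8] um")
  }
  invisible(wavelength)
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field: %d x %d px at %.3g um, lambda %.3g um, energy %.4g\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_pitch,
              x$wavelength, field_energy(x)))
  invisible(x)
}

#' Total field energy
#' @param field A [complex_field()].
#' @return `sum(|amplitude|^2) * pitch^2`.
#' @export
field_energy <- function(field) {
  sum(Mod(field$amplitude)^2) * field$pixel_pitch^2
}

#' Gaussian illumination beam at its waist
#'
#' Builds the illumination field with amplitude
#' \eqn{\exp(-r^2/w_0^2)}, i.e. a \eqn{1/e^2} *intensity* radius of
#' \eqn{w_0 = } `waist_diameter / 2`, flat phase, normalized to unit energy.
#' The default waist diameter is 60 um at the sample plane.
#'
#' @param nx,ny Grid size in pixels.
#' @param pixel_pitch Pixel pitch, um.
#' @param wavelength Vacuum wavelength, um.
#' @param waist_diameter 1/e^2 intensity diameter at the waist, um.
#' @param center Beam center `(x, y)` in um.
#' @return A [complex_field()].
#' @export
make_gaussian <- function(nx = 512, ny = nx, pixel_pitch = 0.5,
                          wavelength = 0.5, waist_diameter = 60,
                          center = c(0, 0)) {
  check_wavelength(wavelength)
  if (waist_diameter <= 2 * wavelength) {
    abort_config("waist_diameter must exceed 2 * wavelength")
  }
  if (min(nx * pixel_pitch, ny * pixel_pitch) < 4 * waist_diameter) {
    abort_config("grid extent must be at least 4x the waist diameter (aliasing)")
  }
  w0 <- waist_diameter / 2
  x <- axis_coords(nx, pixel_pitch) - center[1]
  y <- axis_coords(ny, pixel_pitch) - center[2]
  r2 <- outer(x^2, y^2, `+`)
  amp <- exp(-r2 / w0^2)
  amp <- amp / sqrt(sum(amp^2) * pixel_pitch^2)
  complex_field(amp, wavelength, pixel_pitch)
}

#' Second-moment beam radius
#'
#' For a Gaussian beam the intensity-weighted radial second moment obeys
#' \eqn{\langle r^2 \rangle = w^2/2}, so the returned
#' \eqn{w = \sqrt{2 \langle r^2 \rangle}} is the 1/e^2 intensity radius.
#'
#' @param field A [complex_field()].
#' @return Beam radius in micrometres.
#' @export
beam_radius <- function(field) {
  inten <- Mod(field$amplitude)^2
  x <- axis_coords(nrow(inten), field$pixel_pitch)
  y <- axis_coords(ncol(inten), field$pixel_pitch)
  xc <- sum(x * rowSums(inten)) / sum(inten)
  yc <- sum(y * colSums(inten)) / sum(inten)
  r2 <- outer((x - xc)^2, (y - yc)^2, `+`)
  sqrt(2 * sum(r2 * inten) / sum(inten))
}
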