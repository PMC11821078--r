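# Band-limited angular-spectrum machinery shared by propagate() and the
# multislice sample transmission.

# Transfer function H(fx, fy) for distance z in a homogeneous background of
# index n_medium. With envelope = TRUE the plane-wave carrier exp(i k z) of
# the background is divided out (slowly-varying envelope), which is the
# form used between multislice phase screens so that a laterally uniform
# sample reduces exactly to the projection approximation.
angular_spectrum_tf <- function(nx, ny, pitch, wavelength, z,
                                n_medium = 1, envelope = FALSE) {
  lam <- wavelength / n_medium
  fx <- fft_freqs(nx, pitch)
  fy <- fft_freqs(ny, pitch)
  f2 <- outer(fx^2, fy^2, `+`)
  arg <- 1 / lam^2 - f2
  prop <- arg > 0
  kz <- sqrt(pmax(arg, 0))
  if (envelope) kz <- kz - 1 / lam
  h <- matrix(0 + 0i, nx, ny)
  h[prop] <- exp(2i * pi * z * kz[prop])
  # band limit (Matsushima & Shimobaba) against wrap-around aliasing
  if (abs(z) > 0) {
    flx <- 1 / (lam * sqrt((2 * z / (nx * pitch))^2 + 1))
    fly <- 1 / (lam * sqrt((2 * z / (ny * pitch))^2 + 1))
    h[abs(matrix(fx, nx, ny)) > flx] <- 0i
    h[abs(matrix(fy, nx, ny, byrow = TRUE)) > fly] <- 0i
  }
  h
}

pad_embed <- function(amp, nx_p, ny_p) {
  out <- matrix(0 + 0i, nx_p, ny_p)
  ox <- (nx_p - nrow(amp)) %/% 2
  oy <- (ny_p - ncol(amp)) %/% 2
  out[ox + seq_len(nrow(amp)), oy + seq_len(ncol(amp))] <- amp
  out
}

pad_extract <- function(amp, nx, ny) {
  ox <- (nrow(amp) - nx) %/% 2
  oy <- (ncol(amp) - ny) %/% 2
  amp[ox + seq_len(nx), oy + seq_len(ny)]
}

#' Free-space propagation by the angular-spectrum method
#'
#' Exact scalar propagation of the sampled field over `distance` (negative
#' distances back-propagate). Evanescent components are suppressed; the
#' spectrum is band-limited against wrap-around aliasing, and the field is
#' zero-padded by `pad_factor` before the transform.
#'
#' @param field A [complex_field()].
#' @param distance Propagation distance in micrometres.
#' @param n_medium Refractive index of the background medium.
#' @param pad_factor Zero-padding factor (default 2).
#' @param envelope If `TRUE`, propagate the slowly-varying envelope (the
#'   background plane-wave carrier is divided out).
#' @return The propagated [complex_field()].
#' @export
propagate <- function(field, distance, n_medium = 1, pad_factor = 2,
                      envelope = FALSE) {
  stopifnot(inherits(field, "complex_field"))
  if (distance == 0) return(field)
  nx <- nrow(field$amplitude); ny <- ncol(field$amplitude)
  nx_p <- nx * pad_factor; ny_p <- ny * pad_factor
  h <- angular_spectrum_tf(nx_p, ny_p, field$pixel_pitch, field$wavelength,
                           distance, n_medium, envelope)
  a <- pad_embed(field$amplitude, nx_p, ny_p)
  a <- fft(fft(a) * h, inverse = TRUE) / (nx_p * ny_p)
  field$amplitude <- pad_extract(a, nx, ny)
  field
}

#' Ideal thin lens
#'
#' Multiplies the field by the quadratic phase
#' \eqn{\exp(-i \pi r^2 / (\lambda f))}; a pure phase element, so energy is
#' unchanged. `focal_length = Inf` is the identity.
#'
#' @param field A [complex_field()].
#' @param focal_length Focal length in micrometres (nonzero; may be `Inf`).
#' @return The transformed [complex_field()].
#' @export
apply_lens <- function(field, focal_length) {
  stopifnot(inherits(field, "complex_field"))
  if (focal_length == 0) abort_config("focal length must be nonzero")
  if (is.infinite(focal_length)) return(field)
  x <- axis_coords(nrow(field$amplitude), field$pixel_pitch)
  y <- axis_coords(ncol(field$amplitude), field$pixel_pitch)
  r2 <- outer(x^2, y^2, `+`)
  field$amplitude <- field$amplitude *
    exp(-1i * pi * r2 / (field$wavelength * focal_length))
  field
}

#' Image relay to the camera plane
#'
#' The imaging arm is modeled as an ideal unit-magnification 4f relay
#' focused at `focus_offset` before the exit plane of the sample volume:
#' the camera-plane field is the exit field digitally back-propagated to
#' the in-focus plane. Magnification only rescales the pixel pitch, so the
#' simulation works in sample-plane coordinates.
#'
#' @param exit_field [complex_field()] at the exit face of the volume.
#' @param focus_offset Distance (um) from the in-focus plane to the exit
#'   face, measured along the illumination direction.
#' @param n_medium Background index used for the conjugation.
#' @param pad_factor Zero-padding factor passed to [propagate()].
#' @return The camera-plane [complex_field()].
#' @export
relay_to_camera <- function(exit_field, focus_offset = 0, n_medium = 1,
                            pad_factor = 2) {
  if (focus_offset == 0) return(exit_field)
  propagate(exit_field, -focus_offset, n_medium = n_medium,
            pad_factor = pad_factor, envelope = TRUE)
}
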