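#' Reference-beam specification
#'
#' The reference arm is modeled as an ideal tilted plane wave at the
#' camera, carrying the modulator phase. A modulator setting `phase_offset`
#' *delays* the reference, i.e. the reference field is
#' \eqn{r_0 \exp(i (k \sin\theta (x\cos\alpha + y\sin\alpha) - \varphi_M))}.
#'
#' @param tilt_angle In-plane carrier tilt in degrees (0--10; typically a
#'   few degrees, default 2).
#' @param tilt_azimuth Azimuth of the tilt direction in degrees (0 = +x).
#' @param phase_offset Modulator phase \eqn{\varphi_M} in radians.
#' @param amplitude_ratio Reference amplitude as a multiple of the sample
#'   field's RMS amplitude.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(tilt_angle = 2, tilt_azimuth = 0,
                           phase_offset = 0, amplitude_ratio = 1) {
  if (tilt_angle < 0 || tilt_angle > 10) {
    abort_config("tilt_angle must lie in [0, 10] degrees")
  }
  if (amplitude_ratio <= 0) abort_config("amplitude_ratio must be positive")
  structure(
    list(tilt_angle = tilt_angle, tilt_azimuth = tilt_azimuth,
         phase_offset = phase_offset, amplitude_ratio = amplitude_ratio),
    class = "reference_spec"
  )
}

#' Camera specification
#'
#' @param nx,ny Sensor size in pixels; defaults follow the simulation grid.
#' @param bit_depth Bits per pixel (8--16, default 14).
#' @param noise_std Additive Gaussian read noise, in counts (applied only
#'   when quantizing).
#' @param quantize If `TRUE`, scale exposure so the brightest possible
#'   noiseless pixel sits at 80% of full scale, add read noise, and round
#'   to integer counts. Default `FALSE` (ideal floating-point detector).
#' @return An object of class `camera_spec`.
#' @export
camera_spec <- function(nx = 512, ny = nx, bit_depth = 14, noise_std = 0,
                        quantize = FALSE) {
  if (!bit_depth %in% 8:16) abort_config("bit_depth must be in 8..16")
  if (noise_std < 0) abort_config("noise_std must be non-negative")
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         bit_depth = as.integer(bit_depth), noise_std = noise_std,
         quantize = isTRUE(quantize)),
    class = "camera_spec"
  )
}

reference_amplitude <- function(sample_field, ref) {
  ref$amplitude_ratio * sqrt(mean(Mod(sample_field$amplitude)^2))
}

reference_wave <- function(sample_field, ref, phase_offset) {
  nx <- nrow(sample_field$amplitude)
  ny <- ncol(sample_field$amplitude)
  x <- axis_coords(nx, sample_field$pixel_pitch)
  y <- axis_coords(ny, sample_field$pixel_pitch)
  th <- ref$tilt_angle * pi / 180
  az <- ref$tilt_azimuth * pi / 180
  fc <- sin(th) / sample_field$wavelength        # carrier, cycles/um
  phase <- 2 * pi * fc * outer(x * cos(az), y * sin(az), `+`) - phase_offset
  r0 <- reference_amplitude(sample_field, ref)
  r0 * exp(1i * phase)
}

new_interferogram <- function(intensity, phase_offset, field, ref, cam) {
  structure(
    list(intensity = intensity, phase_offset = phase_offset,
         bit_depth = cam$bit_depth, quantized = cam$quantize,
         pixel_pitch = field$pixel_pitch, wavelength = field$wavelength,
         tilt_angle = ref$tilt_angle, tilt_azimuth = ref$tilt_azimuth),
    class = "interferogram"
  )
}

#' Form one interferogram
#'
#' Camera intensity \eqn{I = |E_s + E_r|^2} of the sample field and the
#' tilted, phase-modulated reference plane wave. With tilt \eqn{\theta}
#' the fringe period along the tilt direction is
#' \eqn{\lambda / \sin\theta}. With `cam$quantize` the frame is scaled,
#' read noise added and rounded to integer counts.
#'
#' @param sample_field [complex_field()] at the camera plane.
#' @param ref A [reference_spec()]; `ref$phase_offset` may be overridden
#'   via `phase_offset`.
#' @param cam A [camera_spec()] matching the field grid.
#' @param phase_offset Optional modulator phase override (radians).
#' @return An object of class `interferogram`.
#' @export
interfere <- function(sample_field, ref = reference_spec(),
                      cam = camera_spec(nrow(sample_field$amplitude),
                                        ncol(sample_field$amplitude)),
                      phase_offset = ref$phase_offset) {
  stopifnot(inherits(sample_field, "complex_field"),
            inherits(ref, "reference_spec"), inherits(cam, "camera_spec"))
  if (cam$nx != nrow(sample_field$amplitude) ||
      cam$ny != ncol(sample_field$amplitude)) {
    abort_dimension("camera size must match the field grid")
  }
  er <- reference_wave(sample_field, ref, phase_offset)
  inten <- Mod(sample_field$amplitude + er)^2
  if (cam$quantize) {
    full <- 2^cam$bit_depth - 1
    imax <- (max(Mod(sample_field$amplitude)) +
               reference_amplitude(sample_field, ref))^2
    counts <- inten * (0.8 * full / imax)
    if (cam$noise_std > 0) {
      counts <- counts + rnorm(length(counts), sd = cam$noise_std)
    }
    inten <- matrix(pmin(pmax(round(counts), 0), full),
                    nrow(inten), ncol(inten))
  }
  new_interferogram(inten, phase_offset, sample_field, ref, cam)
}

#' Acquire a phase-shifting interferogram stack
#'
#' Produces `n_steps` interferograms at modulator phases
#' \eqn{\varphi_M = 2\pi k / N}, `k = 0..N-1`, all other settings fixed.
#' The exposure scale is common to the whole stack.
#'
#' @inheritParams interfere
#' @param n_steps Number of phase steps (at least 3; default 4).
#' @return A list of [interfere()] frames of class `interferogram_stack`.
#' @export
acquire_stack <- function(sample_field, ref = reference_spec(),
                          cam = camera_spec(nrow(sample_field$amplitude),
                                            ncol(sample_field$amplitude)),
                          n_steps = 4) {
  if (n_steps < 3) abort_config("phase-shifting needs at least 3 steps")
  phis <- 2 * pi * (seq_len(n_steps) - 1) / n_steps
  frames <- lapply(phis, function(p) interfere(sample_field, ref, cam, p))
  structure(frames, class = "interferogram_stack")
}
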