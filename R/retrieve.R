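#' Phase map
#'
#' Retrieved (or ground-truth) phase image with validity mask. Wrapped
#' maps take values in \eqn{(-\pi, \pi]}; the OPD representation is
#' `phase * wavelength / (2 pi)` micrometres.
#'
#' @param phase Numeric matrix of phase values (radians).
#' @param wavelength Wavelength in um.
#' @param pixel_pitch Pixel pitch in um.
#' @param mask Logical matrix of valid pixels (default all `TRUE`).
#' @param wrapped Whether `phase` is wrapped to \eqn{(-\pi, \pi]}.
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(phase, wavelength, pixel_pitch, mask = NULL,
                      wrapped = TRUE) {
  if (!is.matrix(phase)) abort_dimension("phase must be a matrix")
  check_wavelength(wavelength)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase), ncol(phase))
  if (!identical(dim(mask), dim(phase))) {
    abort_dimension("mask must match the phase dimensions")
  }
  if (wrapped && any(phase[mask] > pi | phase[mask] <= -pi)) {
    abort_config("wrapped phase must lie in (-pi, pi]")
  }
  structure(
    list(phase = phase, wavelength = wavelength, pixel_pitch = pixel_pitch,
         mask = mask, wrapped = wrapped),
    class = "phase_map"
  )
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase_map: %d x %d px, %s, lambda %.3g um, range [%.3g, %.3g] rad\n",
              nrow(x$phase), ncol(x$phase),
              if (x$wrapped) "wrapped" else "unwrapped",
              x$wavelength, min(x$phase[x$mask]), max(x$phase[x$mask])))
  invisible(x)
}

#' Optical path difference of a phase map
#' @param map A [phase_map()].
#' @return Matrix of OPD values in micrometres.
#' @export
opd_map <- function(map) {
  stopifnot(inherits(map, "phase_map"))
  map$phase * map$wavelength / (2 * pi)
}

#' Phase-shifting retrieval (N-step estimator)
#'
#' For frames \eqn{I_k = A + B \cos(\varphi + \varphi_{M,k})} acquired at
#' uniform modulator phases over a full cycle, the wrapped phase is
#' \deqn{\varphi = \mathrm{atan2}(-\sum_k I_k \sin\varphi_{M,k},
#'                                \sum_k I_k \cos\varphi_{M,k}),}
#' exact per pixel for noiseless, unquantized sinusoidal data under the
#' modulator-delay convention of [reference_spec()].
#'
#' @param stack An `interferogram_stack` (or list of `interferogram`s)
#'   with at least 3 distinct modulator phases.
#' @return A wrapped [phase_map()] of the sample-minus-reference phase
#'   (the carrier ramp of a tilted reference is part of the result).
#' @export
retrieve_phase_shifting <- function(stack) {
  frames <- unclass(stack)
  if (length(frames) < 3) {
    abort_config("phase-shifting retrieval needs at least 3 frames")
  }
  phis <- vapply(frames, function(f) f$phase_offset, numeric(1))
  if (any(duplicated(round(wrap_phase(phis), 12)))) {
    abort_config("modulator phases must be distinct")
  }
  # first-order conditioning: sums of e^{i phi} and e^{2 i phi} must vanish
  # for the N-step estimator to be exact/solvable
  if (Mod(sum(exp(1i * phis))) > 1e-6 * length(phis) ||
      Mod(sum(exp(2i * phis))) > 1e-6 * length(phis)) {
    abort_config("modulator phases must uniformly cover a full cycle")
  }
  s <- 0; co <- 0
  for (k in seq_along(frames)) {
    s <- s + frames[[k]]$intensity * sin(phis[k])
    co <- co + frames[[k]]$intensity * cos(phis[k])
  }
  f1 <- frames[[1]]
  phase_map(atan2(-s, co), f1$wavelength, f1$pixel_pitch, wrapped = TRUE)
}

#' Off-axis (Fourier) retrieval from a single interferogram
#'
#' Isolates the +1 diffraction order of the carrier fringes with a
#' circular filter in the Fourier plane, shifts it to baseband and returns
#' the wrapped argument. The carrier must be separable from the baseband
#' term, i.e. the carrier frequency must exceed roughly twice the
#' specimen's spatial bandwidth.
#'
#' @param frame A single `interferogram` with nonzero tilt.
#' @param carrier Optional carrier frequency `(fx, fy)` in cycles/um;
#'   `NULL` (default) derives it from the frame's tilt metadata, `"auto"`
#'   locates the spectral peak.
#' @param filter_radius_frac Radius of the circular filter as a fraction
#'   of the carrier frequency (default 0.5).
#' @param plane_fit If `TRUE`, remove a best-fit phase plane (residual
#'   carrier ramp from a mis-specified carrier) from the unwrapped-safe
#'   complex field before taking the argument.
#' @param window If `TRUE` (default), apodize the frame with a 2D Hann
#'   window before the transform; suppresses the spectral leakage of the
#'   non-periodic carrier, which otherwise rings through the filter.
#' @return A wrapped [phase_map()].
#' @export
retrieve_offaxis <- function(frame, carrier = NULL, filter_radius_frac = 0.5,
                             plane_fit = FALSE, window = TRUE) {
  stopifnot(inherits(frame, "interferogram"))
  inten <- frame$intensity
  nx <- nrow(inten); ny <- ncol(inten)
  if (window) {
    hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    inten <- inten * outer(hann(nx), hann(ny))
  }
  pitch <- frame$pixel_pitch
  fx <- fft_freqs(nx, pitch)
  fy <- fft_freqs(ny, pitch)
  spec <- fft(inten)
  # Under the reference convention E_r ~ exp(i(2 pi f_c . r - phi_M)), the
  # order carrying E_s (positive specimen phase) sits at -f_c; demodulate
  # there.
  if (is.character(carrier) && identical(carrier, "auto")) {
    mag <- Mod(spec)
    f2 <- outer(fx^2, fy^2, `+`)
    mag[f2 < (4 / (min(nx, ny) * pitch))^2] <- 0   # exclude DC neighborhood
    mag[fx > 0, ] <- 0   # keep the E_s-order half-plane
    pk <- arrayInd(which.max(mag), dim(mag))
    demod <- c(fx[pk[1]], fy[pk[2]])
  } else {
    if (is.null(carrier)) {
      th <- frame$tilt_angle * pi / 180
      az <- frame$tilt_azimuth * pi / 180
      fc <- sin(th) / frame$wavelength
      carrier <- fc * c(cos(az), sin(az))
    }
    demod <- -carrier
  }
  fc_mag <- sqrt(sum(demod^2))
  if (fc_mag <= 0) abort_config("off-axis retrieval needs a nonzero carrier")
  # filter centered on the spectral bin nearest the demodulation frequency
  ix <- which.min(abs(fx - demod[1]))
  iy <- which.min(abs(fy - demod[2]))
  rad <- filter_radius_frac * fc_mag
  if (rad < 2 / (min(nx, ny) * pitch)) {
    abort_config("carrier not separable from baseband at this grid size")
  }
  dfx <- outer(fx - fx[ix], rep(1, ny))
  dfy <- outer(rep(1, nx), fy - fy[iy])
  # distances on the wrapped frequency torus
  fsx <- 1 / pitch; fsy <- 1 / pitch
  dfx <- (dfx + fsx / 2) %% fsx - fsx / 2
  dfy <- (dfy + fsy / 2) %% fsy - fsy / 2
  spec[dfx^2 + dfy^2 > rad^2] <- 0i
  analytic <- fft(spec, inverse = TRUE) / (nx * ny)
  # demodulate by the exact carrier in the space domain
  x <- axis_coords(nx, pitch); y <- axis_coords(ny, pitch)
  analytic <- analytic * exp(-2i * pi * outer(demod[1] * x, demod[2] * y, `+`))
  if (plane_fit) {
    # amplitude-weighted wrap-safe mean phase gradient: robust to the
    # low-amplitude border left by the window
    gx <- Arg(sum(analytic[-1, ] * Conj(analytic[-nx, ])))
    gy <- Arg(sum(analytic[, -1] * Conj(analytic[, -ny])))
    ramp <- outer(gx * (seq_len(nx) - 1), gy * (seq_len(ny) - 1), `+`)
    analytic <- analytic * exp(-1i * ramp)
  }
  phase_map(Arg(analytic), frame$wavelength, pitch, wrapped = TRUE)
}

#' Subtract a reference acquisition from a phase map
#'
#' Removes the well and system phase from a specimen acquisition, leaving
#' the specimen contribution plus any design-dependent residual
#' distortion. For wrapped inputs the difference is computed modulo
#' \eqn{2\pi} (complex-ratio subtraction), which is the standard practice
#' when the common-path phase itself is too steep to unwrap.
#'
#' @param map,empty_map [phase_map()]s on the same grid and wavelength.
#' @return A [phase_map()]; wrapped if either input was wrapped.
#' @export
subtract_reference <- function(map, empty_map) {
  stopifnot(inherits(map, "phase_map"), inherits(empty_map, "phase_map"))
  if (!identical(dim(map$phase), dim(empty_map$phase)) ||
      map$wavelength != empty_map$wavelength ||
      abs(map$pixel_pitch - empty_map$pixel_pitch) > 1e-12) {
    abort_dimension("phase maps must share grid and wavelength")
  }
  mask <- map$mask & empty_map$mask
  if (map$wrapped || empty_map$wrapped) {
    d <- wrap_phase(map$phase - empty_map$phase)
    phase_map(d, map$wavelength, map$pixel_pitch, mask, wrapped = TRUE)
  } else {
    phase_map(map$phase - empty_map$phase, map$wavelength, map$pixel_pitch,
              mask, wrapped = FALSE)
  }
}
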