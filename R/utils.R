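#' @useDynLib anlcsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm median setNames
#' @importFrom utils modifyList head tail
NULL

# Error helpers: classed conditions so callers can distinguish geometry,
# configuration and numerical failures.
abort_dimension <- function(msg) {
  stop(errorCondition(msg, class = c("anlcsim_dimension_error", "error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("anlcsim_config_error", "error")))
}

# Centered axis coordinates (micrometres) for n samples at pitch `delta`.
# The origin sits on the sample at index floor(n/2)+1, matching the FFT
# convention used throughout.
axis_coords <- function(n, delta) {
  (seq_len(n) - (n %/% 2 + 1)) * delta
}

# FFT sample frequencies in cycles/um, standard wrap ordering.
fft_freqs <- function(n, delta) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * delta)
}

# Wrap phase to the principal interval (-pi, pi].
wrap_phase <- function(x) {
  y <- Arg(exp(1i * x))
  # Arg returns values in (-pi, pi]; make -pi map to pi for determinism
  y[y <= -pi] <- pi
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
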