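#' 2D phase unwrapping (quality-guided)
#'
#' Resolves the \eqn{2\pi} ambiguities of a wrapped phase map by
#' quality-guided flood fill: pixels are integrated in order of local
#' phase smoothness, so wrap boundaries in noisy or steep regions are
#' crossed last. Each connected component of the validity mask is
#' unwrapped independently (with a warning when the mask fragments the
#' domain), and the remaining global \eqn{2\pi k} offset of every
#' component is fixed to the zero-median solution. Wrap-free inputs are
#' returned unchanged.
#'
#' @param map A wrapped [phase_map()].
#' @return An unwrapped [phase_map()] (`wrapped = FALSE`).
#' @export
unwrap <- function(map) {
  stopifnot(inherits(map, "phase_map"))
  if (!map$wrapped) return(map)
  res <- unwrap_quality_guided(map$phase, map$mask)
  if (res$n_components > 1) {
    warning("mask fragments the domain; unwrapped each component independently")
  }
  ph <- res$phase
  for (comp in seq_len(res$n_components)) {
    sel <- res$components == comp
    k <- round(median(ph[sel]) / (2 * pi))
    if (k != 0) ph[sel] <- ph[sel] - 2 * pi * k
  }
  ph[!map$mask] <- map$phase[!map$mask]
  phase_map(ph, map$wavelength, map$pixel_pitch, map$mask, wrapped = FALSE)
}
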