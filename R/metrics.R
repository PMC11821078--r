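#' Masked RMS phase error after piston removal
#'
#' \eqn{\sqrt{\mathrm{mean}_{mask}((\varphi - \varphi_{true} - c)^2)}}
#' with \eqn{c} the best-fit piston (masked mean difference). Piston
#' carries no specimen information in interferometry, so all fidelity
#' metrics ignore it.
#'
#' @param retrieved,truth [phase_map()]s (or plain matrices) on one grid.
#' @param mask Logical matrix of pixels to evaluate (default: the
#'   intersection of the maps' masks).
#' @return RMS error in radians.
#' @export
rms_phase_error <- function(retrieved, truth, mask = NULL) {
  r <- if (inherits(retrieved, "phase_map")) retrieved$phase else retrieved
  t_ <- if (inherits(truth, "phase_map")) truth$phase else truth
  if (!identical(dim(r), dim(t_))) abort_dimension("maps must share one grid")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(r), ncol(r))
    if (inherits(retrieved, "phase_map")) mask <- mask & retrieved$mask
    if (inherits(truth, "phase_map")) mask <- mask & truth$mask
  }
  if (!any(mask)) abort_config("empty evaluation mask")
  d <- r[mask] - t_[mask]
  d <- d - mean(d)
  sqrt(mean(d^2))
}

#' Footprint mask of a cell from its OPD map
#'
#' @param opd Matrix of cell OPD (um) or a [phase_map()].
#' @param rel_threshold Fraction of the peak OPD above which a pixel
#'   belongs to the footprint (default 0.05).
#' @return Logical matrix.
#' @export
cell_footprint <- function(opd, rel_threshold = 0.05) {
  if (inherits(opd, "phase_map")) opd <- opd_map(opd)
  if (max(opd) <= 0) abort_config("cell OPD map has no positive support")
  opd > rel_threshold * max(opd)
}

# Dilate a logical mask by a metric radius (um) using a Euclidean
# distance transform.
dilate_mask <- function(mask, radius_um, pixel_pitch) {
  r_px <- radius_um / pixel_pitch
  dist <- EBImage::distmap(1 - mask)   # distance of outside pixels to mask
  mask | (dist <= r_px)
}

#' Halo ratio around a cell footprint
#'
#' Energy of the residual phase in an annulus around the cell footprint
#' (the footprint dilated by `annulus_width` minus the footprint) divided
#' by the energy inside the footprint. A perfectly retrieved specimen
#' confines all energy to the footprint (ratio near 0); wall-induced
#' diffraction (the halo artifact) spills energy into the annulus.
#'
#' @param residual [phase_map()] or matrix: the reference-subtracted
#'   retrieved phase (piston removed internally).
#' @param footprint Logical matrix marking the cell footprint.
#' @param annulus_width Annulus width in micrometres (default 10).
#' @param pixel_pitch Pixel pitch in um (taken from `residual` when it is
#'   a [phase_map()]).
#' @return Dimensionless ratio; `Inf` when the footprint carries no
#'   energy while the annulus does.
#' @export
halo_ratio <- function(residual, footprint, annulus_width = 10,
                       pixel_pitch = NULL) {
  if (inherits(residual, "phase_map")) {
    pixel_pitch <- residual$pixel_pitch
    residual <- residual$phase
  }
  if (is.null(pixel_pitch)) abort_config("pixel_pitch is required for matrices")
  if (!any(footprint)) abort_config("empty cell footprint")
  dilated <- dilate_mask(footprint, annulus_width, pixel_pitch)
  annulus <- dilated & !footprint
  if (!any(annulus)) abort_config("empty annulus: widen annulus_width")
  # piston from a neutral ring just outside the annulus (still well away
  # from the container walls), so a residual confined to the footprint
  # stays confined and a global offset cancels
  ring <- dilate_mask(footprint, 2 * annulus_width, pixel_pitch) & !dilated
  piston <- if (any(ring)) mean(residual[ring]) else mean(residual[dilated])
  res <- residual - piston
  e_foot <- sum(res[footprint]^2)
  e_ann <- sum(res[annulus]^2)
  if (e_foot == 0) {
    if (e_ann == 0) return(0)
    return(Inf)
  }
  e_ann / e_foot
}

#' 1D cross-section through a phase map
#'
#' Bilinearly interpolated profile along the x or y axis through a given
#' point, in physical coordinates.
#'
#' @param map A [phase_map()] or matrix.
#' @param axis `"x"` or `"y"`.
#' @param through Point `(x, y)` in um the section passes through.
#' @param pixel_pitch Pixel pitch (um) when `map` is a matrix.
#' @return A data.frame with columns `position` (um) and `phase` (rad).
#' @export
cross_section <- function(map, axis = c("x", "y"), through = c(0, 0),
                          pixel_pitch = NULL) {
  axis <- match.arg(axis)
  if (inherits(map, "phase_map")) {
    pixel_pitch <- map$pixel_pitch
    m <- map$phase
  } else {
    m <- map
  }
  if (is.null(pixel_pitch)) abort_config("pixel_pitch is required for matrices")
  x <- axis_coords(nrow(m), pixel_pitch)
  y <- axis_coords(ncol(m), pixel_pitch)
  if (through[1] < min(x) || through[1] > max(x) ||
      through[2] < min(y) || through[2] > max(y)) {
    abort_dimension("section point lies outside the grid")
  }
  if (axis == "x") {
    pos <- x
    xi <- x; yi <- rep(through[2], length(x))
  } else {
    pos <- y
    xi <- rep(through[1], length(y)); yi <- y
  }
  # pracma::interp2 indexes (x = columns, y = rows) on a length-ny by
  # length-nx ordering; transpose our [nx, ny] matrix accordingly.
  val <- pracma::interp2(x = x, y = y, Z = t(m), xp = xi, yp = yi,
                         method = "linear")
  data.frame(position = pos, phase = val)
}
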