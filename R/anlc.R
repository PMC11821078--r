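#' Addressable nanoliter container (ANLC) design
#'
#' Parametric description of a micro-well that hosts a single cell during
#' freeze-thaw. Four designs are supported: a pyramid tapering to a small
#' tip, a truncated pyramid with a wide tip, a flat-bottom cylinder, and a
#' cylinder whose floor is a concave spherical cap. Pyramidal wells have
#' square cross-sections; cylindrical wells circular ones.
#'
#' Refractive indices default to standard literature values: aqueous medium
#' 1.33, SU-8 photoresist wall 1.59, borosilicate substrate 1.52,
#' mineral oil 1.40.
#'
#' @param kind One of `"pyramid"`, `"truncated_pyramid"`, `"cylinder_flat"`,
#'   `"cylinder_concave"`.
#' @param lateral_dim Top opening width (pyramids) or diameter (cylinders),
#'   micrometres. Standard designs lie in \[100, 150\] um.
#' @param depth Well depth in micrometres, standard range \[90, 110\] um.
#' @param tip_dim Width of the pyramid tip (apex truncation), micrometres.
#'   Defaults: 10 um for `pyramid`, 80 um for `truncated_pyramid`. Ignored
#'   for cylinders.
#' @param bottom_radius_of_curvature Radius of curvature of the concave
#'   floor (concave cylinder only), micrometres. Default: `lateral_dim`,
#'   a shallow spherical cap spanning the full diameter.
#' @param wall_index,medium_index,substrate_index,oil_index Refractive
#'   indices of the well wall, the aqueous filling medium, the substrate
#'   below the well, and the covering oil above it.
#' @param strict If `TRUE` (default), reject dimensions outside the
#'   standard ranges and indices outside \[1, 2\].
#' @return An object of class `anlc_design`.
#' @export
anlc_design <- function(kind = c("pyramid", "truncated_pyramid",
                                 "cylinder_flat", "cylinder_concave"),
                        lateral_dim = 125, depth = 100,
                        tip_dim = NULL, bottom_radius_of_curvature = NULL,
                        wall_index = 1.59, medium_index = 1.33,
                        substrate_index = 1.52, oil_index = 1.40,
                        strict = TRUE) {
  kind <- match.arg(kind)
  if (is.null(tip_dim)) {
    tip_dim <- switch(kind, pyramid = 10, truncated_pyramid = 80, 0)
  }
  if (is.null(bottom_radius_of_curvature)) {
    bottom_radius_of_curvature <- lateral_dim
  }
  if (lateral_dim <= 0 || depth < 0) {
    abort_config("lateral_dim must be positive and depth non-negative")
  }
  if (kind %in% c("pyramid", "truncated_pyramid") && tip_dim >= lateral_dim) {
    abort_config("tip_dim must be smaller than lateral_dim")
  }
  if (kind == "cylinder_concave" &&
      bottom_radius_of_curvature < lateral_dim / 2) {
    abort_config("bottom radius of curvature must be at least the well radius")
  }
  idx <- c(wall_index, medium_index, substrate_index, oil_index)
  if (strict) {
    if (lateral_dim < 100 || lateral_dim > 150) {
      abort_config("lateral_dim outside the standard [100, 150] um range (set strict = FALSE to override)")
    }
    if (depth < 90 || depth > 110) {
      abort_config("depth outside the standard [90, 110] um range (set strict = FALSE to override)")
    }
    if (any(idx < 1) || any(idx > 2)) {
      abort_config("refractive indices must lie in [1, 2]")
    }
  }
  structure(
    list(kind = kind, lateral_dim = lateral_dim, depth = depth,
         tip_dim = tip_dim,
         bottom_radius_of_curvature = bottom_radius_of_curvature,
         wall_index = wall_index, medium_index = medium_index,
         substrate_index = substrate_index, oil_index = oil_index),
    class = "anlc_design"
  )
}

#' @export
print.anlc_design <- function(x, ...) {
  cat(sprintf("anlc_design: %s, lateral %.3g um, depth %.3g um (%.3g nL)\n",
              x$kind, x$lateral_dim, x$depth, cavity_volume(x)))
  invisible(x)
}

# Sag of the concave spherical-cap floor at the well rim (um).
concave_sag <- function(design, r = design$lateral_dim / 2) {
  rc <- design$bottom_radius_of_curvature
  rc - sqrt(pmax(rc^2 - r^2, 0))
}

# Half-width (pyramids) or radius (cylinders) of the cavity cross-section
# at depth d below the well opening (d in [0, depth]).
cavity_half_width <- function(design, d) {
  switch(design$kind,
    pyramid = ,
    truncated_pyramid = {
      w <- design$lateral_dim +
        (design$tip_dim - design$lateral_dim) * d / design$depth
      w / 2
    },
    design$lateral_dim / 2
  )
}

# Logical cavity mask at depth d below the opening, for lateral coordinate
# matrices X, Y centered on the well axis.
cavity_mask_at_depth <- function(design, X, Y, d) {
  if (d < 0 || d >= design$depth) {
    return(matrix(FALSE, nrow(X), ncol(X)))
  }
  h <- cavity_half_width(design, d)
  if (design$kind %in% c("pyramid", "truncated_pyramid")) {
    mask <- abs(X) <= h & abs(Y) <= h
  } else {
    mask <- X^2 + Y^2 <= h^2
  }
  if (design$kind == "cylinder_concave") {
    # Spherical floor, deepest (= depth) on the axis, rising toward the rim:
    # the cavity at radius r ends at depth - sag(r).
    r2 <- X^2 + Y^2
    floor_d <- design$depth - concave_sag(design, sqrt(pmin(r2, (design$lateral_dim / 2)^2)))
    mask <- mask & (d < floor_d)
  }
  mask
}

#' Closed-form cavity volume of an ANLC design
#'
#' Cylinder: \eqn{\pi r^2 h}; pyramid and truncated pyramid: square frustum
#' \eqn{(h/3)(A_1 + A_2 + \sqrt{A_1 A_2})}; concave-bottom cylinder:
#' cylinder minus the volume between the spherical floor and the flat
#' bottom plane.
#'
#' @param design An [anlc_design()].
#' @return Cavity volume in nanolitres (1 nL = 1e6 um^3).
#' @export
cavity_volume <- function(design) {
  stopifnot(inherits(design, "anlc_design"))
  h <- design$depth
  vol_um3 <- switch(design$kind,
    cylinder_flat = pi * (design$lateral_dim / 2)^2 * h,
    pyramid = ,
    truncated_pyramid = {
      a1 <- design$lateral_dim^2
      a2 <- design$tip_dim^2
      h / 3 * (a1 + a2 + sqrt(a1 * a2))
    },
    cylinder_concave = {
      r <- design$lateral_dim / 2
      rc <- design$bottom_radius_of_curvature
      s <- concave_sag(design)
      cap <- pi * s^2 * (3 * rc - s) / 3
      pi * r^2 * h - (pi * r^2 * s - cap)
    }
  )
  vol_um3 / 1e6
}
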