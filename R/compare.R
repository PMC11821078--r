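#' Optical system configuration for the imaging pipeline
#'
#' Bundles the tunable parameters of the simulated interference
#' microscope. Defaults follow the modeled instrument: 0.5 um wavelength
#' (within the simulated 0.4--0.8 um range), 60 um illumination waist at
#' the sample plane, a reference tilt of 2 degrees, and 4 modulator steps.
#'
#' @param wavelength Vacuum wavelength, um.
#' @param waist_diameter Illumination 1/e^2 intensity diameter, um.
#' @param tilt_angle Reference tilt, degrees.
#' @param n_steps Modulator steps per stack.
#' @param mode Forward model: `"multislice"` (default) or `"projection"`.
#' @param pad_factor Zero-padding factor for propagation.
#' @param annulus_width Halo annulus width, um.
#' @param footprint_threshold Relative OPD threshold defining the cell
#'   footprint.
#' @param quantize,bit_depth,noise_std Camera model, see [camera_spec()].
#' @return A list of class `optics_config`.
#' @export
optics_config <- function(wavelength = 0.5, waist_diameter = 60,
                          tilt_angle = 2, n_steps = 4,
                          mode = c("multislice", "projection"),
                          pad_factor = 2, annulus_width = 10,
                          footprint_threshold = 0.05,
                          quantize = FALSE, bit_depth = 14, noise_std = 0) {
  mode <- match.arg(mode)
  check_wavelength(wavelength)
  structure(
    list(wavelength = wavelength, waist_diameter = waist_diameter,
         tilt_angle = tilt_angle, n_steps = n_steps, mode = mode,
         pad_factor = pad_factor, annulus_width = annulus_width,
         footprint_threshold = footprint_threshold, quantize = quantize,
         bit_depth = bit_depth, noise_std = noise_std),
    class = "optics_config"
  )
}

# Lateral bounding requirements of a phantom whose bounding box is
# centered on the well axis: half-width for square cross-sections and
# bounding radius for circular ones, plus the axial half-extent.
phantom_bounds <- function(phantom) {
  p <- phantom
  a <- p$head_semi_axes[1]
  u <- c(-a, a + p$midpiece_length + p$tail_length)
  u_mid <- (p$midpiece_length + p$tail_length) / 2
  v <- max(p$head_semi_axes[2], p$midpiece_radius, p$tail_radius)
  ct <- cos(p$orientation); st <- sin(p$orientation)
  xs <- -u_mid * ct + c(u * ct - v * abs(st), u * ct + v * abs(st))
  ys <- -u_mid * st + c(u * st - v * abs(ct), u * st + v * abs(ct))
  list(
    center_xy = c(-u_mid * ct, -u_mid * st),
    half_square = max(abs(xs), abs(ys)),
    radius = sqrt(max(xs^2) + max(ys^2)),
    z_half = max(p$head_semi_axes[3], p$midpiece_radius, p$tail_radius)
  )
}

#' Place a phantom inside a well
#'
#' Centers the phantom's bounding box laterally on the well axis. The
#' default axial placement is *resting*: the deepest position at which
#' the phantom still fits the cavity (with a small clearance), as a cell
#' settles to the bottom of its container. In a flat- or concave-bottom
#' cylinder and a truncated pyramid this is essentially the floor; in a
#' pyramid tapering to a 10 um tip the cell is held higher up, wedged
#' between the sloping walls. An explicit `depth_fraction` overrides this.
#'
#' @param phantom A [sperm_phantom()].
#' @param anlc A [build_anlc()] volume.
#' @param depth_fraction Axial position of the phantom center as a
#'   fraction of the well depth below the opening, or `NULL` (default)
#'   for the resting position.
#' @param clearance Gap in um kept between phantom and cavity boundary
#'   for the resting placement (default 1).
#' @param snap If `TRUE` (default), snap the resting axial center to the
#'   nearest slice boundary of the grid so the thin head is rasterized
#'   axially symmetrically (the symmetric split-step sees balanced
#'   half-slabs); only applied to the resting placement.
#' @return The phantom with resolved `position`.
#' @export
place_phantom_in_anlc <- function(phantom, anlc, depth_fraction = NULL,
                                  clearance = 1, snap = TRUE) {
  stopifnot(inherits(anlc, "sample_volume"), !is.null(anlc$design))
  design <- anlc$design
  b <- phantom_bounds(phantom)
  if (is.null(depth_fraction)) {
    dd <- design$depth
    d_max <- switch(design$kind,
      pyramid = ,
      truncated_pyramid = {
        if (2 * b$half_square > design$lateral_dim) {
          abort_dimension("phantom wider than the well opening")
        }
        dd * (design$lateral_dim - 2 * b$half_square) /
          (design$lateral_dim - design$tip_dim)
      },
      cylinder_flat = dd,
      cylinder_concave =
        dd - concave_sag(design, min(b$radius, design$lateral_dim / 2))
    )
    d_center <- min(d_max, dd) - b$z_half - clearance
    if (snap) {
      dz <- anlc$grid$dz
      d_center <- floor((anlc$layout$z_open + d_center) / dz) * dz -
        anlc$layout$z_open
    }
    if (d_center < b$z_half) {
      abort_dimension("phantom does not fit the cavity at any depth")
    }
    depth_fraction <- d_center / dd
  }
  phantom$position <- c(b$center_xy,
                        anlc$layout$z_open + depth_fraction * design$depth)
  phantom
}

# Verify the phantom's bounding box lies in the cavity medium of the well.
check_phantom_in_cavity <- function(phantom, design, layout) {
  p <- phantom
  a <- p$head_semi_axes[1]
  z_half <- max(p$head_semi_axes[3], p$midpiece_radius, p$tail_radius)
  d_lo <- p$position[3] - z_half - layout$z_open
  d_hi <- p$position[3] + z_half - layout$z_open
  if (d_lo < 0 || d_hi > design$depth) {
    abort_dimension("phantom extends axially outside the well cavity")
  }
  u <- c(-a, a + p$midpiece_length + p$tail_length)
  v <- max(p$head_semi_axes[2], p$midpiece_radius, p$tail_radius)
  ct <- cos(p$orientation); st <- sin(p$orientation)
  xs <- p$position[1] + c(u * ct - v * abs(st), u * ct + v * abs(st))
  ys <- p$position[2] + c(u * st - v * abs(ct), u * st + v * abs(ct))
  h <- cavity_half_width(design, d_hi)   # narrowest within the z range
  ok <- if (design$kind %in% c("pyramid", "truncated_pyramid")) {
    max(abs(xs)) <= h && max(abs(ys)) <= h
  } else {
    sqrt(max(xs^2) + max(ys^2)) <= h
  }
  if (design$kind == "cylinder_concave") {
    r_max <- min(sqrt(max(xs^2) + max(ys^2)), design$lateral_dim / 2)
    ok <- ok && d_hi <= design$depth - concave_sag(design, r_max)
  }
  if (!ok) abort_dimension("phantom does not fit inside the well cavity at this position")
  invisible(TRUE)
}

#' Simulate one full interferometric acquisition of a well
#'
#' Runs illuminate -> transmit -> relay -> interfere for a composed
#' ANLC + cell volume and for the empty well (the reference acquisition),
#' with the imaging system focused at the cell plane.
#'
#' @param design An [anlc_design()].
#' @param phantom A [sperm_phantom()]; a missing axial position is
#'   resolved with [place_phantom_in_anlc()].
#' @param grid A [voxel_grid()].
#' @param optics An [optics_config()].
#' @return List with `stack`, `stack_empty`, `truth` (cell-only phase,
#'   unwrapped [phase_map()]), `cell_opd`, `phantom` (as placed), and the
#'   component volumes.
#' @export
simulate_acquisition <- function(design, phantom = sperm_phantom(),
                                 grid = voxel_grid(512, 512, 112,
                                                   dx = 0.5, dz = 1),
                                 optics = optics_config(),
                                 depth_fraction = NULL) {
  anlc <- build_anlc(design, grid)
  if (anyNA(phantom$position)) {
    phantom <- place_phantom_in_anlc(phantom, anlc, depth_fraction)
  }
  check_phantom_in_cavity(phantom, design, anlc$layout)
  cell <- build_sperm(phantom, grid, design$medium_index)
  composed <- compose_volumes(anlc, cell)
  illum <- make_gaussian(grid$nx, grid$ny, grid$dx, optics$wavelength,
                         optics$waist_diameter)
  exit_s <- transmit_sample(illum, composed, optics$mode, optics$pad_factor)
  exit_e <- transmit_sample(illum, anlc, optics$mode, optics$pad_factor)
  if (optics$mode == "multislice") {
    focus_offset <- grid$nz * grid$dz - cell$cell_z
    exit_s <- relay_to_camera(exit_s, focus_offset, design$medium_index,
                              optics$pad_factor)
    exit_e <- relay_to_camera(exit_e, focus_offset, design$medium_index,
                              optics$pad_factor)
  }
  ref <- reference_spec(tilt_angle = optics$tilt_angle)
  cam <- camera_spec(grid$nx, grid$ny, bit_depth = optics$bit_depth,
                     noise_std = optics$noise_std, quantize = optics$quantize)
  truth <- phase_map(2 * pi * cell$opd / optics$wavelength,
                     optics$wavelength, grid$dx, wrapped = FALSE)
  list(stack = acquire_stack(exit_s, ref, cam, optics$n_steps),
       stack_empty = acquire_stack(exit_e, ref, cam, optics$n_steps),
       truth = truth, cell_opd = cell$opd, phantom = phantom,
       anlc = anlc, cell = cell, composed = composed)
}

#' Retrieve the specimen phase from a simulated acquisition
#'
#' Phase-shifting retrieval of both stacks, wrapped reference
#' subtraction, and unwrapping of the small residual.
#'
#' @param acq Result of [simulate_acquisition()].
#' @return Unwrapped residual [phase_map()] (specimen phase plus
#'   design-dependent distortion).
#' @export
retrieve_acquisition <- function(acq) {
  m_s <- retrieve_phase_shifting(acq$stack)
  m_e <- retrieve_phase_shifting(acq$stack_empty)
  unwrap(subtract_reference(m_s, m_e))
}

#' Quantify retrieval fidelity for one design
#'
#' @param design An [anlc_design()].
#' @param phantom,grid,optics See [simulate_acquisition()].
#' @return A `design_report`: list with `kind`, `rms_error` (rad),
#'   `halo_ratio`, `peak_error` (rad), `relative_rms` (RMS error over the
#'   footprint divided by the RMS of the true phase there), and
#'   `cross_sections` (data.frame: position, retrieved, truth).
#' @export
evaluate_design <- function(design, phantom = sperm_phantom(),
                            grid = voxel_grid(512, 512, 112, dx = 0.5, dz = 1),
                            optics = optics_config(),
                            depth_fraction = NULL) {
  acq <- simulate_acquisition(design, phantom, grid, optics, depth_fraction)
  retrieved <- retrieve_acquisition(acq)
  truth <- acq$truth
  footprint <- cell_footprint(acq$cell_opd, optics$footprint_threshold)
  eval_mask <- dilate_mask(footprint, optics$annulus_width, grid$dx)
  rms <- rms_phase_error(retrieved, truth, eval_mask)
  hr <- halo_ratio(retrieved, footprint, optics$annulus_width)
  d <- retrieved$phase - truth$phase
  d <- d - mean(d[eval_mask])
  peak <- max(abs(d[eval_mask]))
  rms_foot <- rms_phase_error(retrieved, truth, footprint)
  rel <- rms_foot / sqrt(mean(truth$phase[footprint]^2))
  center <- acq$phantom$position[1:2]
  cs_r <- cross_section(retrieved, "x", center)
  cs_t <- cross_section(truth, "x", center)
  piston <- mean((retrieved$phase - truth$phase)[eval_mask])
  structure(
    list(kind = design$kind, design = design,
         rms_error = rms, halo_ratio = hr, peak_error = peak,
         relative_rms = rel,
         cross_sections = data.frame(position = cs_r$position,
                                     retrieved = cs_r$phase - piston,
                                     truth = cs_t$phase),
         retrieved = retrieved, truth = truth, footprint = footprint),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("design_report %-18s rms %.4g rad  halo %.4g  peak %.4g rad\n",
              x$kind, x$rms_error, x$halo_ratio, x$peak_error))
  invisible(x)
}

#' Compare ANLC designs by retrieval fidelity
#'
#' Runs the identical pipeline (build, illuminate, transmit, relay,
#' interfere, retrieve, reference-subtract, metric) for every design and
#' ranks them by RMS retrieved-phase error, ascending. A design whose
#' simulation fails is dropped with a diagnostic message and the
#' comparison proceeds on the survivors.
#'
#' @param designs List of [anlc_design()]s (at least 2).
#' @param phantom,grid,optics See [simulate_acquisition()].
#' @return A `design_comparison`: list with `reports` (sorted by
#'   `rms_error`), `ranking` (design kinds, best first), `table`
#'   (data.frame: kind, rms_error, halo_ratio, peak_error), `failed`.
#' @export
compare_designs <- function(designs, phantom = sperm_phantom(),
                            grid = voxel_grid(512, 512, 112, dx = 0.5, dz = 1),
                            optics = optics_config(),
                            depth_fraction = NULL) {
  if (length(designs) < 2) abort_config("need at least 2 designs to compare")
  reports <- list()
  failed <- character(0)
  for (d in designs) {
    rep_d <- tryCatch(evaluate_design(d, phantom, grid, optics,
                                      depth_fraction),
                      error = function(e) {
                        message(sprintf("design %s failed: %s",
                                        d$kind, conditionMessage(e)))
                        NULL
                      })
    if (!is.null(rep_d)) reports[[length(reports) + 1]] <- rep_d
    else failed <- c(failed, d$kind)
  }
  if (length(reports) == 0) abort_config("all designs failed")
  ord <- order(vapply(reports, `[[`, numeric(1), "rms_error"))
  reports <- reports[ord]
  tab <- data.frame(
    kind = vapply(reports, `[[`, character(1), "kind"),
    rms_error = vapply(reports, `[[`, numeric(1), "rms_error"),
    halo_ratio = vapply(reports, `[[`, numeric(1), "halo_ratio"),
    peak_error = vapply(reports, `[[`, numeric(1), "peak_error"),
    relative_rms = vapply(reports, `[[`, numeric(1), "relative_rms")
  )
  structure(list(reports = reports, ranking = tab$kind, table = tab,
                 failed = failed),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("Design comparison (best first):\n")
  print(x$table, row.names = FALSE)
  if (length(x$failed)) cat("failed:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' The four standard well designs
#'
#' Pyramid (10 um tip), concave-bottom cylinder, truncated pyramid
#' (80 um tip) and flat-bottom cylinder, all at 125 um lateral dimension
#' and 100 um depth.
#'
#' @param lateral_dim,depth Shared dimensions, um.
#' @return Named list of four [anlc_design()]s.
#' @export
standard_designs <- function(lateral_dim = 125, depth = 100) {
  list(
    pyramid = anlc_design("pyramid", lateral_dim, depth),
    cylinder_concave = anlc_design("cylinder_concave", lateral_dim, depth),
    truncated_pyramid = anlc_design("truncated_pyramid", lateral_dim, depth),
    cylinder_flat = anlc_design("cylinder_flat", lateral_dim, depth)
  )
}
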