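# Hierarchical run configuration (YAML). Unknown keys are rejected so a
# typo cannot silently fall back to a default; value-level invariants are
# enforced by the constructors the config is translated into.

config_schema <- function() {
  list(
    seed = TRUE,
    output_dir = TRUE,
    optical = list(
      wavelength = TRUE, waist_diameter = TRUE, tilt_angle = TRUE,
      tilt_azimuth = TRUE, n_steps = TRUE, mode = TRUE, pad_factor = TRUE,
      grid = list(nx = TRUE, ny = TRUE, nz = TRUE,
                  dx = TRUE, dy = TRUE, dz = TRUE),
      camera = list(bit_depth = TRUE, noise_std = TRUE, quantize = TRUE)
    ),
    sample = list(
      designs = "list_of_designs",
      phantom = list(head_semi_axes = TRUE, head_index = TRUE,
                     midpiece_length = TRUE, midpiece_radius = TRUE,
                     tail_length = TRUE, tail_radius = TRUE,
                     tail_index = TRUE, position = TRUE, orientation = TRUE),
      depth_fraction = TRUE
    ),
    retrieval = list(annulus_width = TRUE, footprint_threshold = TRUE,
                     retrieval_mode = TRUE),
    droplet = list(V0 = TRUE, C0 = TRUE, saturation_fraction = TRUE,
                   transfer_coefficient = TRUE, duration = TRUE, dt = TRUE,
                   efflux = TRUE)
  )
}

design_schema_keys <- c("kind", "lateral_dim", "depth", "tip_dim",
                        "bottom_radius_of_curvature", "wall_index",
                        "medium_index", "substrate_index", "oil_index",
                        "strict")

validate_config_keys <- function(cfg, schema = config_schema(), where = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad)) {
    abort_config(sprintf("unknown configuration key(s)%s: %s",
                         if (nzchar(where)) paste0(" in ", where) else "",
                         paste0(where, bad, collapse = ", ")))
  }
  for (k in names(cfg)) {
    sub <- schema[[k]]
    if (identical(sub, "list_of_designs")) {
      for (i in seq_along(cfg[[k]])) {
        bad_d <- setdiff(names(cfg[[k]][[i]]), design_schema_keys)
        if (length(bad_d)) {
          abort_config(sprintf("unknown design key(s): %s",
                               paste(bad_d, collapse = ", ")))
        }
      }
    } else if (is.list(sub)) {
      validate_config_keys(cfg[[k]], sub, paste0(where, k, "."))
    }
  }
  invisible(TRUE)
}

#' Default run configuration
#'
#' The full default study: 512 x 512 lateral grid at 0.5 um pitch (256 um
#' field of view), 112 x 1 um axial slices, 0.5 um wavelength, 60 um
#' waist, 2 degree reference tilt, 4 modulator steps, the four standard
#' well designs and the default sperm phantom at mid-depth.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    output_dir = "anlcsim_out",
    optical = list(
      wavelength = 0.5, waist_diameter = 60, tilt_angle = 2,
      tilt_azimuth = 0, n_steps = 4, mode = "multislice", pad_factor = 2,
      grid = list(nx = 512, ny = 512, nz = 112, dx = 0.5, dy = 0.5, dz = 1),
      camera = list(bit_depth = 14, noise_std = 0, quantize = FALSE)
    ),
    sample = list(
      designs = list(
        list(kind = "pyramid"),
        list(kind = "cylinder_concave"),
        list(kind = "truncated_pyramid"),
        list(kind = "cylinder_flat")
      ),
      phantom = list(),
      depth_fraction = "resting"
    ),
    retrieval = list(annulus_width = 10, footprint_threshold = 0.05,
                     retrieval_mode = "phase_shifting"),
    droplet = list(V0 = 1.23, C0 = 1, saturation_fraction = 0,
                   transfer_coefficient = 1e-3, duration = 3000, dt = 1,
                   efflux = "area")
  )
}

#' Read and validate a run configuration file
#'
#' Reads a YAML configuration, rejects unknown keys, merges it over
#' [default_run_config()] and checks value invariants by constructing the
#' corresponding parameter objects.
#'
#' @param path Path to a YAML file, or a configuration list.
#' @return The validated, merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  validate_config_keys(cfg)
  merged <- utils::modifyList(default_run_config(), cfg)
  if (!is.null(cfg$sample$designs)) merged$sample$designs <- cfg$sample$designs
  # construct parameter objects so their invariants run now
  cfg_optics(merged)
  cfg_grid(merged)
  cfg_phantom(merged)
  cfg_designs(merged)
  merged
}

cfg_grid <- function(cfg) {
  g <- cfg$optical$grid
  voxel_grid(g$nx, g$ny, g$nz, g$dx, g$dy %||% g$dx, g$dz)
}

cfg_optics <- function(cfg) {
  o <- cfg$optical
  r <- cfg$retrieval
  optics_config(wavelength = o$wavelength, waist_diameter = o$waist_diameter,
                tilt_angle = o$tilt_angle, n_steps = o$n_steps,
                mode = o$mode, pad_factor = o$pad_factor,
                annulus_width = r$annulus_width,
                footprint_threshold = r$footprint_threshold,
                quantize = isTRUE(o$camera$quantize),
                bit_depth = o$camera$bit_depth,
                noise_std = o$camera$noise_std)
}

cfg_phantom <- function(cfg) {
  p <- cfg$sample$phantom
  args <- p[!vapply(p, is.null, logical(1))]
  if (!is.null(args$head_semi_axes)) {
    args$head_semi_axes <- as.numeric(unlist(args$head_semi_axes))
  }
  if (!is.null(args$position)) {
    args$position <- as.numeric(unlist(args$position))
  }
  do.call(sperm_phantom, args)
}

cfg_designs <- function(cfg) {
  lapply(cfg$sample$designs, function(d) do.call(anlc_design, d))
}

cfg_depth_fraction <- function(cfg) {
  df <- cfg$sample$depth_fraction
  if (is.null(df) || identical(df, "resting")) NULL else as.numeric(df)
}

cfg_droplet <- function(cfg) {
  d <- cfg$droplet
  list(initial = droplet_state(d$V0, d$C0),
       oil = oil_spec(d$saturation_fraction, d$transfer_coefficient),
       duration = d$duration, dt = d$dt, efflux = d$efflux)
}
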