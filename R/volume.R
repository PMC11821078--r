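#' Sampled 3D refractive-index volume
#'
#' A `sample_volume` couples a [voxel_grid()] with a refractive-index
#' distribution, evaluated slice by slice (axial index `iz`) so that large
#' volumes never need to be held in memory at once. On construction the
#' ground-truth optical path difference (OPD) map
#' \eqn{\mathrm{OPD}(x,y) = \sum_z (n - n_{medium})\,dz} is accumulated in a
#' single pass over the slices.
#'
#' @param grid A [voxel_grid()].
#' @param slice_fn Function `(iz) -> nx x ny matrix` of refractive index,
#'   or a 3D array `[nx, ny, nz]`.
#' @param medium_index Background refractive index used for the OPD
#'   definition and as the multislice propagation background.
#' @return An object of class `sample_volume` with elements `grid`,
#'   `slice_fn`, `medium_index`, and `opd` (micrometres).
#' @export
sample_volume <- function(grid, slice_fn, medium_index) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.array(slice_fn) && length(dim(slice_fn)) == 3) {
    arr <- slice_fn
    if (!all(dim(arr) == c(grid$nx, grid$ny, grid$nz))) {
      abort_dimension("index array dimensions do not match the grid")
    }
    slice_fn <- function(iz) arr[, , iz]
  }
  stopifnot(is.function(slice_fn))
  opd <- matrix(0, grid$nx, grid$ny)
  nmin <- Inf
  for (iz in seq_len(grid$nz)) {
    s <- slice_fn(iz)
    nmin <- min(nmin, min(s))
    opd <- opd + (s - medium_index) * grid$dz
  }
  if (nmin < 1) {
    abort_config("refractive indices below 1 are not physical here")
  }
  structure(
    list(grid = grid, slice_fn = slice_fn, medium_index = medium_index,
         opd = opd),
    class = "sample_volume"
  )
}

#' @export
print.sample_volume <- function(x, ...) {
  cat(sprintf("sample_volume on %d x %d x %d grid, n_medium = %.3f, peak OPD %.4g um\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$medium_index, max(x$opd)))
  invisible(x)
}

#' Ground-truth OPD map of a sample volume
#'
#' @param volume A [sample_volume()].
#' @return Matrix of OPD values in micrometres.
#' @export
ground_truth_opd <- function(volume) {
  stopifnot(inherits(volume, "sample_volume"))
  volume$opd
}

#' Materialize a sample volume as a 3D array
#'
#' Intended for small test grids; memory use is `nx * ny * nz * 8` bytes.
#' @param volume A [sample_volume()].
#' @return Numeric array `[nx, ny, nz]` of refractive index.
#' @export
as_index_array <- function(volume) {
  g <- volume$grid
  arr <- array(0, dim = c(g$nx, g$ny, g$nz))
  for (iz in seq_len(g$nz)) arr[, , iz] <- volume$slice_fn(iz)
  arr
}

# Axial layout of a well inside a grid: the well layer is centered
# axially, oil above the opening, substrate below the floor plane.
anlc_layout <- function(design, grid) {
  lz <- grid$nz * grid$dz
  if (lz < design$depth) {
    abort_dimension("grid is too shallow for the well depth")
  }
  z_open <- (lz - design$depth) / 2
  list(z_open = z_open, z_bottom = z_open + design$depth)
}

#' Build the voxelized volume of an empty ANLC
#'
#' Rasterizes a well design onto a grid: wall material outside the cavity
#' within the well layer, aqueous medium inside the cavity, oil above the
#' opening, substrate below the floor.
#'
#' @param design An [anlc_design()].
#' @param grid A [voxel_grid()] whose lateral extent exceeds `lateral_dim`
#'   and whose axial extent covers `depth`.
#' @return A [sample_volume()] with `medium_index = design$medium_index`.
#' @export
build_anlc <- function(design, grid) {
  stopifnot(inherits(design, "anlc_design"), inherits(grid, "voxel_grid"))
  if (grid$nx * grid$dx <= design$lateral_dim ||
      grid$ny * grid$dy <= design$lateral_dim) {
    abort_dimension("grid lateral extent must exceed the well lateral dimension")
  }
  lay <- anlc_layout(design, grid)
  xy <- grid_xy_mats(grid)
  slice_fn <- function(iz) {
    z <- grid_z(grid, iz)
    if (z < lay$z_open) {
      matrix(design$oil_index, grid$nx, grid$ny)
    } else if (z >= lay$z_bottom) {
      matrix(design$substrate_index, grid$nx, grid$ny)
    } else {
      d <- z - lay$z_open
      inside <- cavity_mask_at_depth(design, xy$X, xy$Y, d)
      n <- matrix(design$wall_index, grid$nx, grid$ny)
      n[inside] <- design$medium_index
      n
    }
  }
  vol <- sample_volume(grid, slice_fn, design$medium_index)
  vol$design <- design
  vol$layout <- lay
  vol
}

#' Compose an ANLC volume with a cell volume
#'
#' Cell voxels override cavity medium voxels; wall, oil and substrate
#' voxels are untouched. The ground-truth OPD is recomputed, and equals
#' the sum of the two components' OPDs wherever the cell lies entirely in
#' the cavity medium.
#'
#' @param anlc,cell [sample_volume()]s on the same grid with the same
#'   medium index.
#' @return A composed [sample_volume()].
#' @export
compose_volumes <- function(anlc, cell) {
  stopifnot(inherits(anlc, "sample_volume"), inherits(cell, "sample_volume"))
  if (!identical(unclass(anlc$grid), unclass(cell$grid))) {
    abort_dimension("ANLC and cell volumes must share one grid")
  }
  if (anlc$medium_index != cell$medium_index) {
    abort_dimension("ANLC and cell volumes must share the medium index")
  }
  med <- anlc$medium_index
  a_fn <- anlc$slice_fn
  c_fn <- cell$slice_fn
  slice_fn <- function(iz) {
    a <- a_fn(iz)
    cc <- c_fn(iz)
    ov <- (a == med) & (cc != med)
    a[ov] <- cc[ov]
    a
  }
  vol <- sample_volume(anlc$grid, slice_fn, med)
  vol$design <- anlc$design
  vol$layout <- anlc$layout
  vol
}
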