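#' Voxel grid for 3D sample volumes
#'
#' Defines the discretization on which refractive-index phantoms are built.
#' Lateral coordinates (x, y) are centered on the grid; the axial coordinate
#' z increases along the illumination direction, with slice centers at
#' `(iz - 1/2) * dz` measured from the entrance face of the volume.
#'
#' @param nx,ny,nz Voxel counts along x, y, z (each at least 8).
#' @param dx,dy,dz Voxel size in micrometres (positive).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(nx, ny, nz, dx = 0.5, dy = dx, dz = 1) {
  counts <- c(nx = nx, ny = ny, nz = nz)
  if (any(counts < 8) || any(counts != round(counts))) {
    abort_dimension("voxel counts must be integers >= 8")
  }
  if (any(c(dx, dy, dz) <= 0)) {
    abort_dimension("voxel sizes must be positive")
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
         dx = dx, dy = dy, dz = dz),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g um\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz))
  invisible(x)
}

# x/y axis coordinates (um) of voxel centers, origin at the lateral center.
grid_x <- function(grid) axis_coords(grid$nx, grid$dx)
grid_y <- function(grid) axis_coords(grid$ny, grid$dy)

# z coordinate (um) of slice iz measured from the top face of the volume.
grid_z <- function(grid, iz = seq_len(grid$nz)) (iz - 0.5) * grid$dz

# Meshgrid-style coordinate matrices, computed once per volume build.
grid_xy_mats <- function(grid) {
  x <- grid_x(grid)
  y <- grid_y(grid)
  list(
    X = matrix(x, nrow = grid$nx, ncol = grid$ny),
    Y = matrix(y, nrow = grid$nx, ncol = grid$ny, byrow = TRUE)
  )
}
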