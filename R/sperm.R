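#' Sperm-cell refractive-index phantom
#'
#' A three-part phantom: an ellipsoidal head, a cylindrical midpiece and a
#' thin cylindrical tail, all lying in one plane (the cell rests in the
#' well) with an in-plane orientation angle. The default head measures
#' 4.5 x 3.2 x 1.5 um (full axes), a typical human sperm head; the head
#' refractive index 1.37 and tail index 1.35 follow standard quantitative
#' phase imaging cell models.
#'
#' @param head_semi_axes Semi-axes (a, b, c) of the head ellipsoid in um;
#'   `a` along the cell axis, `c` along the optical axis.
#' @param head_index Refractive index of the head.
#' @param midpiece_length,midpiece_radius Midpiece cylinder dimensions, um.
#' @param tail_length,tail_radius Tail cylinder dimensions, um.
#' @param tail_index Refractive index of midpiece and tail.
#' @param position `(x, y, z)` of the head center in um; `x, y` relative to
#'   the grid center, `z` measured from the top face of the volume. A
#'   missing `z` (`NA`) is resolved to the axial grid center at build time.
#' @param orientation In-plane angle (radians); 0 points the tail along +x.
#' @return An object of class `sperm_phantom`.
#' @export
sperm_phantom <- function(head_semi_axes = c(2.25, 1.6, 0.75),
                          head_index = 1.37,
                          midpiece_length = 4, midpiece_radius = 0.5,
                          tail_length = 45, tail_radius = 0.4,
                          tail_index = 1.35,
                          position = c(0, 0, NA),
                          orientation = 0) {
  dims <- c(head_semi_axes, midpiece_length, midpiece_radius,
            tail_length, tail_radius)
  if (any(dims <= 0)) abort_config("all phantom dimensions must be positive")
  if (length(head_semi_axes) != 3) abort_config("head_semi_axes must have length 3")
  structure(
    list(head_semi_axes = head_semi_axes, head_index = head_index,
         midpiece_length = midpiece_length, midpiece_radius = midpiece_radius,
         tail_length = tail_length, tail_radius = tail_radius,
         tail_index = tail_index, position = position,
         orientation = orientation),
    class = "sperm_phantom"
  )
}

# Total in-plane span of the phantom along its axis (um), head tip to tail tip.
phantom_span <- function(p) {
  2 * p$head_semi_axes[1] + p$midpiece_length + p$tail_length
}

# Fraction of the voxel slab [z - dz/2, z + dz/2] covered by the interval
# [lo, hi] (matrices; empty where lo > hi).
slab_overlap <- function(lo, hi, z, dz) {
  pmax(0, pmin(hi, z + dz / 2) - pmax(lo, z - dz / 2)) / dz
}

#' Rasterize a sperm phantom into a sample volume
#'
#' Voxelization is exact along the optical axis: for every lateral voxel
#' column the analytic chord of each phantom component through the slab is
#' converted to a partial-volume weight, so the ground-truth OPD equals the
#' analytic chord length times the index contrast (e.g. `2 c (n_head -
#' n_medium)` at the head center) up to floating-point error.
#'
#' @param phantom A [sperm_phantom()].
#' @param grid A [voxel_grid()].
#' @param medium_index Background refractive index (must be below
#'   `head_index`).
#' @return A [sample_volume()]; everything outside the cell is at
#'   `medium_index`.
#' @export
build_sperm <- function(phantom, grid, medium_index = 1.33) {
  stopifnot(inherits(phantom, "sperm_phantom"), inherits(grid, "voxel_grid"))
  if (phantom$head_index < medium_index) {
    abort_config("head_index must not be below medium_index")
  }
  p <- phantom
  pos <- p$position
  if (length(pos) != 3) abort_config("position must be (x, y, z)")
  if (is.na(pos[3])) pos[3] <- grid$nz * grid$dz / 2
  a <- p$head_semi_axes[1]; b <- p$head_semi_axes[2]; c_ax <- p$head_semi_axes[3]
  zmax_half <- max(c_ax, p$midpiece_radius, p$tail_radius)
  # containment in the grid (lateral bounding box of the rotated axis segment)
  u_lo <- -a; u_hi <- a + p$midpiece_length + p$tail_length
  v_half <- max(b, p$midpiece_radius, p$tail_radius)
  ct <- cos(p$orientation); st <- sin(p$orientation)
  xs <- pos[1] + c(u_lo * ct - v_half * abs(st), u_hi * ct + v_half * abs(st),
                   u_lo * ct + v_half * abs(st), u_hi * ct - v_half * abs(st))
  ys <- pos[2] + c(u_lo * st - v_half * abs(ct), u_hi * st + v_half * abs(ct),
                   u_lo * st + v_half * abs(ct), u_hi * st - v_half * abs(ct))
  half_x <- grid$nx * grid$dx / 2; half_y <- grid$ny * grid$dy / 2
  if (min(xs) < -half_x || max(xs) > half_x ||
      min(ys) < -half_y || max(ys) > half_y ||
      pos[3] - zmax_half < 0 || pos[3] + zmax_half > grid$nz * grid$dz) {
    abort_dimension("phantom does not fit inside the grid")
  }

  xy <- grid_xy_mats(grid)
  # cell-frame coordinates: u along the axis (tailward), v transverse
  U <- (xy$X - pos[1]) * ct + (xy$Y - pos[2]) * st
  V <- -(xy$X - pos[1]) * st + (xy$Y - pos[2]) * ct
  dn_head <- p$head_index - medium_index
  dn_tail <- p$tail_index - medium_index

  # z-chord half-lengths per column, one matrix per component
  s_lat <- (U / a)^2 + (V / b)^2
  h_head <- c_ax * sqrt(pmax(1 - s_lat, 0))
  in_mid <- U >= a & U <= a + p$midpiece_length
  h_mid <- sqrt(pmax(p$midpiece_radius^2 - V^2, 0)) * in_mid
  u0_tail <- a + p$midpiece_length
  in_tail <- U >= u0_tail & U <= u0_tail + p$tail_length
  h_tail <- sqrt(pmax(p$tail_radius^2 - V^2, 0)) * in_tail
  z0 <- pos[3]

  slice_fn <- function(iz) {
    z <- grid_z(grid, iz)
    w_head <- slab_overlap(z0 - h_head, z0 + h_head, z, grid$dz)
    w_head[h_head == 0] <- 0
    w_mid <- slab_overlap(z0 - h_mid, z0 + h_mid, z, grid$dz)
    w_mid[h_mid == 0] <- 0
    w_tail <- slab_overlap(z0 - h_tail, z0 + h_tail, z, grid$dz)
    w_tail[h_tail == 0] <- 0
    medium_index + pmax(dn_head * w_head, dn_tail * pmax(w_mid, w_tail))
  }
  vol <- sample_volume(grid, slice_fn, medium_index)
  vol$phantom <- p
  vol$cell_z <- z0
  vol
}
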