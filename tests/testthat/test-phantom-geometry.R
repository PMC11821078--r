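test_that("closed-form cavity volumes match textbook formulas", {
  cyl <- anlc_design("cylinder_flat", lateral_dim = 125, depth = 100)
  expect_equal(cavity_volume(cyl), pi * 62.5^2 * 100 / 1e6, tolerance = 1e-12)

  fr <- anlc_design("truncated_pyramid", lateral_dim = 125, depth = 100,
                    tip_dim = 80)
  a1 <- 125^2; a2 <- 80^2
  expect_equal(cavity_volume(fr), (100 / 3) * (a1 + a2 + sqrt(a1 * a2)) / 1e6,
               tolerance = 1e-12)

  pyr <- anlc_design("pyramid", lateral_dim = 125, depth = 100, tip_dim = 10)
  expect_equal(cavity_volume(pyr),
               (100 / 3) * (125^2 + 10^2 + 125 * 10) / 1e6, tolerance = 1e-12)

  # degenerate depth
  flat0 <- anlc_design("cylinder_flat", depth = 0, strict = FALSE)
  expect_equal(cavity_volume(flat0), 0)

  # concave = cylinder minus the material between spherical floor and base
  cc <- anlc_design("cylinder_concave", lateral_dim = 125, depth = 100)
  rc <- 125; r <- 62.5
  s <- rc - sqrt(rc^2 - r^2)
  cap <- pi * s^2 * (3 * rc - s) / 3
  expect_equal(cavity_volume(cc),
               (pi * r^2 * 100 - (pi * r^2 * s - cap)) / 1e6,
               tolerance = 1e-12)
  expect_lt(cavity_volume(cc), cavity_volume(cyl))
})

test_that("voxelized cavity volume converges to the closed form", {
  d <- anlc_design("cylinder_flat", lateral_dim = 125, depth = 100)
  count_cavity <- function(grid) {
    vol <- build_anlc(d, grid)
    n_cav <- 0
    for (iz in seq_len(grid$nz)) {
      n_cav <- n_cav + sum(vol$slice_fn(iz) == d$medium_index)
    }
    n_cav * grid$dx * grid$dy * grid$dz / 1e6
  }
  v_ref <- cavity_volume(d)
  v1 <- count_cavity(voxel_grid(150, 150, 110, dx = 1, dz = 1))
  expect_lt(abs(v1 - v_ref) / v_ref, 0.02)
  v2 <- count_cavity(voxel_grid(150, 150, 440, dx = 1, dz = 0.25))
  expect_lt(abs(v2 - v_ref) / v_ref, 0.005)
})

test_that("pyramid tapers linearly to its tip dimension", {
  d <- anlc_design("pyramid", lateral_dim = 125, depth = 100, tip_dim = 10)
  expect_equal(2 * anlcsim:::cavity_half_width(d, 100), 10)
  expect_equal(2 * anlcsim:::cavity_half_width(d, 0), 125)
  expect_equal(2 * anlcsim:::cavity_half_width(d, 50), (125 + 10) / 2)
  # rasterized bottom slice width within one voxel of the tip dimension
  grid <- voxel_grid(160, 160, 220, dx = 1, dz = 0.5)
  vol <- build_anlc(d, grid)
  lay <- vol$layout
  iz_bottom <- max(which(anlcsim:::grid_z(grid) < lay$z_bottom))
  sl <- vol$slice_fn(iz_bottom)
  width <- sum(sl[, grid$ny %/% 2 + 1] == d$medium_index) * grid$dx
  expect_lte(abs(width - 10), 1 + grid$dx / 2)
})

test_that("index-matched ANLC has identically zero OPD", {
  d <- anlc_design("cylinder_flat", wall_index = 1.33, substrate_index = 1.33,
                   oil_index = 1.33, strict = FALSE)
  vol <- build_anlc(d, voxel_grid(140, 140, 28, dx = 1, dz = 4))
  expect_equal(max(abs(ground_truth_opd(vol))), 0)
})

test_that("ANLC build rejects grids that cannot hold the design", {
  d <- anlc_design("cylinder_flat", lateral_dim = 125)
  expect_error(build_anlc(d, voxel_grid(64, 64, 28, dx = 1, dz = 4)),
               class = "anlcsim_dimension_error")
  expect_error(build_anlc(d, voxel_grid(140, 140, 10, dx = 1, dz = 4)),
               class = "anlcsim_dimension_error")
  expect_error(anlc_design("bowl"))
  expect_error(anlc_design("cylinder_flat", lateral_dim = 200),
               class = "anlcsim_config_error")
  expect_silent(anlc_design("cylinder_flat", lateral_dim = 200,
                            strict = FALSE))
})

test_that("sperm head OPD matches the analytic chord through the ellipsoid", {
  g <- voxel_grid(64, 64, 16, dx = 0.25, dz = 0.5)
  ph <- small_phantom(tail_length = 4, position = c(-3, 0, 4))
  vol <- build_sperm(ph, g, 1.33)
  # chord through the head center: 2 c, times the index contrast
  expect_equal(max(ground_truth_opd(vol)), 2 * 0.75 * (1.37 - 1.33),
               tolerance = 1e-9)
  expect_gte(min(ground_truth_opd(vol)), 0)
})

test_that("zero-contrast phantom yields an identically zero OPD", {
  g <- voxel_grid(64, 64, 16, dx = 0.25, dz = 0.5)
  ph <- sperm_phantom(head_index = 1.33, tail_index = 1.33, tail_length = 4,
                      position = c(-3, 0, 4))
  vol <- build_sperm(ph, g, 1.33)
  expect_equal(max(abs(ground_truth_opd(vol))), 0)
})

test_that("rotating the phantom by pi point-reflects the OPD map", {
  g <- voxel_grid(64, 64, 16, dx = 0.25, dz = 0.5)
  # head only (symmetric component): midpiece+tail off to one side is the
  # part that moves; compare head-centered windows
  ph0 <- small_phantom(tail_length = 2, midpiece_length = 2,
                       position = c(0, 0, 4), orientation = 0)
  ph1 <- small_phantom(tail_length = 2, midpiece_length = 2,
                       position = c(0, 0, 4), orientation = pi)
  o0 <- ground_truth_opd(build_sperm(ph0, g, 1.33))
  o1 <- ground_truth_opd(build_sperm(ph1, g, 1.33))
  # position (0,0) sits at voxel center (33, 33); reflect i -> 66 - i
  idx <- 2:64
  refl <- o1[66 - idx, 66 - idx]
  expect_lt(max(abs(o0[idx, idx] - refl)), 1e-8)
})

test_that("phantom placement outside the grid is a dimension error", {
  g <- voxel_grid(32, 32, 16, dx = 0.25, dz = 0.5)
  expect_error(build_sperm(sperm_phantom(), g, 1.33),
               class = "anlcsim_dimension_error")
})

test_that("composition overrides cavity medium and is additive in OPD", {
  g <- voxel_grid(128, 128, 28, dx = 1, dz = 4)
  d <- anlc_design("cylinder_flat", lateral_dim = 100)
  dm <- anlc_design("cylinder_flat", lateral_dim = 100, wall_index = 1.33,
                    substrate_index = 1.33, oil_index = 1.33, strict = FALSE)
  anlc <- build_anlc(d, g)
  matched <- build_anlc(dm, g)
  cell <- build_sperm(small_phantom(position = c(-5, 0, NA)), g, 1.33)

  # index-matched ANLC: composition OPD equals the cell-only OPD
  expect_equal(ground_truth_opd(compose_volumes(matched, cell)),
               ground_truth_opd(cell), tolerance = 1e-12)

  # zero-contrast cell: composition OPD equals the ANLC-only OPD
  cell0 <- build_sperm(sperm_phantom(head_index = 1.33, tail_index = 1.33,
                                     tail_length = 12,
                                     position = c(-5, 0, NA)), g, 1.33)
  expect_equal(ground_truth_opd(compose_volumes(anlc, cell0)),
               ground_truth_opd(anlc), tolerance = 1e-12)

  # compose then subtract the ANLC: residual is the cell (cell entirely in
  # the cavity medium here, so additivity is exact)
  comp <- compose_volumes(anlc, cell)
  expect_equal(ground_truth_opd(comp) - ground_truth_opd(anlc),
               ground_truth_opd(cell), tolerance = 1e-12)

  # grid mismatch
  g2 <- voxel_grid(64, 64, 28, dx = 1, dz = 4)
  cell2 <- build_sperm(small_phantom(position = c(-5, 0, NA)), g2, 1.33)
  expect_error(compose_volumes(anlc, cell2),
               class = "anlcsim_dimension_error")
})

test_that("composition is idempotent for index-matched components", {
  g <- voxel_grid(64, 64, 16, dx = 1, dz = 4)
  dm <- anlc_design("cylinder_flat", lateral_dim = 50, depth = 40,
                    wall_index = 1.33, substrate_index = 1.33,
                    oil_index = 1.33, strict = FALSE)
  matched <- build_anlc(dm, g)
  cell0 <- build_sperm(sperm_phantom(head_index = 1.33, tail_index = 1.33,
                                     tail_length = 4, position = c(-3, 0, NA)),
                       g, 1.33)
  once <- compose_volumes(matched, cell0)
  twice <- compose_volumes(once, cell0)
  expect_equal(ground_truth_opd(twice), ground_truth_opd(once))
  expect_equal(max(abs(ground_truth_opd(once))), 0)
})
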