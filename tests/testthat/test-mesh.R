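test_that("the default uniaxial mesh reproduces the reference resolution", {
  mesh <- build_uniaxial_mesh(skin_stack(2))
  expect_equal(nrow(mesh$elems), 252)
  expect_equal(mesh$meta$Lx, 1)
  expect_equal(mesh$meta$Ly, 2.5)
  expect_equal(mesh$meta$Lz, 2)
  # element count = nx * ny * nz for arbitrary resolutions
  m2 <- build_uniaxial_mesh(skin_stack(2), nx = 3, ny = 4,
                            nz_layers = c(1, 1, 2))
  expect_equal(nrow(m2$elems), 3 * 4 * 4)
  # layer tags cover all elements and respect the stack
  expect_true(all(mesh$layer %in% 1:3))
  expect_equal(sum(mesh$layer == 1), 36)   # Epi: one element layer
  expect_equal(sum(mesh$layer == 3), 180)  # RD: five element layers
})

test_that("a single-layer stack tags all elements alike", {
  mesh <- build_uniaxial_mesh(mono_stack(tab1$RD, 2), nx = 2, ny = 2,
                              nz_layers = 3)
  expect_true(all(mesh$layer == 1L))
})

test_that("element geometry is valid (positive Jacobian via volume sum)", {
  st <- skin_stack(2)
  mesh <- build_uniaxial_mesh(st, nx = 2, ny = 2, nz_layers = c(1, 1, 2))
  bcs <- list(u = list(bc_dirichlet(mesh$sets$origin, 1, 0)),
              mu = integer(0))
  h <- solve_transient(mesh, st, bcs, times = 1)
  expect_equal(sum(h$dVgp), 1 * 2.5 * 2, tolerance = 1e-10)
})

test_that("suction meshes carry the right layers and a refined edge band", {
  st8 <- suction_stack(8)
  expect_equal(names(st8$layers), c("Epi", "PD", "RD", "Hypo", "Muscle"))
  expect_equal(st8$layers$RD$thickness, 1.1)
  st2 <- suction_stack(2)
  expect_false("Muscle" %in% names(st2$layers))
  mesh <- build_suction_mesh(st2, 2, radius = 8, h_edge = 0.5)
  expect_equal(mesh$meta$H, st2$total_thickness)
  # radial spacing near the probe edge is refined relative to the far
  # field (h_edge is capped so the dome is resolved)
  rs <- sort(unique(mesh$nodes[abs(mesh$nodes[, 2]) < 1e-9, 1]))
  rc <- rs[seq(1, length(rs), by = 2)]             # element breaks
  dr <- diff(rc)
  near <- which.min(abs(rc[-length(rc)] - 1))
  expect_lte(dr[near], 2 / 6 * 1.01)
  expect_gt(max(dr), 2 * dr[near])
  # pressure edges lie inside the opening
  ed <- mesh$edge_sets$opening
  expect_true(all(mesh$nodes[as.vector(ed), 1] <= 1 + 1e-9))
  expect_true(all(abs(mesh$nodes[as.vector(ed), 2] - mesh$meta$H) < 1e-9))
})

test_that("refinement factor multiplies the edge-band element count", {
  st2 <- suction_stack(2)
  m1 <- build_suction_mesh(st2, 2, radius = 8, h_edge = 0.6, refine = 1)
  m2 <- build_suction_mesh(st2, 2, radius = 8, h_edge = 0.6, refine = 2)
  band_count <- function(m) {
    # elements whose centroid radius lies within the band around the edge
    cx <- rowMeans(matrix(m$nodes[m$elems, 1], nrow(m$elems), 9))
    sum(cx > 0.5 & cx < 1.5)
  }
  expect_gte(band_count(m2), 2.2 * band_count(m1))
  expect_lte(band_count(m2), 5 * band_count(m1))
})

test_that("invalid suction geometry is rejected", {
  expect_error(build_suction_mesh(suction_stack(2), 20, radius = 8),
               "radius")
})

test_that("VTK export writes the corner sub-mesh", {
  mesh <- build_uniaxial_mesh(skin_stack(2), nx = 2, ny = 2,
                              nz_layers = c(1, 1, 1))
  f <- tempfile(fileext = ".vtk")
  write_vtk(mesh, f, point_data = list(uz = rep(0.5, nrow(mesh$nodes))))
  ln <- readLines(f)
  expect_true(any(grepl("^POINTS 36 double", ln)))   # 3x3x4 corner grid
  expect_true(any(grepl("^CELL_TYPES", ln)))
})
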