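test_that("analytic truncated-ellipsoid volume matches the half-ellipsoid formula", {
  d <- lv_dimensions(30, 65, 9, 0)
  expect_equal(analytic_cavity_volume(d), (2 / 3) * pi * 30^2 * 65 / 1000,
               tolerance = 1e-12)
  # full ellipsoid limit: truncation just below the top
  d2 <- lv_dimensions(30, 65, 9, 64.99999)
  expect_equal(analytic_cavity_volume(d2), (4 / 3) * pi * 30^2 * 65 / 1000,
               tolerance = 1e-5)
})

test_that("mesh construction gives the expected element count and layout", {
  m <- coarse_mesh()
  expect_equal(nrow(m$elems), 8 * 4 * 7)
  expect_equal(sort(unique(m$layer)), 1:7)
  expect_equal(as.vector(table(m$layer)), rep(32L, 7))
  # helix angle ramps +60 -> -60 in 20 degree steps; midwall layer is 0
  expect_equal(as.numeric(tapply(m$helix_deg, m$layer, unique)),
               seq(60, -60, by = -20))
  expect_equal(unique(m$helix_deg[m$layer == 4]), 0)
})

test_that("degenerate dimensions are rejected", {
  expect_error(lv_dimensions(30, 65, 0), "enclose")
  expect_error(lv_dimensions(30, 65, 9, 70), "base plane")
  expect_error(lv_dimensions(-1, 65, 9), "positive")
  expect_error(build_lv_mesh(n_circ = 4), "n_circ")
})

test_that("discrete cavity volume is calibrated to the target and converges when uncalibrated", {
  m <- build_lv_mesh(target_volume_ml = 122)
  expect_equal(cavity_volume(m), 122, tolerance = 1e-9)
  # inscribed placement underestimates; error shrinks with refinement
  va <- analytic_cavity_volume(lv_dimensions())
  e1 <- abs(cavity_volume(build_lv_mesh(n_circ = 8, n_long = 4,
                                        target_volume_ml = NULL)) - va) / va
  e2 <- abs(cavity_volume(build_lv_mesh(n_circ = 16, n_long = 8,
                                        target_volume_ml = NULL)) - va) / va
  e3 <- abs(cavity_volume(build_lv_mesh(n_circ = 32, n_long = 16,
                                        target_volume_ml = NULL)) - va) / va
  expect_lt(e2, e1)
  expect_lt(e3, e2)
  expect_gt(log2(e2 / e3), 1)  # at least first order in the resolution
})

test_that("wall volume approaches the analytic shell volume under refinement", {
  d <- lv_dimensions()
  shell <- analytic_cavity_volume(d, "outer") - analytic_cavity_volume(d)
  m1 <- build_lv_mesh(n_circ = 8, n_long = 4, target_volume_ml = NULL)
  m2 <- build_lv_mesh(n_circ = 24, n_long = 12, target_volume_ml = NULL)
  e1 <- abs(sum(m1$elem_vol) / 1000 - shell) / shell
  e2 <- abs(sum(m2$elem_vol) / 1000 - shell) / shell
  expect_lt(e2, e1)
  expect_lt(e2, 0.02)
})

test_that("cavity volume is translation invariant and scales cubically", {
  m <- coarse_mesh()
  v0 <- cavity_volume(m)
  u <- matrix(rep(c(3, -2, 5), each = nrow(m$nodes)), ncol = 3)
  expect_equal(cavity_volume(m, u), v0, tolerance = 1e-10)
  u_scale <- 0.1 * m$nodes
  expect_equal(cavity_volume(m, u_scale), v0 * 1.1^3, tolerance = 1e-10)
})

test_that("fibre directions are unit vectors tangent to the layer surface", {
  m <- build_lv_mesh()
  expect_equal(rowSums(m$fibres^2), rep(1, nrow(m$elems)), tolerance = 1e-12)
  nrm <- cbind(
    m$e_circ[, 2] * m$e_long[, 3] - m$e_circ[, 3] * m$e_long[, 2],
    m$e_circ[, 3] * m$e_long[, 1] - m$e_circ[, 1] * m$e_long[, 3],
    m$e_circ[, 1] * m$e_long[, 2] - m$e_circ[, 2] * m$e_long[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  expect_lt(max(abs(rowSums(m$fibres * nrm))), 1e-6)
})

test_that("wall depth fractions follow the layer structure", {
  m <- build_lv_mesh()
  wd <- wall_depth(m)
  expect_true(all(wd$depth_frac > 0 & wd$depth_frac < 1))
  fr <- tapply(wd$depth_frac, wd$layer, mean)
  expect_equal(as.numeric(fr), (1:7 - 0.5) / 7, tolerance = 1e-6)
  # strictly increasing along each transmural stack
  n_stack <- m$n_circ * m$n_long
  for (s in c(1, 17, 60, n_stack)) {
    st <- wd$depth_frac[seq(s, by = n_stack, length.out = 7)]
    expect_true(all(diff(st) > 0))
  }
  # midwall element of a ~9 mm wall sits ~4.5 mm deep at the equator
  eq4 <- which(m$layer == 4)[which.max(m$centroid[m$layer == 4, 3])]
  expect_equal(m$depth_mm[eq4], 0.5 * m$thickness_mm[eq4], tolerance = 1e-9)
  expect_equal(m$depth_mm[eq4], 4.5, tolerance = 0.1)
})

test_that("VTK export writes a readable unstructured grid", {
  m <- coarse_mesh()
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f, point_data = list(disp = matrix(0, nrow(m$nodes), 3)))
  lines <- readLines(f)
  expect_true(any(grepl("^DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl(sprintf("^POINTS %d double", nrow(m$nodes)), lines)))
  expect_true(any(grepl("^VECTORS fibre double", lines)))
  unlink(f)
})
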