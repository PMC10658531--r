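# Region selection, design frame, contour extraction, extrusion and wound
# morphometry, validated against the analytic phantom truth.

test_that("lasso selection recovers the stoma region area", {
  sc <- standard_case()
  reg <- sc$region
  expect_s3_class(reg, "fistula_region")
  expect_gt(length(reg$faces), 100)
  sub_area <- sum(face_areas(reg$mesh$vertices,
                             reg$mesh$faces[reg$faces, , drop = FALSE]))
  truth_area <- truth_stoma_area(sc$phantom$truth, margin = 2)
  expect_equal(sub_area, truth_area, tolerance = 0.03)
})

test_that("a lasso that selects nothing raises a selection error", {
  sc <- standard_case()
  far <- cbind(circle_contour(5, center = c(500, 500)), 0)
  expect_error(select_fistula_region(sc$mesh, far), class = "selection_error")
  expect_error(select_fistula_region(sc$mesh, far[1:2, ]),
               class = "selection_error")
})

test_that("the design frame looks along the outward surface normal", {
  sc <- standard_case()
  fr <- sc$frame
  expect_s3_class(fr, "design_frame")
  # the phantom floor is horizontal: frame z-axis ~ +z
  expect_gt(sum(fr$rotation[, 3] * c(0, 0, 1)), 0.99)
  # origin near the stoma centre at floor level (lasso has margin 2)
  st <- sc$phantom$truth$spec$stomas[[1]]
  expect_equal(fr$origin[1:2], st$center, tolerance = 1)
  expect_equal(fr$origin[3], sc$phantom$truth$bed_level, tolerance = 1.5)
})

test_that("the extracted contour matches the lasso's analytic area", {
  sc <- standard_case()
  ct <- extract_contour(sc$region, sc$frame)
  expect_equal(nrow(ct), 256)
  # region boundary ~ circle of radius stoma r + lasso margin, quantised by
  # the 1 mm grid
  expect_equal(polygon_area(ct), pi * 12^2, tolerance = 0.05)
  expect_equal(polygon_centroid(ct), c(0, 0), tolerance = 1)
})

test_that("extrusion volume is exactly area x height and scales as s^2", {
  lshape <- rbind(c(0, 0), c(4, 0), c(4, 1), c(1, 1), c(1, 3), c(0, 3))
  for (ct in list(circle_contour(10), lshape)) {
    prism <- extrude_fistula(fistula_contour(ct), -2, 13)
    expect_true(is_watertight(prism))
    expect_equal(mesh_stats(prism)$euler_characteristic, 2)
    expect_equal(mesh_volume(prism), polygon_area(ensure_ccw(ct)) * 15,
                 tolerance = 1e-12)
  }
  base <- mesh_volume(extrude_fistula(fistula_contour(circle_contour(5)), 0, 4))
  for (s in c(2, 3)) {
    scaled <- mesh_volume(extrude_fistula(
      fistula_contour(circle_contour(5 * s)), 0, 4))
    expect_equal(scaled, s^2 * base, tolerance = 1e-9)
  }
  expect_error(extrude_fistula(fistula_contour(circle_contour(5)), 3, 3),
               class = "geometry_error")
})

test_that("measure_wound recovers the phantom truth", {
  sc <- standard_case()
  truth <- sc$phantom$truth
  meas <- measure_wound(sc$mesh, truth_rim(truth), list(sc$region))
  expect_equal(meas$length, truth$length, tolerance = 0.01)
  expect_equal(meas$width, truth$width, tolerance = 0.01)
  expect_equal(meas$depth, truth$depth, tolerance = 0.02)
  expect_equal(meas$n_orifices, 1)
  expect_equal(meas$fistula_orifice_heights, truth$stoma_heights,
               tolerance = 0.05)
  expect_gte(meas$length, meas$width)
  swapped <- measure_wound(sc$mesh, truth_rim(truth), swap_axes = TRUE)
  expect_equal(swapped$length, meas$width)
  expect_equal(swapped$width, meas$length)
})

test_that("measurements are invariant under rigid motion", {
  sc <- standard_case()
  truth <- sc$phantom$truth
  rim <- truth_rim(truth)
  lasso <- truth_stoma_lasso(truth)
  meas0 <- measure_wound(sc$mesh, rim, list(sc$region))

  th <- 0.7; ax <- 0.25
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  R <- Rx %*% R
  shift <- c(-12, 30, 5)
  move <- function(p) sweep(p %*% t(R), 2, shift, `+`)
  mesh_m <- sc$mesh
  mesh_m$vertices <- move(mesh_m$vertices)
  reg_m <- select_fistula_region(mesh_m, move(lasso))
  meas_m <- measure_wound(mesh_m, move(rim), list(reg_m))
  expect_equal(meas_m$length, meas0$length, tolerance = 1e-6)
  expect_equal(meas_m$width, meas0$width, tolerance = 1e-6)
  expect_equal(meas_m$depth, meas0$depth, tolerance = 1e-6)
  expect_equal(meas_m$fistula_orifice_heights,
               meas0$fistula_orifice_heights, tolerance = 1e-6)
})

test_that("two stomas yield two orifice heights", {
  spec <- phantom_spec(wound_axes = c(60, 40), depth = 20,
                       stomas = list(
                         list(center = c(-12, 0), radius = 7, height = 12),
                         list(center = c(12, 0), radius = 7, height = 16)),
                       sigma = 0, n_points = 120000, seed = 11)
  ph <- generate_phantom(spec)
  mesh <- reconstruct_surface(ph$cloud, 1)
  regs <- list(select_fistula_region(mesh, truth_stoma_lasso(ph$truth, 1)),
               select_fistula_region(mesh, truth_stoma_lasso(ph$truth, 2)))
  meas <- measure_wound(mesh, truth_rim(ph$truth), regs)
  expect_equal(meas$n_orifices, 2)
  expect_equal(meas$fistula_orifice_heights, c(1.2, 1.6), tolerance = 0.05)
})
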