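# Parametric ring-adapter construction against closed-form solids and an
# independent ray-casting volume oracle.

test_that("the middle-sketch fraction follows the height rule", {
  expect_equal(resolve_middle_fraction(10), 0.25)
  expect_equal(resolve_middle_fraction(20), 0.15)
  expect_equal(resolve_middle_fraction(15), 0.20)
  expect_equal(resolve_middle_fraction(5), 0.25)   # clamped
  expect_equal(resolve_middle_fraction(30), 0.15)  # clamped
  expect_error(resolve_middle_fraction(0), class = "design_infeasible")
})

test_that("adapter_spec validates the clinical parameter ranges", {
  expect_s3_class(adapter_spec(), "adapter_spec")
  expect_warning(adapter_spec(height = 25), "outside")
  expect_warning(adapter_spec(height = 8), "outside")
  expect_error(adapter_spec(top_offset = 21), class = "design_infeasible")
  expect_error(adapter_spec(bottom_offset = 0), class = "design_infeasible")
  expect_error(adapter_spec(hole_clearance = 1.5), class = "design_infeasible")
  expect_error(adapter_spec(middle_fraction = 1), class = "design_infeasible")
})

test_that("sketches sit at z = 0, f*h, h with the requested offsets", {
  bs <- build_sketches(circle_contour(10), adapter_spec(height = 15))
  zs <- vapply(bs$sketches, `[[`, 0, "z")
  expect_equal(zs, c(0, 0.20 * 15, 15))
  radii <- lapply(bs$sketches, function(s) sqrt(rowSums(s$contour^2)))
  expect_equal(range(radii[[1]]), c(15, 15), tolerance = 0.005)
  expect_equal(range(radii[[2]]), c(15, 15), tolerance = 0.005)
  expect_equal(range(radii[[3]]), c(25, 25), tolerance = 0.005)
  expect_equal(range(sqrt(rowSums(bs$hole^2))), c(10, 10), tolerance = 0.005)
})

test_that("an eccentricity pushing the hole outside is infeasible", {
  err <- expect_error(
    build_sketches(circle_contour(10),
                   adapter_spec(height = 15, eccentricity = c(18, 0))),
    class = "design_infeasible")
  expect_match(conditionMessage(err), "violating margin")
})

test_that("lofted solids match closed-form volumes within 0.5%", {
  # cylinder r = 15, h = 15
  cyl <- loft_solid(list(make_sketch(circle_contour(15), 0),
                         make_sketch(circle_contour(15), 7.5),
                         make_sketch(circle_contour(15), 15)))
  expect_true(is_watertight(cyl))
  expect_equal(mesh_stats(cyl)$euler_characteristic, 2)
  expect_equal(mesh_volume(cyl), pi * 15^2 * 15, tolerance = 0.005)
  # frustum R = 20 -> r = 10, h = 12
  fr <- loft_solid(list(make_sketch(circle_contour(20), 0),
                        make_sketch(circle_contour(10), 12)))
  expect_equal(mesh_volume(fr), pi * 12 / 3 * (400 + 200 + 100),
               tolerance = 0.005)
  expect_error(loft_solid(list(make_sketch(circle_contour(10), 5),
                               make_sketch(circle_contour(10), 5))),
               class = "geometry_error")
})

test_that("the ring adapter equals the annular cylinder closed form", {
  loft <- loft_solid(list(make_sketch(circle_contour(15), 0),
                          make_sketch(circle_contour(15), 15)))
  ring <- subtract_hole(loft, circle_contour(10), 15)
  expect_true(is_watertight(ring$mesh))
  expect_equal(mesh_stats(ring$mesh)$euler_characteristic, 0)
  expect_equal(mesh_volume(ring$mesh), pi * (15^2 - 10^2) * 15,
               tolerance = 0.005)
  # hole must be strictly inside every cross-section
  expect_error(subtract_hole(loft, circle_contour(15), 15),
               class = "design_infeasible")
})

test_that("volume identity: volume(adapter) + area(hole) * h = volume(loft)", {
  ct <- ellipse_contour(12, 8)
  spec <- adapter_spec(height = 14, bottom_offset = 4, top_offset = 12,
                       eccentricity = c(3, -2))
  bs <- build_sketches(ct, spec)
  loft <- loft_solid(bs$sketches)
  ring <- subtract_hole(loft, bs$hole, spec$height, spec)
  expect_equal(mesh_volume(ring$mesh) + polygon_area(ring$hole) * spec$height,
               mesh_volume(loft), tolerance = 1e-9)
})

test_that("the voxel ray-casting oracle confirms the mesh volume", {
  ad <- design_adapter(circle_contour(8),
                       adapter_spec(height = 12, bottom_offset = 4,
                                    top_offset = 10))
  vox <- voxel_volume(ad$mesh, pitch = 0.25)
  expect_equal(vox, mesh_volume(ad$mesh), tolerance = 0.01)
})

test_that("ledge reports give cm ranges, collapsing equal endpoints", {
  conc <- design_adapter(circle_contour(10),
                         adapter_spec(height = 15, bottom_offset = 5,
                                      top_offset = 15))
  L <- ledge_report(conc)
  expect_equal(L$bottom_ledge, "0.5")
  expect_equal(L$top_ledge, "1.5")
  expect_equal(L$height, 1.5)
  expect_equal(L$length, 5.0, tolerance = 0.01)  # top diameter 2*(10+15) mm

  ecc <- design_adapter(circle_contour(10),
                        adapter_spec(height = 15, bottom_offset = 5,
                                     top_offset = 10, eccentricity = c(2, 0)))
  Le <- ledge_report(ecc)
  expect_equal(Le$top_ledge, "0.8–1.2")
  expect_equal(Le$bottom_ledge, "0.5")
})

test_that("fit check passes on the design's own wound and fails when moved", {
  sc <- standard_case()
  ct <- extract_contour(sc$region, sc$frame)
  ad <- design_adapter(ct, adapter_spec(height = 15, bottom_offset = 5,
                                        top_offset = 12))
  # resting pose: lift the bottom plane onto the highest contact point
  wq <- to_frame(sc$mesh$vertices, sc$frame)
  samp <- rbind(ad$rings[[1]], ad$hole, (ad$rings[[1]] + ad$hole) / 2)
  lift <- max(eafadapt:::surface_height_at(wq, samp), na.rm = TRUE)
  fit <- fit_check(ad, sc$mesh, sc$frame, offset = c(0, 0, lift),
                   fistula_contour = ct,
                   rim = truth_rim(sc$phantom$truth))
  expect_equal(fit$max_penetration, 0)
  expect_true(fit$hole_contains_fistula)
  expect_gt(fit$min_clearance_to_rim, 0)

  # shifted sideways by more than the clearance: fistula leaves the hole
  bad <- fit_check(ad, sc$mesh, sc$frame, offset = c(10, 0, lift),
                   fistula_contour = ct)
  expect_false(bad$hole_contains_fistula)
})

test_that("adapter volume grows monotonically with the top offset", {
  ct <- circle_contour(10)
  vols <- vapply(c(8, 12, 16, 20), function(d_t)
    mesh_volume(design_adapter(ct, adapter_spec(height = 15, top_offset = d_t))$mesh),
    0)
  expect_true(all(diff(vols) > 0))
})

test_that("the design is equivariant under in-plane rotation of the contour", {
  ct <- ellipse_contour(12, 8)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  spec <- adapter_spec(height = 15, bottom_offset = 5, top_offset = 12)
  v0 <- mesh_volume(design_adapter(ct, spec)$mesh)
  v1 <- mesh_volume(design_adapter(ct %*% t(R), spec)$mesh)
  expect_equal(v1, v0, tolerance = 1e-3)
})
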