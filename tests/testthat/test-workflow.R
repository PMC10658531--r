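# End-to-end case workflow: QC gate, adapter versions, remodeling, reports.

small_inputs <- function(seed = 7, n_points = 120000, ...) {
  ph <- generate_phantom(phantom_spec(n_points = n_points, seed = seed, ...))
  list(phantom = ph, rim = truth_rim(ph$truth),
       lasso = truth_stoma_lasso(ph$truth))
}

test_that("the workflow stops at QC when the cloud is short and no re-scan exists", {
  inp <- small_inputs(n_points = 30000)
  cfg <- workflow_config()   # 400,000-point gate
  bundle <- run_workflow(inp$phantom$cloud, inp$rim, inp$lasso, cfg)
  expect_equal(bundle$status, "rescan_required")
  expect_match(bundle$message, "re-scan")
  expect_length(bundle$versions, 0)
})

test_that("a merged re-scan passes QC and completes the workflow", {
  first <- generate_phantom(phantom_spec(n_points = 250000, seed = 21))
  second <- generate_phantom(phantom_spec(n_points = 250000, seed = 22))
  rim <- truth_rim(first$truth)
  lasso <- truth_stoma_lasso(first$truth)
  bundle <- run_workflow(first$cloud, rim, lasso, workflow_config(),
                         second_cloud = second$cloud, case_id = "merged-case")
  expect_equal(bundle$status, "complete")
  expect_length(bundle$qc, 2)
  expect_equal(bundle$qc[[1]]$decision, "rescan")
  expect_equal(bundle$qc[[2]]$decision, "accept")
  expect_length(bundle$versions, 1)
  v <- bundle$versions[[1]]
  expect_true(is_watertight(v$adapter$mesh))
  expect_equal(v$fit$max_penetration, 0)
  expect_true(v$fit$hole_contains_fistula)
})

test_that("remodeling appends a second, smaller-hole adapter version", {
  inp <- small_inputs()
  cfg <- workflow_config(qc_threshold = 100000)
  bundle <- run_workflow(inp$phantom$cloud, inp$rim, inp$lasso, cfg,
                         case_id = "remodel-case")
  expect_equal(bundle$status, "complete")
  shrunk <- generate_phantom(phantom_spec(
    wound_axes = c(40, 28), depth = 14,
    stomas = list(list(center = c(3, 0), radius = 7, height = 10)),
    n_points = 120000, seed = 8))
  bundle <- remodel_case(bundle, shrunk$cloud, truth_rim(shrunk$truth),
                         truth_stoma_lasso(shrunk$truth), cfg)
  expect_length(bundle$versions, 2)
  a1 <- polygon_area(bundle$versions[[1]]$adapter$hole)
  a2 <- polygon_area(bundle$versions[[2]]$adapter$hole)
  expect_lt(a2, a1)
  rep <- render_report(bundle)
  expect_equal(rep$version, 1:2)
  expect_true(all(rep$hole_contains_fistula))
})

test_that("reports render ledges as ranges, collapsing equal endpoints", {
  ad <- design_adapter(circle_contour(10),
                       adapter_spec(height = 15, bottom_offset = 5,
                                    top_offset = 15))
  bundle <- structure(list(case_id = "x", status = "complete", qc = list(),
                           versions = list(list(
                             adapter = ad, ledges = ledge_report(ad),
                             fit = list(max_penetration = 0,
                                        hole_contains_fistula = TRUE)))),
                      class = "case_bundle")
  rep <- render_report(bundle)
  expect_equal(rep$bottom_ledge, "0.5")   # not "0.5–0.5"
  expect_equal(rep$top_ledge, "1.5")
  empty <- structure(list(versions = list()), class = "case_bundle")
  expect_error(render_report(empty), class = "report_error")
})

test_that("identical runs write byte-identical JSON reports", {
  inp <- small_inputs()
  cfg <- workflow_config(qc_threshold = 100000)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  b1 <- run_workflow(inp$phantom$cloud, inp$rim, inp$lasso, cfg, case_id = "det")
  b2 <- run_workflow(inp$phantom$cloud, inp$rim, inp$lasso, cfg, case_id = "det")
  write_case_report(b1, f1)
  write_case_report(b2, f2)
  expect_identical(readLines(f1), readLines(f2))
  js <- jsonlite::read_json(f1)
  expect_equal(js$status, "complete")
  expect_equal(js$measurements$length_cm, 12)
})

test_that("YAML configs load with unknown keys rejected", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("qc_threshold: 150000", "grid_pitch: 0.8", "height: 12"), f)
  cfg <- read_workflow_config(f)
  expect_equal(cfg$qc_threshold, 150000)
  expect_equal(cfg$grid_pitch, 0.8)
  expect_equal(cfg$height, 12)
  expect_equal(cfg$bottom_offset, 5)     # defaults preserved
  writeLines(c("qc_threshold: 1", "frobnicate: yes"), f)
  expect_error(read_workflow_config(f), "frobnicate", class = "config_error")
  expect_error(workflow_config(grid_pitch = 0), class = "config_error")
})

test_that("workflow inputs may be given as file paths", {
  inp <- small_inputs(n_points = 120000)
  pc <- tempfile(fileext = ".xyz")
  write_point_cloud(inp$phantom$cloud, pc)
  rimf <- tempfile(fileext = ".txt")
  writeLines(sprintf("%.6f %.6f %.6f", inp$rim[, 1], inp$rim[, 2],
                     inp$rim[, 3]), rimf)
  lasf <- tempfile(fileext = ".txt")
  writeLines(sprintf("%.6f %.6f %.6f", inp$lasso[, 1], inp$lasso[, 2],
                     inp$lasso[, 3]), lasf)
  bundle <- run_workflow(pc, rimf, lasf, workflow_config(qc_threshold = 1e5))
  expect_equal(bundle$status, "complete")
  expect_equal(bundle$measurements$length, 12, tolerance = 0.01)
})
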