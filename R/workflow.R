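# End-to-end case workflow: scan QC -> (re-scan merge) -> reconstruct ->
# measure -> design -> fit-check, with a remodeling loop that appends new
# adapter versions as the wound evolves.

#' Default workflow configuration
#'
#' @param qc_threshold minimum point count before re-scan is demanded.
#' @param grid_pitch reconstruction grid pitch, mm.
#' @param height device height in mm, or `"auto"` (10 x wound depth in cm,
#'   clamped to the clinical 10-20 mm range).
#' @param bottom_offset,middle_fraction,hole_clearance see [adapter_spec()].
#' @param top_offset top-brim offset in mm, or `"auto"` (rim clearance minus
#'   a 5 mm margin, capped at 20 mm).
#' @param seed seed for any stochastic step.
#' @return list of validated settings.
#' @export
workflow_config <- function(qc_threshold = 400000, grid_pitch = 1,
                            height = "auto", bottom_offset = 5,
                            top_offset = "auto", middle_fraction = "auto",
                            hole_clearance = 0, seed = 1) {
  if (qc_threshold < 0) stop_with("config_error", "qc_threshold must be >= 0")
  if (grid_pitch <= 0) stop_with("config_error", "grid_pitch must be > 0")
  list(qc_threshold = qc_threshold, grid_pitch = grid_pitch,
       height = height, bottom_offset = bottom_offset,
       top_offset = top_offset, middle_fraction = middle_fraction,
       hole_clearance = hole_clearance, seed = seed)
}

#' Read a workflow configuration from YAML
#'
#' Declarative per-case settings; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a validated config list (see [workflow_config()]).
#' @export
read_workflow_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(workflow_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_with("config_error", paste("unknown config keys:",
                                    paste(bad, collapse = ", ")))
  do.call(workflow_config, vals)
}

#' Run the case workflow
#'
#' QC gates the cloud (merging a second scan when supplied); the surface is
#' reconstructed, the wound and fistula are measured, the adapter is
#' designed from the extracted fistula contour and fit-checked in a resting
#' pose (bottom plane lifted to the highest contact point, so penetration is
#' zero by construction and the residual clearance is reported).
#'
#' @param cloud a `point_cloud` (or path to one).
#' @param wound_lasso wound rim polyline, n x 3 (or path).
#' @param fistula_lasso stoma lasso polyline, n x 3 (or path), or a list of
#'   them for multiple orifices.
#' @param config from [workflow_config()].
#' @param second_cloud optional re-scan merged in when the first fails QC.
#' @param case_id free-text case label.
#' @return object of class `case_bundle`: `case_id`, `qc` reports, the
#'   mesh, measurements and a list `versions` of adapter records
#'   (`adapter`, `ledges`, `fit`, `timestamp`). If QC demands a re-scan and
#'   none is available the bundle stops at the QC stage with
#'   `status = "rescan_required"`.
#' @export
run_workflow <- function(cloud, wound_lasso, fistula_lasso,
                         config = workflow_config(), second_cloud = NULL,
                         case_id = "case") {
  if (is.character(cloud)) cloud <- read_point_cloud(cloud)
  if (is.character(wound_lasso)) wound_lasso <- read_lasso(wound_lasso)
  lassos <- if (is.list(fistula_lasso)) fistula_lasso else list(fistula_lasso)
  lassos <- lapply(lassos, function(l) if (is.character(l)) read_lasso(l) else l)

  bundle <- structure(list(case_id = case_id, qc = list(), status = "running",
                           versions = list()),
                      class = "case_bundle")
  qc1 <- qc_point_cloud(cloud, config$qc_threshold)
  bundle$qc <- list(qc1)
  if (qc1$decision == "rescan") {
    if (is.null(second_cloud)) {
      bundle$status <- "rescan_required"
      bundle$message <- sprintf(
        "cloud has %d points (< %d): re-scan the wound and re-run",
        qc1$n_points, qc1$threshold)
      return(bundle)
    }
    if (is.character(second_cloud)) second_cloud <- read_point_cloud(second_cloud)
    cloud <- merge_clouds(cloud, second_cloud)
    qc2 <- qc_point_cloud(cloud, config$qc_threshold)
    bundle$qc <- c(bundle$qc, list(qc2))
    if (qc2$decision == "rescan") {
      bundle$status <- "rescan_required"
      bundle$message <- sprintf(
        "merged cloud still has %d points (< %d)", qc2$n_points, qc2$threshold)
      return(bundle)
    }
  }
  bundle$cloud <- cloud
  add_adapter_version(bundle, cloud, wound_lasso, lassos, config)
}

# Shared by run_workflow and remodel_case: reconstruct, measure, design,
# fit-check, and append the new adapter version to the bundle.
add_adapter_version <- function(bundle, cloud, wound_lasso, lassos, config) {
  mesh <- reconstruct_surface(cloud, config$grid_pitch)
  regions <- lapply(lassos, function(l) select_fistula_region(mesh, l))
  meas <- measure_wound(mesh, wound_lasso, regions)
  frame <- fit_design_frame(regions[[1]])
  contour <- extract_contour(regions[[1]], frame)

  h <- config$height
  if (identical(h, "auto"))
    h <- min(20, max(10, 10 * meas$depth))
  d_t <- config$top_offset
  if (identical(d_t, "auto")) {
    rim2 <- to_frame(wound_lasso, frame)[, 1:2, drop = FALSE]
    clearance <- min(dist_to_polygon(contour, rim2))
    d_t <- min(20, clearance - 5)
    if (d_t <= config$bottom_offset)
      d_t <- config$bottom_offset + 1  # fistula hugging the rim: minimal brim
  }
  spec <- adapter_spec(height = h, bottom_offset = config$bottom_offset,
                       top_offset = d_t,
                       middle_fraction = config$middle_fraction,
                       hole_clearance = config$hole_clearance)
  adapter <- design_adapter(contour, spec, source = bundle$case_id)

  # resting pose: lift the bottom plane onto the highest contact point
  wq <- to_frame(mesh$vertices, frame)
  samp <- rbind(adapter$rings[[1]], adapter$hole,
                (adapter$rings[[1]] + adapter$hole) / 2)
  z_surf <- surface_height_at(wq, samp)
  lift <- max(z_surf, na.rm = TRUE) - adapter$ring_z[1]
  fit <- fit_check(adapter, mesh, frame, offset = c(0, 0, lift),
                   fistula_contour = contour, rim = wound_lasso)

  bundle$mesh <- mesh
  bundle$measurements <- meas
  bundle$versions <- c(bundle$versions, list(list(
    adapter = adapter, ledges = ledge_report(adapter), fit = fit,
    frame = frame, pose_lift_mm = lift, height_mm = h, top_offset_mm = d_t,
    timestamp = Sys.time())))
  bundle$status <- "complete"
  bundle
}

#' Remodel: append a new adapter version from a fresh scan
#'
#' The remodeling loop: when a cure reveals geometric change, the wound is
#' re-scanned and the device regenerated from the latest measurements.
#'
#' @param bundle an existing `case_bundle`.
#' @param cloud the new `point_cloud`.
#' @param wound_lasso,fistula_lasso the new selections.
#' @param config workflow settings.
#' @return the bundle with one more entry in `versions`.
#' @export
remodel_case <- function(bundle, cloud, wound_lasso, fistula_lasso,
                         config = workflow_config()) {
  lassos <- if (is.list(fistula_lasso)) fistula_lasso else list(fistula_lasso)
  add_adapter_version(bundle, cloud, wound_lasso, lassos, config)
}

#' @export
print.case_bundle <- function(x, ...) {
  cat("case_bundle '", x$case_id, "': status ", x$status, ", ",
      length(x$versions), " adapter version(s)\n", sep = "")
  invisible(x)
}

#' Per-version device report
#'
#' One row per adapter version in chronological order, with the device
#' dimensions in cm and ledges rendered as ranges (single number when the
#' endpoints agree).
#'
#' @param bundle a `case_bundle` with at least one adapter version.
#' @return data frame with columns version, height_cm, width_cm, length_cm,
#'   top_ledge, bottom_ledge, max_penetration_mm, hole_contains_fistula.
#' @export
render_report <- function(bundle) {
  if (length(bundle$versions) == 0)
    stop_with("report_error", "bundle has no adapter versions")
  rows <- lapply(seq_along(bundle$versions), function(i) {
    v <- bundle$versions[[i]]
    L <- v$ledges
    data.frame(version = i,
               height_cm = round_half_up(L$height, 1),
               width_cm = round_half_up(L$width, 1),
               length_cm = round_half_up(L$length, 1),
               top_ledge = L$top_ledge, bottom_ledge = L$bottom_ledge,
               max_penetration_mm = round(v$fit$max_penetration, 2),
               hole_contains_fistula = v$fit$hole_contains_fistula)
  })
  do.call(rbind, rows)
}

#' Serialize a case bundle report as JSON
#'
#' Deterministic output (timestamps excluded): identical runs give
#' byte-identical files.
#'
#' @param bundle a `case_bundle`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(bundle, path) {
  meas <- bundle$measurements
  out <- list(
    case_id = bundle$case_id,
    status = bundle$status,
    qc = lapply(bundle$qc, function(q) q[c("n_points", "threshold", "decision")]),
    measurements = if (!is.null(meas)) list(
      length_cm = round_half_up(meas$length, 1),
      width_cm = round_half_up(meas$width, 1),
      depth_cm = round_half_up(meas$depth, 1),
      orifice_heights_cm = round_half_up(meas$fistula_orifice_heights, 1),
      n_orifices = meas$n_orifices),
    versions = render_report_list(bundle))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

render_report_list <- function(bundle) {
  if (length(bundle$versions) == 0) return(list())
  df <- render_report(bundle)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}
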