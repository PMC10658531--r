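# Parametric ring-adapter construction: three offset sketches, loft,
# through-hole ring assembly, dimension/ledge report and fit check.
#
# Because the hole is a straight extrusion strictly inside every cross
# section, the ring is assembled analytically (outer loft wall + inner prism
# wall + annular caps) instead of via a general mesh Boolean: robustness over
# generality.

#' Adapter design parameters
#'
#' @param height device height h in mm (the clinical range is 10-20 mm; a
#'   warning is issued outside it).
#' @param bottom_offset radial offset of the bottom sketch from the fistula
#'   contour, mm (clinical default 5 mm: kept small so the NPWT sponge
#'   contacts as much wound bed as possible).
#' @param top_offset radial offset of the top brim, mm, up to 20 mm (the brim
#'   holds the sealing film and is narrowed when the fistula sits close to
#'   the adipose wall).
#' @param middle_fraction height fraction of the middle sketch in (0, 1), or
#'   `"auto"` for the height-dependent rule of [resolve_middle_fraction()].
#' @param middle_offset radial offset of the middle sketch, mm; defaults to
#'   `bottom_offset` (a narrow body flaring to the top brim — the conical
#'   morphology the NPWT seal relies on).
#' @param eccentricity 2-vector, mm: lateral shift of the top sketch used to
#'   steer the brim away from the adipose wall.
#' @param hole_clearance extra radial clearance of the hole around the
#'   fistula contour, mm in [0, 1] (0 = hole has exactly the intestinal
#'   surface geometry).
#' @return object of class `adapter_spec`.
#' @export
adapter_spec <- function(height = 15, bottom_offset = 5, top_offset = 15,
                         middle_fraction = "auto", middle_offset = NULL,
                         eccentricity = c(0, 0), hole_clearance = 0) {
  if (height <= 0) stop_with("design_infeasible", "height must be > 0")
  if (height < 10 || height > 20)
    warning("device height ", height, " mm is outside the usual 10-20 mm range")
  if (is.null(middle_offset)) middle_offset <- bottom_offset
  if (bottom_offset <= 0 || top_offset <= 0 || middle_offset <= 0)
    stop_with("design_infeasible", "sketch offsets must be > 0")
  if (top_offset > 20)
    stop_with("design_infeasible", "top offset exceeds the 20 mm maximum")
  if (!identical(middle_fraction, "auto")) {
    if (middle_fraction <= 0 || middle_fraction >= 1)
      stop_with("design_infeasible", "middle_fraction must lie in (0, 1)")
  }
  if (hole_clearance < 0 || hole_clearance > 1)
    stop_with("design_infeasible", "hole_clearance must lie in [0, 1] mm")
  structure(list(height = height, bottom_offset = bottom_offset,
                 top_offset = top_offset, middle_fraction = middle_fraction,
                 middle_offset = middle_offset,
                 eccentricity = as.numeric(eccentricity),
                 hole_clearance = hole_clearance),
            class = "adapter_spec")
}

#' @export
print.adapter_spec <- function(x, ...) {
  f <- if (identical(x$middle_fraction, "auto"))
    sprintf("auto (%.2f)", resolve_middle_fraction(x$height)) else
      sprintf("%.2f", x$middle_fraction)
  cat(sprintf(
    "adapter_spec: h=%.1f mm, offsets b/m/t = %.1f/%.1f/%.1f mm, f=%s, e=(%.1f, %.1f) mm, clearance %.1f mm\n",
    x$height, x$bottom_offset, x$middle_offset, x$top_offset, f,
    x$eccentricity[1], x$eccentricity[2], x$hole_clearance))
  invisible(x)
}

#' Height-dependent middle-sketch fraction
#'
#' The middle sketch sits between 15% and 25% of the device height: the
#' lower the device, the greater the fraction. Linear between the anchors
#' f = 0.25 at h = 10 mm and f = 0.15 at h = 20 mm, clamped outside.
#'
#' @param h device height, mm (> 0).
#' @return fraction in [0.15, 0.25].
#' @export
resolve_middle_fraction <- function(h) {
  if (any(h <= 0)) stop_with("design_infeasible", "height must be > 0")
  pmin(0.25, pmax(0.15, 0.25 - 0.01 * (h - 10)))
}

#' Build the three device sketches
#'
#' Sketches at z = 0 (bottom, offset `bottom_offset`), z = f*h (middle,
#' offset `middle_offset`) and z = h (top, offset `top_offset`, translated
#' by the eccentricity). Each sketch must strictly contain the hole contour
#' (the fistula contour offset by the clearance); otherwise the design is
#' infeasible and the violating margin is reported.
#'
#' @param contour the fistula contour (n x 2 mm, simple, CCW).
#' @param spec an `adapter_spec`.
#' @param n_samples vertex count of each sketch.
#' @return list with `sketches` (list of three `plane_sketch`: fields `z`,
#'   `contour`) and `hole` (the hole contour).
#' @export
build_sketches <- function(contour, spec, n_samples = 256) {
  contour <- fistula_contour(resample_contour(ensure_ccw(as.matrix(contour)),
                                              n_samples))
  f <- if (identical(spec$middle_fraction, "auto"))
    resolve_middle_fraction(spec$height) else spec$middle_fraction
  hole <- offset_contour(contour, spec$hole_clearance, n_samples)
  bottom <- offset_contour(contour, spec$bottom_offset, n_samples)
  middle <- offset_contour(contour, spec$middle_offset, n_samples)
  top <- offset_contour(contour, spec$top_offset, n_samples)
  top <- sweep(top, 2, spec$eccentricity, `+`)
  sk <- list(
    structure(list(z = 0, contour = bottom), class = "plane_sketch"),
    structure(list(z = f * spec$height, contour = middle), class = "plane_sketch"),
    structure(list(z = spec$height, contour = top), class = "plane_sketch"))
  for (s in sk) {
    viol <- !points_in_polygon(hole, s$contour, strict = TRUE)
    if (any(viol)) {
      margin <- max(dist_to_polygon(hole[viol, , drop = FALSE], s$contour))
      stop_with("design_infeasible", sprintf(
        "sketch at z=%.1f mm does not contain the hole contour (violating margin %.2f mm)",
        s$z, margin))
    }
  }
  list(sketches = sk, hole = hole, middle_fraction = f)
}

# Cyclic shift of ring b (n x 2 or n x 3) minimising total squared distance
# to ring a; ties broken by the lowest shift index.
align_ring <- function(a, b) {
  n <- nrow(a)
  cost <- vapply(0:(n - 1), function(k) {
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    sum((a[, 1] - b[idx, 1])^2 + (a[, 2] - b[idx, 2])^2)
  }, 0)
  k <- which.min(cost) - 1
  idx <- ((seq_len(n) - 1 + k) %% n) + 1
  b[idx, , drop = FALSE]
}

# Wall band between ring A (lower) and ring B (upper), both n x 3, aligned,
# CCW seen from +z. Returns faces with outward normals given global offsets.
band_faces <- function(offset_a, offset_b, n, flip = FALSE) {
  i <- seq_len(n); j <- c(seq_len(n)[-1], 1)
  f <- rbind(cbind(offset_a + i, offset_a + j, offset_b + j),
             cbind(offset_a + i, offset_b + j, offset_b + i))
  if (flip) f[, c(1, 3, 2)] else f
}

#' Loft a solid through a stack of planar sketches
#'
#' Skins a ruled surface between consecutive rings (correspondence by
#' uniform arc length with the twist-minimising cyclic shift) and closes the
#' stack with planar caps: a watertight genus-0 solid.
#'
#' @param sketches list of >= 2 `plane_sketch` objects (strictly increasing
#'   z, equal vertex counts, CCW).
#' @return a `surface_mesh` (`closed_solid`) carrying the aligned rings as
#'   attribute `rings`.
#' @export
loft_solid <- function(sketches) {
  zs <- vapply(sketches, `[[`, 0, "z")
  if (is.unsorted(zs, strictly = TRUE))
    stop_with("geometry_error", "sketch planes must have strictly increasing z")
  rings <- lapply(sketches, function(s) ensure_ccw(as.matrix(s$contour)))
  n <- nrow(rings[[1]])
  if (!all(vapply(rings, nrow, 0L) == n))
    stop_with("geometry_error", "sketches must share a vertex count")
  for (k in seq_along(rings)[-1]) rings[[k]] <- align_ring(rings[[k - 1]], rings[[k]])
  m <- length(rings)
  verts <- do.call(rbind, lapply(seq_len(m),
                                 function(k) cbind(rings[[k]], zs[k])))
  walls <- do.call(rbind, lapply(seq_len(m - 1), function(k)
    band_faces((k - 1) * n, k * n, n)))
  tri_b <- ear_clip(rings[[1]])[, c(1, 3, 2), drop = FALSE]   # -z cap
  tri_t <- ear_clip(rings[[m]]) + (m - 1) * n                 # +z cap
  mesh <- surface_mesh(verts, rbind(walls, tri_b, tri_t),
                       kind = "closed_solid")
  attr(mesh, "rings") <- rings
  attr(mesh, "ring_z") <- zs
  mesh
}

#' Open the through-hole: assemble the ring adapter
#'
#' Subtracts the straight extrusion of the hole contour from the lofted
#' body. Implemented as a direct assembly of the outer loft wall, the inner
#' prism wall and two annular caps; valid because the hole lies strictly
#' inside every cross-section. The result is a watertight ring with Euler
#' characteristic 0 and volume volume(loft) - area(hole) * h.
#'
#' @param loft the `surface_mesh` returned by [loft_solid()].
#' @param hole_contour the hole contour (n x 2 mm) strictly inside all loft
#'   cross-sections.
#' @param h device height, mm (must equal the loft's top plane).
#' @param spec optional `adapter_spec` recorded for reporting.
#' @param source description of the contour's provenance.
#' @return object of class `adapter_solid`: fields `mesh`, `spec`, `hole`,
#'   `rings`, `ring_z`, `source`.
#' @export
subtract_hole <- function(loft, hole_contour, h, spec = NULL, source = "") {
  rings <- attr(loft, "rings")
  zs <- attr(loft, "ring_z")
  if (is.null(rings))
    stop_with("geometry_error", "loft must come from loft_solid()")
  if (abs(zs[length(zs)] - zs[1] - h) > 1e-9)
    stop_with("geometry_error", "h must match the loft height")
  hole <- ensure_ccw(as.matrix(hole_contour))
  n <- nrow(rings[[1]])
  if (nrow(hole) != n) hole <- resample_contour(hole, n)
  for (k in seq_along(rings)) {
    if (!all(points_in_polygon(hole, rings[[k]], strict = TRUE)))
      stop_with("design_infeasible", sprintf(
        "hole contour is not strictly inside the cross-section at z=%.1f mm", zs[k]))
  }
  hole <- align_ring(rings[[1]], hole)
  m <- length(rings)
  verts <- rbind(
    do.call(rbind, lapply(seq_len(m), function(k) cbind(rings[[k]], zs[k]))),
    cbind(hole, zs[1]), cbind(hole, zs[m]))
  outer_walls <- do.call(rbind, lapply(seq_len(m - 1), function(k)
    band_faces((k - 1) * n, k * n, n)))
  inner_wall <- band_faces(m * n, (m + 1) * n, n, flip = TRUE)
  cap_bottom <- band_faces(0, m * n, n, flip = TRUE)      # outer ring 0 -> hole bottom
  cap_top <- band_faces((m - 1) * n, (m + 1) * n, n)      # outer ring top -> hole top
  mesh <- surface_mesh(verts, rbind(outer_walls, inner_wall,
                                    cap_bottom, cap_top),
                       kind = "closed_solid")
  structure(list(mesh = mesh, spec = spec, hole = hole, rings = rings,
                 ring_z = zs, source = source),
            class = "adapter_solid")
}

#' @export
print.adapter_solid <- function(x, ...) {
  st <- mesh_stats(x$mesh)
  cat(sprintf(
    "adapter_solid: volume %.1f mm^3, hole area %.1f mm^2, chi=%d, %s\n",
    mesh_volume(x$mesh), polygon_area(x$hole), st$euler_characteristic,
    if (is_watertight(x$mesh)) "watertight" else "NOT watertight"))
  invisible(x)
}

#' Design an adapter from a fistula contour
#'
#' Convenience wrapper: sketches, loft, hole subtraction.
#'
#' @param contour the fistula contour (n x 2, mm).
#' @param spec an `adapter_spec`.
#' @param n_samples sketch vertex count.
#' @param source provenance note.
#' @return an `adapter_solid`.
#' @export
design_adapter <- function(contour, spec = adapter_spec(),
                           n_samples = 256, source = "") {
  bs <- build_sketches(contour, spec, n_samples)
  loft <- loft_solid(bs$sketches)
  subtract_hole(loft, bs$hole, spec$height, spec = spec, source = source)
}

format_range_cm <- function(lo, hi) {
  f <- function(v) sub("\\.0$", "", sprintf("%.1f", v))
  lo <- round_half_up(lo, 1); hi <- round_half_up(hi, 1)
  if (lo == hi) f(lo) else paste0(f(lo), "–", f(hi))
}

#' Dimension and ledge report for an adapter
#'
#' The ledge (protrusion) is the radial width between the hole contour and
#' the outer contour, reported as a min-max range in cm at the top and
#' bottom planes; height/width/length are the bounding-box dimensions in the
#' design frame with length >= width.
#'
#' @param adapter an `adapter_solid`.
#' @return object of class `ledge_report` with numeric fields (cm) and
#'   preformatted `top_ledge` / `bottom_ledge` range strings.
#' @export
ledge_report <- function(adapter) {
  hole <- adapter$hole
  rings <- adapter$rings
  bottom <- rings[[1]]; top <- rings[[length(rings)]]
  bl <- dist_to_polygon(hole, bottom)
  tl <- dist_to_polygon(hole, top)
  allxy <- do.call(rbind, rings)
  ext <- c(diff(range(allxy[, 1])), diff(range(allxy[, 2])))
  structure(list(
    height = mm_to_cm(adapter$ring_z[length(adapter$ring_z)] - adapter$ring_z[1]),
    length = mm_to_cm(max(ext)), width = mm_to_cm(min(ext)),
    top_ledge_min = mm_to_cm(min(tl)), top_ledge_max = mm_to_cm(max(tl)),
    bottom_ledge_min = mm_to_cm(min(bl)), bottom_ledge_max = mm_to_cm(max(bl)),
    top_ledge = format_range_cm(mm_to_cm(min(tl)), mm_to_cm(max(tl))),
    bottom_ledge = format_range_cm(mm_to_cm(min(bl)), mm_to_cm(max(bl)))),
    class = "ledge_report")
}

#' @export
print.ledge_report <- function(x, ...) {
  cat(sprintf(
    "device: height %.1f cm, width %.1f cm, length %.1f cm; top ledge %s cm, bottom ledge %s cm\n",
    x$height, x$width, x$length, x$top_ledge, x$bottom_ledge))
  invisible(x)
}

#' Check the adapter's fit against the wound scan
#'
#' Places the adapter (hole axis along the frame z-axis, bottom plane at
#' frame z = 0 plus `offset`) over the wound mesh and reports the maximum
#' penetration of bottom-face sample points below the wound surface, whether
#' all fistula boundary points project inside the hole, and (when a rim is
#' supplied) the minimum lateral clearance between the brim and the wound
#' rim.
#'
#' @param adapter an `adapter_solid`.
#' @param wound a `surface_mesh` of the wound patch (world coordinates).
#' @param frame the `design_frame` posing the adapter on the wound.
#' @param offset 3-vector, mm: additional pose translation in frame
#'   coordinates.
#' @param fistula_contour contour (n x 2, frame coordinates) that must pass
#'   through the hole; defaults to the adapter's own hole contour
#'   (self-consistency check).
#' @param rim optional wound rim polyline (n x 3, world coordinates).
#' @return object of class `fit_report` with `max_penetration` (mm, >= 0),
#'   `min_clearance_to_rim` (mm or NA) and `hole_contains_fistula`.
#' @export
fit_check <- function(adapter, wound, frame, offset = c(0, 0, 0),
                      fistula_contour = NULL, rim = NULL) {
  if (!inherits(frame, "design_frame"))
    stop_with("pose_error", "frame must be a design_frame")
  wq <- to_frame(wound$vertices, frame)
  bottom <- adapter$rings[[1]]
  hole <- adapter$hole
  # sample the annular bottom face at three radial stations
  samp <- rbind(bottom, hole, (bottom + hole) / 2)
  samp <- sweep(samp, 2, offset[1:2], `+`)
  z_dev <- adapter$ring_z[1] + offset[3]
  z_surf <- surface_height_at(wq, samp)
  pen <- max(0, max(z_surf - z_dev, na.rm = TRUE))

  fc <- if (is.null(fistula_contour)) adapter$hole else
    ensure_ccw(as.matrix(fistula_contour))
  hole_posed <- sweep(hole, 2, offset[1:2], `+`)
  # points on the hole boundary itself count as contained (0.05 mm slack
  # against resampling round-off)
  inside <- points_in_polygon(fc, hole_posed)
  contains <- all(inside | dist_to_polygon(fc, hole_posed) < 0.05)

  clearance <- NA_real_
  if (!is.null(rim)) {
    rim2 <- to_frame(as.matrix(rim), frame)[, 1:2, drop = FALSE]
    brim <- sweep(adapter$rings[[length(adapter$rings)]], 2, offset[1:2], `+`)
    clearance <- min(dist_to_polygon(brim, rim2))
  }
  structure(list(max_penetration = pen, min_clearance_to_rim = clearance,
                 hole_contains_fistula = contains),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "fit: max penetration %.2f mm, hole contains fistula: %s, rim clearance %s\n",
    x$max_penetration, x$hole_contains_fistula,
    if (is.na(x$min_clearance_to_rim)) "n/a" else
      sprintf("%.1f mm", x$min_clearance_to_rim)))
  invisible(x)
}

# Local surface height (frame z) of a height-field mesh at xy query points:
# mean z of mesh vertices in the query's neighbourhood (hash-grid lookup).
# NA where no vertices are nearby.
surface_height_at <- function(vq, xy, radius = NULL) {
  if (is.null(radius)) {
    # heuristic cell size from point density
    area <- diff(range(vq[, 1])) * diff(range(vq[, 2]))
    radius <- max(1, 2 * sqrt(area / nrow(vq)))
  }
  gx <- floor(vq[, 1] / radius); gy <- floor(vq[, 2] / radius)
  key <- paste(gx, gy)
  buckets <- split(vq[, 3], key)
  out <- rep(NA_real_, nrow(xy))
  qx <- floor(xy[, 1] / radius); qy <- floor(xy[, 2] / radius)
  for (i in seq_len(nrow(xy))) {
    ks <- paste(rep(qx[i] + (-1:1), 3), rep(qy[i] + (-1:1), each = 3))
    zs <- unlist(buckets[ks], use.names = FALSE)
    if (length(zs)) out[i] <- mean(zs)
  }
  out
}
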