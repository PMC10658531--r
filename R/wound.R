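# Fistula-region selection on the wound mesh, design-frame fitting, contour
# extraction/extrusion and wound morphometry.

#' Read a lasso polyline from a text file
#'
#' Plain-text ordered `x y z` rows (mm), `#` comments allowed; the polyline
#' is treated as closed.
#'
#' @param path input file.
#' @return n x 3 matrix.
#' @export
read_lasso <- function(path) {
  m <- read_xyz_points(path)
  if (nrow(m) < 3) stop_with("selection_error", "lasso needs >= 3 vertices")
  m
}

#' Select the fistula region on a wound mesh
#'
#' Keeps the faces whose centroids fall inside the lasso after projection
#' onto the lasso's best-fit plane. If the selection splits into several
#' edge-connected components the largest is kept with a warning.
#'
#' @param mesh a `surface_mesh`.
#' @param lasso n x 3 matrix, ordered closed polyline around the stoma.
#' @return object of class `fistula_region`: the parent mesh, the face index
#'   set and the ordered boundary vertex loop.
#' @export
select_fistula_region <- function(mesh, lasso) {
  lasso <- as.matrix(lasso)
  if (nrow(lasso) < 3) stop_with("selection_error", "lasso needs >= 3 vertices")
  pl <- fit_plane(lasso)
  fr <- design_frame(pl$centroid, pl$normal)
  l2 <- to_frame(lasso, fr)[, 1:2, drop = FALSE]
  if (!polygon_is_simple(l2))
    stop_with("selection_error", "lasso projects to a self-intersecting curve")
  ctr <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  c2 <- to_frame(ctr, fr)[, 1:2, drop = FALSE]
  inside <- which(points_in_polygon(c2, ensure_ccw(l2)))
  if (length(inside) == 0)
    stop_with("selection_error", "lasso selects no faces")
  comp <- face_components(mesh$faces, inside)
  sizes <- tabulate(comp)
  if (sum(sizes > 0) > 1) {
    warning("selection has ", sum(sizes > 0),
            " connected components; keeping the largest")
    inside <- inside[comp == which.max(sizes)]
  }
  boundary <- region_boundary_loop(mesh$faces, inside)
  structure(list(mesh = mesh, faces = inside, boundary = boundary),
            class = "fistula_region")
}

#' @export
print.fistula_region <- function(x, ...) {
  cat("fistula_region:", length(x$faces), "faces, boundary loop of",
      length(x$boundary), "vertices\n")
  invisible(x)
}

# Connected components of a face subset under shared-edge adjacency
# (union-find with path halving).
face_components <- function(faces, subset) {
  f <- faces[subset, , drop = FALSE]
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_along(subset), 3)
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  same <- which(key[-1] == key[-length(key)])
  pairs <- cbind(fid[same], fid[same + 1])

  parent <- seq_along(subset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(subset), find, 0L)
  match(roots, unique(roots))
}

# Ordered boundary vertex loop of a face subset: directed edges whose
# reverse is absent within the subset, chained head-to-tail. Returns the
# longest loop (vertex indices, no repeated endpoint).
region_boundary_loop <- function(faces, subset) {
  f <- faces[subset, , drop = FALSE]
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  rev_ <- paste(e[, 2], e[, 1])
  bnd <- e[!(fwd %in% rev_), , drop = FALSE]
  if (nrow(bnd) == 0)
    stop_with("geometry_error", "region has no boundary (closed surface?)")
  nxt <- bnd[, 2]
  names(nxt) <- as.character(bnd[, 1])
  visited <- rep(FALSE, nrow(bnd))
  names(visited) <- as.character(bnd[, 1])
  best <- integer(0)
  starts <- as.character(bnd[, 1])
  for (s in starts) {
    if (visited[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      if (is.na(nxt[cur])) break
      if (isTRUE(visited[cur])) break
      visited[cur] <- TRUE
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[cur])
      if (cur == s) break
    }
    if (length(loop) > length(best)) best <- loop
  }
  if (length(best) < 3)
    stop_with("geometry_error", "could not trace a boundary loop")
  best
}

#' Fit the design frame of a fistula region
#'
#' Least-squares plane through the region's boundary loop; the z-axis is the
#' plane normal oriented to match the region's average face normal (outward
#' from the wound bed) and the origin is the boundary centroid.
#'
#' @param region a `fistula_region`.
#' @return a `design_frame`.
#' @export
fit_design_frame <- function(region) {
  bpts <- region$mesh$vertices[region$boundary, , drop = FALSE]
  if (nrow(bpts) < 3)
    stop_with("degenerate_geometry", "boundary has < 3 vertices")
  pl <- fit_plane(bpts)
  if (pl$singular_values[2] < 1e-9 * pl$singular_values[1])
    stop_with("degenerate_geometry", "boundary vertices are collinear")
  sub <- region$mesh
  sub$faces <- sub$faces[region$faces, , drop = FALSE]
  avg_n <- colMeans(face_normals(sub))
  z <- if (sum(pl$normal * avg_n) < 0) -pl$normal else pl$normal
  design_frame(pl$centroid, z, x_hint = pl$axes[, 1])
}

#' Extract the planar fistula contour
#'
#' Projects the region boundary onto the design frame's xy-plane, optionally
#' smooths the grid-quantised loop, and resamples it to uniform arc length,
#' counter-clockwise.
#'
#' @param region a `fistula_region`.
#' @param frame its `design_frame` (default: fitted from the region).
#' @param n_samples output vertex count.
#' @param smooth odd moving-average window applied before resampling to
#'   soften grid staircase artefacts (1 = none).
#' @return a `fistula_contour` (n_samples x 2, mm).
#' @export
extract_contour <- function(region, frame = fit_design_frame(region),
                            n_samples = 256, smooth = 5) {
  p2 <- to_frame(region$mesh$vertices[region$boundary, , drop = FALSE],
                 frame)[, 1:2, drop = FALSE]
  if (smooth > 1) p2 <- smooth_contour(p2, smooth)
  if (!polygon_is_simple(p2, tol = 0.01)) {
    ps <- polyclip::polysimplify(list(x = p2[, 1], y = p2[, 2]),
                                 filltype = "evenodd")
    areas <- vapply(ps, function(r) abs(polygon_area(cbind(r$x, r$y))), 0)
    if (length(ps) == 0 || max(areas) < 0.95 * abs(polygon_area(p2)))
      stop_with("geometry_error",
                "projected boundary self-intersects badly; re-select the region")
    p2 <- cbind(ps[[which.max(areas)]]$x, ps[[which.max(areas)]]$y)
  }
  fistula_contour(resample_contour(ensure_ccw(p2), n_samples))
}

#' Extrude a fistula contour into a closed prism
#'
#' The straight vertical extrusion of the intestinal-surface outline, the
#' solid subtracted from the lofted body to open the device's through-hole.
#'
#' @param contour a `fistula_contour` (n x 2, mm).
#' @param z_min,z_max extrusion interval in frame z (mm), `z_max > z_min`.
#' @return a watertight `surface_mesh` of kind `closed_solid` with volume
#'   area(contour) * (z_max - z_min).
#' @export
extrude_fistula <- function(contour, z_min, z_max) {
  if (z_max <= z_min)
    stop_with("geometry_error", "z_max must exceed z_min")
  p <- ensure_ccw(as.matrix(contour))
  if (!polygon_is_simple(p))
    stop_with("geometry_error", "cannot extrude a self-intersecting contour")
  n <- nrow(p)
  verts <- rbind(cbind(p, z_min), cbind(p, z_max))
  tri <- ear_clip(p)
  bottom <- tri[, c(1, 3, 2), drop = FALSE]          # normal -z
  top <- tri + n                                     # normal +z
  i <- seq_len(n); j <- c(seq_len(n)[-1], 1)
  side <- rbind(cbind(i, j, j + n), cbind(i, j + n, i + n))
  surface_mesh(verts, rbind(bottom, top, side), kind = "closed_solid")
}

#' Measure wound and fistula dimensions
#'
#' Length and width are the extents of the wound rim loop along its two
#' principal axes (length >= width unless `swap_axes`); depth is the
#' distance from the rim's best-fit plane down to the robust wound-bed level
#' (the `bed_quantile` quantile of rim-plane heights of mesh vertices inside
#' the rim); each fistula orifice height is its stoma plateau level (95th
#' percentile of region vertex heights) minus the bed level. All reported in
#' cm.
#'
#' @param mesh a `surface_mesh` of the wound patch.
#' @param wound_lasso n x 3 matrix, ordered closed polyline along the wound
#'   rim.
#' @param fistula_regions list of `fistula_region` objects (may be empty).
#' @param swap_axes report the second principal extent as length (for
#'   anatomical longitudinal/transverse assignment the frame cannot know).
#' @param bed_quantile quantile of in-wound heights defining the bed level
#'   (default 0.05: the deepest region, robust to scanner noise).
#' @return object of class `wound_measurements` with fields `length`,
#'   `width`, `depth`, `fistula_orifice_heights` (cm) and `n_orifices`.
#' @export
measure_wound <- function(mesh, wound_lasso, fistula_regions = list(),
                          swap_axes = FALSE, bed_quantile = 0.05) {
  wound_lasso <- as.matrix(wound_lasso)
  if (nrow(wound_lasso) < 3)
    stop_with("selection_error", "wound lasso needs >= 3 vertices")
  pl <- fit_plane(wound_lasso)
  avg_n <- colMeans(face_normals(mesh))
  z <- if (sum(pl$normal * avg_n) < 0) -pl$normal else pl$normal
  fr <- design_frame(pl$centroid, z, x_hint = pl$axes[, 1])
  rim2 <- to_frame(wound_lasso, fr)[, 1:2, drop = FALSE]
  if (!polygon_is_simple(rim2, tol = 0.01))
    stop_with("selection_error", "wound lasso is not a simple closed curve")

  # principal extents of the rim loop
  pc <- prcomp(rim2)
  ext <- apply(pc$x, 2, function(v) diff(range(v)))
  len <- max(ext); wid <- min(ext)
  if (swap_axes) { tmp <- len; len <- wid; wid <- tmp }

  vq <- to_frame(mesh$vertices, fr)
  inside <- points_in_polygon(vq[, 1:2, drop = FALSE], ensure_ccw(rim2))
  if (!any(inside))
    stop_with("selection_error", "no mesh vertices inside the wound lasso")
  bed <- stats::quantile(vq[inside, 3], bed_quantile, names = FALSE)
  depth <- max(0, -bed)

  heights <- vapply(fistula_regions, function(rg) {
    vids <- unique(as.vector(rg$mesh$faces[rg$faces, ]))
    zr <- to_frame(rg$mesh$vertices[vids, , drop = FALSE], fr)[, 3]
    stats::quantile(zr, 0.95, names = FALSE) - bed
  }, 0)

  structure(list(length = mm_to_cm(len), width = mm_to_cm(wid),
                 depth = mm_to_cm(depth),
                 fistula_orifice_heights = mm_to_cm(heights),
                 n_orifices = length(heights),
                 frame = fr, bed_level_mm = bed),
            class = "wound_measurements")
}

#' @export
print.wound_measurements <- function(x, ...) {
  cat(sprintf("wound: length %.1f cm, width %.1f cm, depth %.1f cm\n",
              x$length, x$width, x$depth))
  if (x$n_orifices > 0)
    cat("fistula orifice heights (cm):",
        paste(sprintf("%.1f", x$fistula_orifice_heights), collapse = ", "), "\n")
  invisible(x)
}
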