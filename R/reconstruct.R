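# 2.5-D surface reconstruction: project the cloud onto its best-fit plane,
# bin onto a regular grid, average heights per cell and triangulate the grid
# nodes. Suited to height-field-like wound patches; volumetric reconstruction
# is out of scope (real meshes may be supplied directly as STL).

#' Reconstruct a triangle mesh from a wound point cloud
#'
#' @param cloud a `point_cloud`, approximately a height field over its
#'   best-fit plane.
#' @param grid_pitch grid cell size in mm (> 0). Vertices are placed at cell
#'   centres with height equal to the mean height of the cell's points.
#' @param up orientation hint: the reconstructed normals are made to point
#'   to the side of the best-fit plane with positive dot product against
#'   `up` (default +z, the outward direction for a supine abdominal scan).
#' @param fill_holes fill interior cells that received no points by
#'   iterative neighbour averaging (default TRUE).
#' @param min_occupancy minimum fraction of occupied cells in the bounding
#'   rectangle before the cloud is declared too sparse for the pitch.
#' @return a `surface_mesh` of kind `open_patch`, consistently oriented with
#'   normals along `up`; carries the projection frame as attribute `frame`.
#' @export
reconstruct_surface <- function(cloud, grid_pitch, up = c(0, 0, 1),
                                fill_holes = TRUE, min_occupancy = 0.5) {
  if (grid_pitch <= 0) stop_with("geometry_error", "grid_pitch must be > 0")
  pts <- cloud$points
  if (nrow(pts) < 3)
    stop_with("reconstruction_error", "need at least 3 points")
  pl <- fit_plane(pts)
  zax <- pl$normal
  if (sum(zax * up) < 0) zax <- -zax
  frame <- design_frame(pl$centroid, zax)
  q <- to_frame(pts, frame)

  ix <- floor((q[, 1] - min(q[, 1])) / grid_pitch)
  iy <- floor((q[, 2] - min(q[, 2])) / grid_pitch)
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  cell <- ix + nx * iy + 1
  zsum <- rowsum(q[, 3], cell)
  cnt <- rowsum(rep(1, length(cell)), cell)
  zgrid <- matrix(NA_real_, nx, ny)
  zgrid[as.integer(rownames(zsum))] <- zsum / cnt

  occ <- mean(!is.na(zgrid))
  if (occ < min_occupancy)
    stop_with("reconstruction_error", sprintf(
      "cloud too sparse for pitch %.3g mm (%.0f%% of grid cells empty); try a larger pitch",
      grid_pitch, 100 * (1 - occ)))

  if (fill_holes && anyNA(zgrid)) zgrid <- fill_grid_holes(zgrid)

  # vertices at occupied cell centres
  has <- which(!is.na(zgrid), arr.ind = TRUE)
  vid <- matrix(0L, nx, ny)
  vid[has] <- seq_len(nrow(has))
  vx <- min(q[, 1]) + (has[, 1] - 0.5) * grid_pitch
  vy <- min(q[, 2]) + (has[, 2] - 0.5) * grid_pitch
  vz <- zgrid[has]
  verts_frame <- cbind(vx, vy, vz)

  # two CCW triangles per fully occupied 2x2 block
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- vid[cbind(i, j)]; b <- vid[cbind(i + 1, j)]
  c3 <- vid[cbind(i + 1, j + 1)]; d <- vid[cbind(i, j + 1)]
  full <- a > 0 & b > 0 & c3 > 0 & d > 0
  faces <- rbind(cbind(a[full], b[full], c3[full]),
                 cbind(a[full], c3[full], d[full]))

  mesh <- surface_mesh(from_frame(verts_frame, frame), faces,
                       kind = "open_patch", validate = FALSE)
  attr(mesh, "frame") <- frame
  attr(mesh, "grid_pitch") <- grid_pitch
  mesh
}

# Iteratively replace interior NAs by the mean of available 4-neighbours.
# "Interior" means having occupied cells in all four axis directions in the
# original occupancy: true dropout holes qualify, while the empty corner
# wedges left by a cloud rotated against the grid axes do not (filling must
# not grow the patch past its footprint).
fill_grid_holes <- function(z, max_iter = 50) {
  nx <- nrow(z); ny <- ncol(z)
  occ <- !is.na(z)
  cm <- function(m) matrix(as.logical(apply(m, 2, cummax)), nrow(m))
  interior <- cm(occ) & cm(occ[nx:1, , drop = FALSE])[nx:1, , drop = FALSE] &
    t(cm(t(occ))) & t(cm(t(occ[, ny:1, drop = FALSE])))[, ny:1, drop = FALSE]
  for (it in seq_len(max_iter)) {
    nas <- is.na(z)
    if (!any(nas & interior)) break
    zp <- rbind(NA, z[-nx, , drop = FALSE]); zn <- rbind(z[-1, , drop = FALSE], NA)
    zl <- cbind(NA, z[, -ny, drop = FALSE]); zr <- cbind(z[, -1, drop = FALSE], NA)
    zero <- function(m) { m[is.na(m)] <- 0; m }
    cnt <- (!is.na(zp)) + (!is.na(zn)) + (!is.na(zl)) + (!is.na(zr))
    avg <- (zero(zp) + zero(zn) + zero(zl) + zero(zr)) / pmax(cnt, 1)
    fill <- nas & interior & cnt >= 2
    if (!any(fill)) break
    z[fill] <- avg[fill]
  }
  z
}
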