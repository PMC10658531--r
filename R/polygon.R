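# Planar polygon primitives used by the contour and sketch machinery.
# Contours are n x 2 matrices of mm coordinates, counter-clockwise, with no
# repeated closing vertex.

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise polygons.
#'
#' @param p n x 2 matrix, closed polygon without repeated last vertex.
#' @return signed area in mm^2.
#' @export
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon perimeter
#' @param p n x 2 matrix.
#' @return perimeter in mm.
#' @export
polygon_perimeter <- function(p) {
  d <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

ensure_ccw <- function(p) {
  if (polygon_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# TRUE where query points fall strictly inside polygon p (boundary counts as
# inside only when strict = FALSE).
points_in_polygon <- function(q, p, strict = FALSE) {
  r <- sp::point.in.polygon(q[, 1], q[, 2], p[, 1], p[, 2])
  if (strict) r == 1 else r >= 1
}

# Minimum distance from each query point to the polygon boundary (polyline
# segments), vectorised over segments.
dist_to_polygon <- function(q, p) {
  a <- p
  b <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-300
  out <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    ap1 <- q[i, 1] - a[, 1]; ap2 <- q[i, 2] - a[, 2]
    t <- pmin(1, pmax(0, (ap1 * ab[, 1] + ap2 * ab[, 2]) / len2))
    dx <- ap1 - t * ab[, 1]; dy <- ap2 - t * ab[, 2]
    out[i] <- sqrt(min(dx * dx + dy * dy))
  }
  out
}

# Simplicity check via Clipper: a simple polygon survives polysimplify as a
# single ring with (near) unchanged area.
polygon_is_simple <- function(p, tol = 1e-6) {
  ps <- polyclip::polysimplify(list(x = p[, 1], y = p[, 2]),
                               filltype = "evenodd")
  if (length(ps) != 1) return(FALSE)
  a0 <- abs(polygon_area(p))
  a1 <- abs(polygon_area(cbind(ps[[1]]$x, ps[[1]]$y)))
  abs(a1 - a0) <= tol * max(a0, 1e-12)
}

#' Resample a closed contour at uniform arc length
#'
#' @param p n x 2 matrix (closed, no repeated last vertex).
#' @param n number of output vertices.
#' @return n x 2 matrix starting at the original first vertex.
#' @export
resample_contour <- function(p, n = 256) {
  q <- rbind(p, p[1, ])
  seg <- sqrt(rowSums((q[-1, , drop = FALSE] - q[-nrow(q), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop_with("degenerate_geometry", "contour has zero length")
  t_out <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(stats::approx(s, q[, 1], xout = t_out, ties = "ordered")$y,
        stats::approx(s, q[, 2], xout = t_out, ties = "ordered")$y)
}

# Circular moving-average smoothing of a closed contour (window must be odd).
smooth_contour <- function(p, window = 5) {
  if (window <= 1) return(p)
  n <- nrow(p)
  k <- (window - 1) / 2
  idx <- outer(seq_len(n), -k:k, function(i, j) ((i + j - 1) %% n) + 1)
  cbind(rowMeans(matrix(p[idx, 1], n)), rowMeans(matrix(p[idx, 2], n)))
}

#' Validate and normalise a fistula contour
#'
#' A fistula contour is the closed planar outline of the exposed intestinal
#' surface in the design frame's xy-plane. It must be simple with positive
#' area; orientation is normalised to counter-clockwise.
#'
#' @param p n x 2 matrix of mm coordinates.
#' @return the validated contour (CCW n x 2 matrix) of class
#'   `fistula_contour`.
#' @export
fistula_contour <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3)
    stop_with("degenerate_geometry", "contour needs >= 3 planar vertices")
  if (!all(is.finite(p)))
    stop_with("degenerate_geometry", "contour has non-finite coordinates")
  if (!polygon_is_simple(p))
    stop_with("geometry_error", "contour is self-intersecting")
  p <- ensure_ccw(p)
  if (polygon_area(p) <= 0)
    stop_with("degenerate_geometry", "contour has zero area")
  class(p) <- c("fistula_contour", class(matrix()))
  p
}

#' Outward polygon offset with round joins
#'
#' Dilates a simple closed contour by `d` mm (Minkowski sum with a disk of
#' radius `d`), the operation used to derive the device sketches from the
#' fistula outline. `d = 0` returns the input unchanged. If cleanup of
#' self-intersections yields several rings the largest-area ring is kept.
#'
#' @param contour n x 2 matrix, simple closed polygon (mm).
#' @param d offset distance, mm, >= 0.
#' @param n_samples vertex count of the resampled result.
#' @return offset contour, `n_samples` x 2, counter-clockwise.
#' @export
offset_contour <- function(contour, d, n_samples = nrow(contour)) {
  contour <- as.matrix(contour)
  if (d < 0) stop_with("geometry_error", "offset distance must be >= 0")
  if (!polygon_is_simple(contour))
    stop_with("geometry_error", "cannot offset a self-intersecting contour")
  contour <- ensure_ccw(contour)
  if (d == 0) return(fistula_contour(resample_contour(contour, n_samples)))
  res <- polyclip::polyoffset(list(x = contour[, 1], y = contour[, 2]),
                              delta = d, jointype = "round",
                              arctol = min(0.005 * d, 0.02))
  if (length(res) == 0)
    stop_with("geometry_error", "offset annihilated the contour")
  areas <- vapply(res, function(r) abs(polygon_area(cbind(r$x, r$y))), 0)
  best <- res[[which.max(areas)]]
  out <- ensure_ccw(cbind(best$x, best$y))
  fistula_contour(resample_contour(out, n_samples))
}

# Ear-clipping triangulation of a simple CCW polygon. Returns an (n-2) x 3
# matrix of vertex indices with CCW winding.
ear_clip <- function(p) {
  p <- ensure_ccw(as.matrix(p))
  n <- nrow(p)
  if (n < 3) stop_with("degenerate_geometry", "cannot triangulate < 3 vertices")
  idx <- seq_len(n)
  tris <- matrix(0L, n - 2, 3)
  k <- 0L
  guard <- 0L
  while (length(idx) > 3) {
    m <- length(idx)
    clipped <- FALSE
    for (j in seq_len(m)) {
      i0 <- idx[(j - 2) %% m + 1]
      i1 <- idx[(j - 1) %% m + 1]
      i2 <- idx[j %% m + 1]
      a <- p[i0, ]; b <- p[i1, ]; cpt <- p[i2, ]
      cross <- (b[1] - a[1]) * (cpt[2] - a[2]) - (b[2] - a[2]) * (cpt[1] - a[1])
      if (cross <= 1e-12 * max(abs(p))) next  # reflex or degenerate
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others)) {
        q <- p[others, , drop = FALSE]
        # barycentric point-in-triangle, vectorised
        d1 <- (q[, 1] - a[1]) * (b[2] - a[2]) - (q[, 2] - a[2]) * (b[1] - a[1])
        d2 <- (q[, 1] - b[1]) * (cpt[2] - b[2]) - (q[, 2] - b[2]) * (cpt[1] - b[1])
        d3 <- (q[, 1] - cpt[1]) * (a[2] - cpt[2]) - (q[, 2] - cpt[2]) * (a[1] - cpt[1])
        inside <- (d1 <= 0 & d2 <= 0 & d3 <= 0)
        if (any(inside)) next
      }
      k <- k + 1L
      tris[k, ] <- c(i0, i1, i2)
      idx <- idx[idx != i1]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      # numerically stuck (collinear runs): clip the least-reflex corner
      guard <- guard + 1L
      if (guard > 2) stop_with("geometry_error", "ear clipping failed; polygon may be non-simple")
      m <- length(idx)
      j <- 1
      i0 <- idx[(j - 2) %% m + 1]; i1 <- idx[(j - 1) %% m + 1]; i2 <- idx[j %% m + 1]
      k <- k + 1L
      tris[k, ] <- c(i0, i1, i2)
      idx <- idx[idx != i1]
    }
  }
  k <- k + 1L
  tris[k, ] <- idx
  tris[seq_len(k), , drop = FALSE]
}
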