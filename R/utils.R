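# Internal helpers shared across modules. All geometry is in mm; clinical
# reports convert to cm at the last moment.

MM_PER_CM <- 10

mm_to_cm <- function(x) x / MM_PER_CM
cm_to_mm <- function(x) x * MM_PER_CM

#' Round half away from zero at a fixed number of decimals
#'
#' Reproduces the rounding used by mainstream clinical statistics packages
#' (half-up), as opposed to R's round-half-to-even. Used when comparing
#' computed aggregates against values printed at a fixed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Error constructors ---------------------------------------------------------

stop_with <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "eafadapt_error")))
}

# Orthonormal right-handed coordinate frame ----------------------------------

#' Construct a design frame
#'
#' A design frame is a right-handed orthonormal coordinate system: all device
#' sketches are drawn in its xy-plane and the z-axis points outward from the
#' wound bed.
#'
#' @param origin 3-vector, mm.
#' @param z_axis outward unit vector (normalised internally).
#' @param x_hint optional vector whose projection onto the plane defines the
#'   x-axis; defaults to an arbitrary perpendicular.
#' @return object of class `design_frame` with fields `origin` and `rotation`
#'   (3x3 matrix whose columns are the x, y, z axes).
#' @export
design_frame <- function(origin = c(0, 0, 0), z_axis = c(0, 0, 1),
                         x_hint = NULL) {
  z <- z_axis / sqrt(sum(z_axis^2))
  if (is.null(x_hint)) {
    x_hint <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  }
  x <- x_hint - sum(x_hint * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop_with("degenerate_geometry", "x_hint parallel to z-axis")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],  # z cross x
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  structure(list(origin = as.numeric(origin),
                 rotation = cbind(x = x, y = y, z = z)),
            class = "design_frame")
}

#' @export
print.design_frame <- function(x, ...) {
  cat("design_frame: origin (",
      paste(sprintf("%.2f", x$origin), collapse = ", "), ") mm, z-axis (",
      paste(sprintf("%.3f", x$rotation[, 3]), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Transform points into / out of a design frame
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param frame a `design_frame`.
#' @return n x 3 matrix in frame coordinates.
#' @export
to_frame <- function(points, frame) {
  sweep(points, 2, frame$origin) %*% frame$rotation
}

#' @rdname to_frame
#' @export
from_frame <- function(points, frame) {
  sweep(points %*% t(frame$rotation), 2, frame$origin, `+`)
}

# Least-squares plane through points: returns list(centroid, normal)
fit_plane <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3],
       axes = sv$v[, 1:2], singular_values = sv$d)
}

# Run code with a private RNG stream so package functions are deterministic
# given their seed argument without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
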