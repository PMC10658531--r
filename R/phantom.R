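# Synthetic abdominal-wound phantom: an analytic surface (flat skin, a
# cosine-tapered elliptical crater with a flat floor, smooth plateau-topped
# stoma bumps) sampled like a structured-light scan, with exact ground truth
# for every downstream measurement.

#' Specify a wound phantom
#'
#' @param patch c(Lx, Ly): scanned skin patch extents, mm.
#' @param wound_axes c(a, b): wound ellipse semi-axes, mm.
#' @param depth wound depth (skin plane to flat floor), mm, > 0.
#' @param stomas list of stomas, each `list(center = c(x, y), radius = r
#'   or c(rx, ry), height = h)` (mm); the plateau top sits `height` above
#'   the wound floor. Every stoma base must lie on the flat floor (inside
#'   `floor_fraction` of the wound ellipse) so its truth height is
#'   unambiguous.
#' @param sigma scanner noise sd along the surface normal, mm (white-light
#'   scanner resolution range 0.1-0.3; default 0.2).
#' @param dropout fraction of samples lost, in [0, 1).
#' @param n_points target sample count (default 500,000: above the QC gate,
#'   the order of the clinical final meshes).
#' @param floor_fraction elliptical radius fraction where the flat floor
#'   ends and the cosine taper to the rim begins.
#' @param seed RNG seed making the cloud reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(patch = c(160, 120), wound_axes = c(60, 40),
                         depth = 20,
                         stomas = list(list(center = c(5, 0), radius = 10,
                                            height = 15)),
                         sigma = 0.2, dropout = 0, n_points = 500000,
                         floor_fraction = 0.55, seed = 1) {
  if (depth <= 0) stop_with("phantom_spec_error", "depth must be > 0")
  if (sigma < 0) stop_with("phantom_spec_error", "sigma must be >= 0")
  if (dropout < 0 || dropout >= 1)
    stop_with("phantom_spec_error", "dropout must be in [0, 1)")
  a <- wound_axes[1]; b <- wound_axes[2]
  for (s in stomas) {
    r <- rep(s$radius, length.out = 2)
    rho_c <- sqrt((s$center[1] / a)^2 + (s$center[2] / b)^2)
    if (rho_c >= 1)
      stop_with("phantom_spec_error", "stoma centre outside the wound ellipse")
    if (rho_c + max(r) / min(a, b) > floor_fraction)
      stop_with("phantom_spec_error",
                "stoma base must lie on the flat wound floor")
  }
  structure(list(patch = patch, wound_axes = wound_axes, depth = depth,
                 stomas = stomas, sigma = sigma, dropout = dropout,
                 n_points = n_points, floor_fraction = floor_fraction,
                 seed = seed),
            class = "phantom_spec")
}

#' Built-in phantom presets
#'
#' `"patient-like"`: 160 x 120 mm patch, 120 x 80 mm wound, 20 mm deep, one
#' 10 mm stoma 15 mm high. `"small"`: a reduced patch for quick runs.
#'
#' @param preset preset name.
#' @param ... overrides passed to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
phantom_preset <- function(preset = c("patient-like", "small"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "patient-like" = list(),
    "small" = list(patch = c(90, 70), wound_axes = c(30, 22), depth = 12,
                   stomas = list(list(center = c(2, 0), radius = 6,
                                      height = 8)),
                   n_points = 150000))
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# Analytic phantom surface z(x, y) and its gradient, vectorised.
phantom_surface_fn <- function(spec) {
  a <- spec$wound_axes[1]; b <- spec$wound_axes[2]
  r0 <- spec$floor_fraction
  taper <- function(rho) {
    w <- numeric(length(rho))
    w[rho <= r0] <- 1
    mid <- rho > r0 & rho < 1
    w[mid] <- 0.5 * (1 + cos(pi * (rho[mid] - r0) / (1 - r0)))
    w
  }
  function(x, y) {
    rho <- sqrt((x / a)^2 + (y / b)^2)
    z <- -spec$depth * taper(rho)
    for (s in spec$stomas) {
      r <- rep(s$radius, length.out = 2)
      rr <- sqrt(((x - s$center[1]) / r[1])^2 + ((y - s$center[2]) / r[2])^2)
      z <- z + s$height * taper(rr)
    }
    z
  }
}

#' Generate a synthetic wound scan
#'
#' Samples the phantom surface uniformly over the patch, displaces each
#' sample along the local surface normal by Gaussian noise of sd `sigma`,
#' applies dropout, and draws the realised count from a Poisson law around
#' the target. Deterministic given the spec's seed.
#'
#' @param spec a `phantom_spec`.
#' @return list with `cloud` (a `point_cloud`) and `truth` (a
#'   `phantom_truth`: the analytic surface function, true dimensions in cm,
#'   stoma contours/heights and the stoma design frames).
#' @export
generate_phantom <- function(spec) {
  surf <- phantom_surface_fn(spec)
  cloud <- with_seed(spec$seed, {
    n_raw <- stats::rpois(1, spec$n_points / (1 - spec$dropout))
    x <- stats::runif(n_raw, -spec$patch[1] / 2, spec$patch[1] / 2)
    y <- stats::runif(n_raw, -spec$patch[2] / 2, spec$patch[2] / 2)
    z <- surf(x, y)
    if (spec$sigma > 0) {
      h <- 0.05
      gx <- (surf(x + h, y) - surf(x - h, y)) / (2 * h)
      gy <- (surf(x, y + h) - surf(x, y - h)) / (2 * h)
      inv <- 1 / sqrt(1 + gx^2 + gy^2)
      d <- stats::rnorm(n_raw, 0, spec$sigma)
      x <- x - d * gx * inv
      y <- y - d * gy * inv
      z <- z + d * inv
    }
    keep <- if (spec$dropout > 0)
      stats::runif(n_raw) >= spec$dropout else rep(TRUE, n_raw)
    point_cloud(cbind(x, y, z)[keep, , drop = FALSE],
                source_id = sprintf("phantom(seed=%d)", spec$seed))
  })
  truth <- structure(list(
    spec = spec, surface = surf,
    length = mm_to_cm(2 * spec$wound_axes[1]),
    width = mm_to_cm(2 * spec$wound_axes[2]),
    depth = mm_to_cm(spec$depth),
    stoma_heights = mm_to_cm(vapply(spec$stomas, `[[`, 0, "height")),
    bed_level = -spec$depth),
    class = "phantom_truth")
  list(cloud = cloud, truth = truth)
}

#' Analytic stoma base contour
#'
#' @param truth a `phantom_truth`.
#' @param stoma_index which stoma.
#' @param n_samples polygon vertex count.
#' @return a `fistula_contour` (mm, in the stoma's design frame centred on
#'   the stoma base at the wound-floor plane).
#' @export
truth_contour <- function(truth, stoma_index = 1, n_samples = 256) {
  st <- truth$spec$stomas
  if (stoma_index < 1 || stoma_index > length(st))
    stop_with("phantom_spec_error", "no such stoma")
  s <- st[[stoma_index]]
  r <- rep(s$radius, length.out = 2)
  th <- seq(0, 2 * pi, length.out = n_samples + 1)[seq_len(n_samples)]
  fistula_contour(cbind(r[1] * cos(th), r[2] * sin(th)))
}

#' Design frame of a phantom stoma
#'
#' Origin at the stoma centre on the wound-floor plane, z-axis outward.
#'
#' @param truth a `phantom_truth`.
#' @param stoma_index which stoma.
#' @return a `design_frame`.
#' @export
truth_frame <- function(truth, stoma_index = 1) {
  s <- truth$spec$stomas[[stoma_index]]
  design_frame(c(s$center, truth$bed_level), c(0, 0, 1), x_hint = c(1, 0, 0))
}

#' Analytic lateral surface area of a stoma bump
#'
#' Numerical integration of sqrt(1 + |grad z|^2) over the stoma base
#' region on a fine grid; serves as the ground truth for region-selection
#' area checks.
#'
#' @param truth a `phantom_truth`.
#' @param stoma_index which stoma.
#' @param margin radial margin beyond the base included in the region (use
#'   the lasso margin when validating a lasso selection), mm.
#' @param pitch integration grid pitch, mm.
#' @return area in mm^2.
#' @export
truth_stoma_area <- function(truth, stoma_index = 1, margin = 0,
                             pitch = 0.05) {
  s <- truth$spec$stomas[[stoma_index]]
  r <- rep(s$radius, length.out = 2) + margin
  surf <- truth$surface
  xs <- seq(s$center[1] - r[1], s$center[1] + r[1], by = pitch)
  ys <- seq(s$center[2] - r[2], s$center[2] + r[2], by = pitch)
  g <- expand.grid(x = xs, y = ys)
  inside <- ((g$x - s$center[1]) / r[1])^2 + ((g$y - s$center[2]) / r[2])^2 <= 1
  g <- g[inside, ]
  h <- pitch / 2
  gx <- (surf(g$x + h, g$y) - surf(g$x - h, g$y)) / pitch
  gy <- (surf(g$x, g$y + h) - surf(g$x, g$y - h)) / pitch
  sum(sqrt(1 + gx^2 + gy^2)) * pitch^2
}

#' Truth wound-rim polyline
#'
#' The wound ellipse sampled in 3D (world coordinates, on the skin plane),
#' usable as a wound lasso for [measure_wound()].
#'
#' @param truth a `phantom_truth`.
#' @param n_samples vertex count.
#' @return n x 3 matrix.
#' @export
truth_rim <- function(truth, n_samples = 128) {
  th <- seq(0, 2 * pi, length.out = n_samples + 1)[seq_len(n_samples)]
  cbind(truth$spec$wound_axes[1] * cos(th),
        truth$spec$wound_axes[2] * sin(th), 0)
}

#' Truth lasso around a stoma
#'
#' A 3D polyline slightly outside the stoma base on the wound floor, for
#' [select_fistula_region()].
#'
#' @param truth a `phantom_truth`.
#' @param stoma_index which stoma.
#' @param margin radial margin outside the base, mm.
#' @param n_samples vertex count.
#' @return n x 3 matrix (world coordinates).
#' @export
truth_stoma_lasso <- function(truth, stoma_index = 1, margin = 2,
                              n_samples = 128) {
  s <- truth$spec$stomas[[stoma_index]]
  r <- rep(s$radius, length.out = 2)
  th <- seq(0, 2 * pi, length.out = n_samples + 1)[seq_len(n_samples)]
  cbind(s$center[1] + (r[1] + margin) * cos(th),
        s$center[2] + (r[2] + margin) * sin(th),
        truth$bed_level)
}
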