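# Shared geometry fixtures and independent oracles, built in code.

circle_contour <- function(r, center = c(0, 0), n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_contour <- function(a, b, center = c(0, 0), n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

make_sketch <- function(contour, z) {
  structure(list(z = z, contour = contour), class = "plane_sketch")
}

square_contour <- function(side = 1, center = c(0, 0)) {
  s <- side / 2
  cbind(center[1] + c(-s, s, s, -s), center[2] + c(-s, -s, s, s))
}

# Independent volume oracle: z-ray casting on an xy column grid (pitch mm),
# exact z-integration between crossing pairs. Uses only the raw triangle
# soup, nothing from the solid's constructive representation.
voxel_volume <- function(mesh, pitch = 0.25) {
  v <- mesh$vertices
  f <- mesh$faces
  x0 <- min(v[, 1]) + 0.5 * pitch + pitch * 1e-3
  y0 <- min(v[, 2]) + 0.5 * pitch + pitch * 2e-3
  nx <- max(1, ceiling((max(v[, 1]) - x0) / pitch))
  ny <- max(1, ceiling((max(v[, 2]) - y0) / pitch))
  cols <- integer(0)
  zs <- numeric(0)
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
    det <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    if (abs(det) < 1e-9) next  # wall triangle, parallel to the ray
    i_lo <- max(0, floor((min(a[1], b[1], cc[1]) - x0) / pitch))
    i_hi <- min(nx, ceiling((max(a[1], b[1], cc[1]) - x0) / pitch))
    j_lo <- max(0, floor((min(a[2], b[2], cc[2]) - y0) / pitch))
    j_hi <- min(ny, ceiling((max(a[2], b[2], cc[2]) - y0) / pitch))
    if (i_hi < i_lo || j_hi < j_lo) next
    gx <- x0 + (i_lo:i_hi) * pitch
    gy <- y0 + (j_lo:j_hi) * pitch
    px <- rep(gx, length(gy)); py <- rep(gy, each = length(gx))
    w1 <- ((b[2] - cc[2]) * (px - cc[1]) + (cc[1] - b[1]) * (py - cc[2])) / det
    w2 <- ((cc[2] - a[2]) * (px - cc[1]) + (a[1] - cc[1]) * (py - cc[2])) / det
    w3 <- 1 - w1 - w2
    hit <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(hit)) next
    zhit <- w1[hit] * a[3] + w2[hit] * b[3] + w3[hit] * cc[3]
    colid <- (rep(i_lo:i_hi, length(gy)) + nx * rep(j_lo:j_hi, each = length(gx)))[hit]
    cols <- c(cols, colid)
    zs <- c(zs, zhit)
  }
  tot <- 0
  for (grp in split(zs, cols)) {
    z <- sort(grp)
    if (length(z) %% 2 != 0) next  # tangential artefact; skip column
    tot <- tot + sum(z[seq(2, length(z), by = 2)] - z[seq(1, length(z), by = 2)])
  }
  tot * pitch^2
}

# One standard phantom pipeline, computed once per test run.
standard_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(phantom_spec(n_points = 120000, seed = 7))
      mesh <- reconstruct_surface(ph$cloud, 1)
      reg <- select_fistula_region(mesh, truth_stoma_lasso(ph$truth))
      frame <- fit_design_frame(reg)
      cache <<- list(phantom = ph, mesh = mesh, region = reg, frame = frame)
    }
    cache
  }
})
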