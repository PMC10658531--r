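# Triangle mesh container and topological reports.

#' Construct a surface mesh
#'
#' An oriented triangle mesh in mm: either an `open_patch` (a reconstructed
#' wound surface with boundary) or a `closed_solid` (a watertight device
#' body). Degenerate (zero-area) faces are removed.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based, CCW seen
#'   from outside).
#' @param kind `"open_patch"` or `"closed_solid"`.
#' @param validate check watertightness and positive volume for closed
#'   solids.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, kind = c("open_patch", "closed_solid"),
                         validate = TRUE) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop_with("geometry_error", "vertices must be n x 3")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop_with("geometry_error", "face indices out of range")
    faces <- faces[face_areas(vertices, faces) > 1e-12, , drop = FALSE]
  }
  m <- structure(list(vertices = vertices, faces = faces, kind = kind),
                 class = "surface_mesh")
  if (validate && kind == "closed_solid") {
    if (!is_watertight(m))
      stop_with("geometry_error", "closed_solid mesh is not watertight")
    if (mesh_volume(m) <= 0)
      stop_with("geometry_error", "closed_solid mesh has non-positive volume")
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh (", x$kind, "): ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " triangles", sep = "")
  if (x$kind == "closed_solid")
    cat(sprintf(", volume %.1f mm^3", mesh_volume(x)))
  cat("\n")
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c3 - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- c3 - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Enclosed volume of a mesh
#'
#' Signed volume by the divergence theorem; meaningful for closed,
#' consistently oriented meshes (positive when normals point outward).
#'
#' @param mesh a `surface_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# Undirected edge table: one row per unique edge with its face multiplicity
# and the count of each direction.
edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- paste(lo, hi)
  mult <- table(key)
  list(n_unique = length(mult), multiplicity = mult,
       directed_dup = anyDuplicated(key_dir) > 0)
}

#' Watertightness check
#'
#' TRUE when every edge is shared by exactly two faces with opposite
#' direction (consistent orientation, no boundary).
#'
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  et <- edge_table(mesh)
  all(et$multiplicity == 2) && !et$directed_dup
}

#' Mesh statistics report
#'
#' Counts of vertices, triangles, boundary edges and the Euler
#' characteristic V - E + F (2 for a closed genus-0 solid, 0 for a
#' through-hole ring, 1 for a disk-like open patch).
#'
#' @param mesh a `surface_mesh`.
#' @return object of class `mesh_stats` with fields `n_vertices`,
#'   `n_triangles`, `n_boundary_edges`, `euler_characteristic`.
#' @export
mesh_stats <- function(mesh) {
  et <- edge_table(mesh)
  structure(list(n_vertices = nrow(mesh$vertices),
                 n_triangles = nrow(mesh$faces),
                 n_edges = et$n_unique,
                 n_boundary_edges = sum(et$multiplicity == 1),
                 euler_characteristic =
                   nrow(mesh$vertices) - et$n_unique + nrow(mesh$faces)),
            class = "mesh_stats")
}

#' @export
print.mesh_stats <- function(x, ...) {
  cat(sprintf("mesh: V=%d F=%d E=%d boundary edges=%d chi=%d\n",
              x$n_vertices, x$n_triangles, x$n_edges,
              x$n_boundary_edges, x$euler_characteristic))
  invisible(x)
}

# Drop vertices not referenced by any face, remapping indices.
drop_unused_vertices <- function(vertices, faces) {
  used <- sort(unique(as.vector(faces)))
  map <- integer(nrow(vertices))
  map[used] <- seq_along(used)
  list(vertices = vertices[used, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3))
}

# Merge coincident vertices (exact key match after fixed-precision print),
# used when rebuilding topology from triangle soup (STL).
weld_vertices <- function(tri_vertices, digits = 9) {
  key <- paste(formatC(tri_vertices[, 1], digits = digits, format = "g"),
               formatC(tri_vertices[, 2], digits = digits, format = "g"),
               formatC(tri_vertices[, 3], digits = digits, format = "g"))
  first <- !duplicated(key)
  ids <- match(key, key[first])
  list(vertices = tri_vertices[first, , drop = FALSE],
       index = ids)
}
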