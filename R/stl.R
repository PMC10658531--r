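# STL import/export, binary and ASCII dialects. STL stores a triangle soup;
# reading welds coincident vertices to recover topology.

#' Write a mesh to STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @param dialect `"binary"` (float32, compact) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (nrow(mesh$faces) == 0)
    stop_with("geometry_error", "refusing to write an empty mesh")
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  nrm <- face_normals(mesh)
  nf <- nrow(mesh$faces)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(utf8ToInt("eafadapt mesh"), rep(0, 80 - 13))), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, v1, v2, v3))           # 12 floats per face
    fl <- writeBin(as.vector(dat), raw(), size = 4, endian = "little")
    # interleave 48 float bytes + 2 attribute bytes per face
    rec <- matrix(as.raw(0), 50, nf)
    rec[1:48, ] <- matrix(fl, 48, nf)
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid eafadapt", con)
    body <- sprintf(
      "facet normal %.9e %.9e %.9e\nouter loop\nvertex %.9e %.9e %.9e\nvertex %.9e %.9e %.9e\nvertex %.9e %.9e %.9e\nendloop\nendfacet",
      nrm[, 1], nrm[, 2], nrm[, 3],
      v1[, 1], v1[, 2], v1[, 3],
      v2[, 1], v2[, 2], v2[, 3],
      v3[, 1], v3[, 2], v3[, 3])
    writeLines(body, con)
    writeLines("endsolid eafadapt", con)
  }
  invisible(path)
}

#' Read a mesh from STL
#'
#' Detects binary vs ASCII automatically, welds coincident vertices and
#' classifies the result as `closed_solid` when watertight, `open_patch`
#' otherwise.
#'
#' @param path STL file.
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop_with("io_error", paste("no such file:", path))
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(512, sz))
  close(con)
  printable <- head >= as.raw(32) & head <= as.raw(126) |
    head %in% as.raw(c(9, 10, 13))
  txt <- rawToChar(head[printable])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, fixed = TRUE, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  w <- weld_vertices(tri)
  faces <- matrix(w$index, ncol = 3, byrow = TRUE)
  m <- surface_mesh(w$vertices, faces, kind = "open_patch", validate = FALSE)
  if (is_watertight(m)) {
    m$kind <- "closed_solid"
    if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (sz != 84 + 50 * nf)
    stop_with("parse_error", "binary STL size inconsistent with facet count")
  body <- readBin(con, "raw", n = 50 * nf)
  keep <- rep(c(rep(TRUE, 48), FALSE, FALSE), nf)
  fl <- readBin(body[keep], "numeric", n = 12 * nf, size = 4,
                endian = "little")
  d <- matrix(fl, 12, nf)      # rows 4..12 are the three vertices
  v <- rbind(t(d[4:6, , drop = FALSE]), t(d[7:9, , drop = FALSE]),
             t(d[10:12, , drop = FALSE]))
  # reorder to per-face consecutive v1,v2,v3
  ord <- as.vector(t(matrix(seq_len(3 * nf), nf, 3)))
  v[ord, , drop = FALSE]
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop_with("parse_error", "ASCII STL: vertex count not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(nums)) stop_with("parse_error", "ASCII STL: malformed vertex line")
  nums
}
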