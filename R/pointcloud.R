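# Point-cloud ingestion and the scan quality-control gate.

#' Construct a point cloud
#'
#' Raw structured-light scanner output: per-point positions in mm.
#'
#' @param points n x 3 numeric matrix (mm); a 0-row matrix is valid (it will
#'   simply fail QC downstream).
#' @param source_id free-text provenance label.
#' @param capture_stage `"first_scan"`, `"second_scan"` or `"merged"`.
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(points, source_id = "",
                        capture_stage = c("first_scan", "second_scan", "merged")) {
  capture_stage <- match.arg(capture_stage)
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), 0, 3)
  if (ncol(points) != 3) stop_with("parse_error", "points must be n x 3")
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop_with("parse_error", "point cloud contains non-finite coordinates")
  structure(list(points = points, source_id = source_id,
                 capture_stage = capture_stage),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", n_points(x), "points,", x$capture_stage,
      if (nzchar(x$source_id)) paste0("(", x$source_id, ")") else "", "\n")
  invisible(x)
}

#' Read a point cloud from disk
#'
#' Supports whitespace-separated XYZ (one `x y z` record per line, `#`
#' comments) and PLY (ASCII, or binary little-endian with all-float32 vertex
#' properties).
#'
#' @param path input file.
#' @param format `"xyz"`, `"ply"` or `"auto"` (by extension, default xyz).
#' @param source_id provenance label; defaults to the file name.
#' @param capture_stage see [point_cloud()].
#' @return a `point_cloud`.
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply"),
                             source_id = basename(path),
                             capture_stage = "first_scan") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_with("io_error", paste("no such file:", path))
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  pts <- if (format == "ply") read_ply_points(path) else read_xyz_points(path)
  point_cloud(pts, source_id = source_id, capture_stage = capture_stage)
}

read_xyz_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(matrix(numeric(0), 0, 3))
  parts <- strsplit(trimws(lines), "[\\s,]+", perl = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    bad <- which(nfield < 3)[1]
    stop_with("parse_error",
              sprintf("malformed XYZ record at data line %d: '%s'",
                      bad, lines[bad]))
  }
  # non-numeric fields surface as NAs and are reported below
  m <- matrix(suppressWarnings(as.numeric(unlist(lapply(parts, `[`, 1:3)))),
              ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop_with("parse_error",
              sprintf("non-numeric XYZ record at data line %d: '%s'",
                      bad, lines[bad]))
  }
  m
}

read_ply_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- read_bin_line(con)
    if (is.null(line)) stop_with("parse_error", "PLY: premature end of header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
    if (length(hdr) > 200) stop_with("parse_error", "PLY: header too long")
  }
  if (hdr[1] != "ply") stop_with("parse_error", "PLY: missing magic line")
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", hdr,
                                                value = TRUE)[1]))
  if (is.na(nv)) stop_with("parse_error", "PLY: no vertex element")
  # vertex properties up to the next element
  vi <- grep("^element vertex", hdr)
  after <- hdr[(vi + 1):length(hdr)]
  stopi <- grep("^(element|end_header)", after)[1]
  props <- grep("^property", after[seq_len(stopi - 1)], value = TRUE)
  pnames <- sub(".*\\s", "", props)
  xyz_idx <- match(c("x", "y", "z"), pnames)
  if (anyNA(xyz_idx)) stop_with("parse_error", "PLY: vertex lacks x/y/z")
  if (grepl("^ascii", fmt)) {
    rows <- character(nv)
    for (i in seq_len(nv)) {
      line <- read_bin_line(con)
      if (is.null(line)) stop_with("parse_error",
                                   sprintf("PLY: vertex %d missing", i))
      rows[i] <- line
    }
    vals <- strsplit(trimws(rows), "\\s+")
    m <- t(vapply(vals, function(x) as.numeric(x[xyz_idx]), numeric(3)))
    if (anyNA(m)) stop_with("parse_error", "PLY: malformed ascii vertex")
    m
  } else if (grepl("little_endian", fmt)) {
    ptypes <- vapply(strsplit(props, "\\s+"), `[`, "", 2)
    if (!all(ptypes %in% c("float", "float32")))
      stop_with("parse_error", "PLY binary: only all-float32 vertices supported")
    np <- length(pnames)
    fl <- readBin(con, "numeric", n = np * nv, size = 4, endian = "little")
    m <- matrix(fl, ncol = np, byrow = TRUE)[, xyz_idx, drop = FALSE]
    m
  } else stop_with("parse_error", paste("PLY: unsupported format", fmt))
}

# Read one LF/CRLF-terminated line from a binary connection.
read_bin_line <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

#' Write a point cloud as XYZ text
#' @param cloud a `point_cloud`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  writeLines(sprintf("%.6f %.6f %.6f", cloud$points[, 1],
                     cloud$points[, 2], cloud$points[, 3]), path)
  invisible(path)
}

#' Scan quality-control gate
#'
#' Applies the capture-quality rule used in the clinical workflow: a cloud
#' with fewer than 400,000 points requires a re-scan of the wound.
#'
#' @param cloud a `point_cloud`.
#' @param threshold minimum acceptable point count (default 400,000).
#' @return object of class `qc_report` with fields `n_points`, `threshold`
#'   and `decision` (`"accept"` or `"rescan"`).
#' @export
qc_point_cloud <- function(cloud, threshold = 400000) {
  n <- n_points(cloud)
  structure(list(n_points = n, threshold = threshold,
                 decision = if (n < threshold) "rescan" else "accept"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("scan QC: %d points (threshold %d) -> %s\n",
              x$n_points, x$threshold, x$decision))
  invisible(x)
}

#' Merge two pre-aligned point clouds
#'
#' Concatenation only: the clouds must already be expressed in the same
#' coordinate frame (registration is the scanner software's job).
#'
#' @param a,b `point_cloud` objects.
#' @return merged `point_cloud` with `capture_stage = "merged"`.
#' @export
merge_clouds <- function(a, b) {
  point_cloud(rbind(a$points, b$points),
              source_id = paste(a$source_id, b$source_id, sep = "+"),
              capture_stage = "merged")
}
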