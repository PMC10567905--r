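#' Read a triangle mesh from STL or PLY
#'
#' Both binary and ASCII STL dialects are supported, plus ASCII PLY.
#' STL stores an independent vertex triple per facet, so the raw soup is
#' cleaned on load: coincident vertices are merged within `merge_tol`
#' (default 1e-6 mm) and degenerate faces dropped. STL carries no unit
#' metadata; coordinates are assumed to be in `units` (default "mm") and the
#' assumption is logged.
#'
#' @param path file path.
#' @param format "stl", "ply" or "auto" (by extension, falling back to stl).
#' @param units unit label to attach.
#' @param merge_tol vertex merge tolerance in mm.
#' @return a cleaned `trimesh`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply"), units = "mm",
                      merge_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else "stl"
  }
  raw <- switch(format, stl = .read_stl(path), ply = .read_ply(path))
  mesh <- clean_mesh(trimesh(raw$vertices, raw$faces, units = units,
                             validate = FALSE), tol = merge_tol)
  .cf_log(sprintf("read %s: %d vertices, %d faces (units assumed %s)",
                  basename(path), nrow(mesh$vertices), nrow(mesh$faces),
                  units))
  mesh
}

.is_ascii_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = 512L)
  txt <- rawToChar(head[head != as.raw(0)])
  Encoding(txt) <- "bytes"
  grepl("^[[:space:]]*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
}

.read_stl <- function(path) {
  if (.is_ascii_stl(path)) .read_stl_ascii(path) else .read_stl_binary(path)
}

.read_stl_binary <- function(path) {
  sz <- file.size(path)
  if (sz < 84) stop("STL format error in ", path,
                    ": file shorter than the 84-byte binary header (",
                    sz, " bytes)")
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + n * 50
  if (sz != expected)
    stop("STL format error in ", path, ": header declares ", n,
         " facets (", expected, " bytes) but file is ", sz, " bytes",
         " (mismatch at byte offset 80)")
  body <- readBin(con, "raw", n = n * 50L)
  dim(body) <- c(50L, n)
  floats <- readBin(as.vector(body[1:48, ]), "numeric", n = 12L * n,
                    size = 4L, endian = "little")
  dim(floats) <- c(12L, n)
  verts <- t(floats[4:12, , drop = FALSE])        # drop facet normals
  vertices <- matrix(t(verts), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3L * n), ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L)
    stop("STL format error in ", path, ": no 'vertex' records found",
         " (first line: '", if (length(lines)) lines[1] else "", "')")
  if (length(vl) %% 3L != 0L)
    stop("STL format error in ", path, ": vertex count ", length(vl),
         " is not a multiple of 3 (near line ", vl[length(vl)], ")")
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad))
    stop("STL format error in ", path, ": malformed vertex at line ",
         vl[bad[1]])
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(toks, `[`, 2:4), use.names = FALSE)))
  if (anyNA(vals))
    stop("STL format error in ", path, ": non-numeric vertex coordinate",
         " near line ", vl[which(is.na(vals))[1] %/% 3 + 1])
  vertices <- matrix(vals, ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(nrow(vertices)), ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY format error in ", path, ": no end_header")
  hdr <- trimws(lines[seq_len(end)])
  if (!identical(hdr[1], "ply"))
    stop("PLY format error in ", path, ": line 1 is not 'ply'")
  if (!any(grepl("^format ascii", hdr)))
    stop("PLY format error in ", path, ": only ascii PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  body <- lines[(end + 1L):length(lines)]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vertices <- matrix(as.numeric(unlist(lapply(vtok, `[`, 1:3))),
                     ncol = 3, byrow = TRUE)
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))) + 1L,
                  ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

#' Write a triangle mesh to STL or PLY
#'
#' STL output carries geometry only. PLY output can carry one scalar per
#' vertex, mapped to 8-bit RGB through [deviation_colormap()] (a symmetric
#' diverging blue-white-red map); this is how gap-deviation colour maps are
#' exported for inspection in standard mesh viewers.
#'
#' @param mesh a `trimesh`.
#' @param path output file path.
#' @param format "stl" or "ply".
#' @param vertex_scalars optional per-vertex values (same length as the
#'   vertex count) to encode as colour (PLY only).
#' @param binary write binary STL (default) or the ASCII dialect.
#' @param scalar_limit symmetric colour range limit passed to
#'   [deviation_colormap()].
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("stl", "ply"),
                       vertex_scalars = NULL, binary = TRUE,
                       scalar_limit = NULL) {
  format <- match.arg(format)
  validate_trimesh(mesh)
  if (!is.null(vertex_scalars) &&
      length(vertex_scalars) != nrow(mesh$vertices))
    stop("vertex_scalars length (", length(vertex_scalars),
         ") must equal vertex count (", nrow(mesh$vertices), ")")
  ok <- tryCatch({
    switch(format,
           stl = if (binary) .write_stl_binary(mesh, path)
                 else .write_stl_ascii(mesh, path),
           ply = .write_ply(mesh, path, vertex_scalars, scalar_limit))
    TRUE
  }, error = function(e) {
    stop("I/O error writing ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

.write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(80L), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  fn <- face_normals(mesh)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  block <- t(cbind(fn, v1, v2, v3))      # 12 floats per facet, column-major
  fl <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
  dim(fl) <- c(48L, nf)
  body <- rbind(fl, matrix(as.raw(0), 2L, nf))
  writeBin(as.vector(body), con)
}

.write_stl_ascii <- function(mesh, path) {
  fn <- face_normals(mesh)
  f <- mesh$faces; v <- mesh$vertices
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  out <- c("solid crownfit",
           as.vector(rbind(
             paste("  facet normal", fmt(fn)),
             "    outer loop",
             paste("      vertex", fmt(v[f[, 1], , drop = FALSE])),
             paste("      vertex", fmt(v[f[, 2], , drop = FALSE])),
             paste("      vertex", fmt(v[f[, 3], , drop = FALSE])),
             "    endloop",
             "  endfacet")),
           "endsolid crownfit")
  writeLines(out, path)
}

.write_ply <- function(mesh, path, vertex_scalars, scalar_limit) {
  v <- mesh$vertices; f <- mesh$faces
  has_col <- !is.null(vertex_scalars)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (has_col) {
    rgb <- deviation_colormap(vertex_scalars, limit = scalar_limit)
    vlines <- sprintf("%.9g %.9g %.9g %d %d %d", v[, 1], v[, 2], v[, 3],
                      rgb[, 1], rgb[, 2], rgb[, 3])
  } else {
    vlines <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  }
  flines <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
}

#' Read / write margin landmark files
#'
#' Plain text, one "x y z" triple (mm) per line; blank lines and lines
#' starting with '#' are ignored.
#'
#' @param path file path.
#' @param label cohort/surface label ("abutment" or "crown").
#' @return `read_landmarks`: a `landmark_set` (list with `points` matrix,
#'   `label`, `source`).
#' @export
read_landmarks <- function(path, label = "abutment") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[\\s,]+", perl = TRUE)
  bad <- which(vapply(toks, length, 1L) != 3L)
  if (length(bad)) stop("landmark format error in ", path, " at record ",
                        bad[1], ": expected 3 coordinates")
  pts <- matrix(as.numeric(unlist(toks)), ncol = 3, byrow = TRUE)
  if (anyNA(pts)) stop("landmark format error in ", path,
                       ": non-numeric coordinate")
  landmark_set(pts, label = label, source = path)
}

#' @rdname read_landmarks
#' @param points n x 3 matrix of landmark positions (mm).
#' @param source provenance string.
#' @export
landmark_set <- function(points, label = "abutment", source = "<memory>") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("landmarks must be n x 3")
  if (nrow(points) < 4L) stop("need at least 4 landmarks, got ", nrow(points))
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  if (min(d) < 1e-6)
    stop("two landmarks coincide within 1e-6 mm")
  structure(list(points = points, label = label, source = source),
            class = "landmark_set")
}

#' @rdname read_landmarks
#' @param landmarks a `landmark_set` or n x 3 matrix.
#' @export
write_landmarks <- function(landmarks, path) {
  pts <- if (inherits(landmarks, "landmark_set")) landmarks$points
         else as.matrix(landmarks)
  writeLines(c("# crownfit margin landmarks (x y z, mm)",
               sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3])),
             path)
  invisible(path)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, label '%s' (%s)\n",
              nrow(x$points), x$label, x$source))
  invisible(x)
}
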