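#' Triangle mesh objects
#'
#' A `trimesh` is the package's mesh container: an n x 3 numeric matrix of
#' vertex coordinates (millimetres) and an m x 3 integer matrix of 1-based
#' vertex indices, one row per triangular face. STL files carry no unit
#' metadata, so the unit label is attached explicitly and defaults to "mm".
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in `units`.
#' @param faces integer matrix (m x 3) of 1-based vertex index triples.
#' @param units unit label for the coordinates; the package assumes "mm".
#' @param validate check the mesh invariants (valid indices, no repeated
#'   vertex within a face, no degenerate face).
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, units = "mm", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  mesh <- structure(list(vertices = vertices, faces = faces, units = units),
                    class = "trimesh")
  if (validate) validate_trimesh(mesh)
  mesh
}

#' @rdname trimesh
#' @param mesh a `trimesh`.
#' @export
validate_trimesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) < 3L) stop("mesh has fewer than 3 vertices")
  if (nrow(f) < 1L) stop("mesh has no faces")
  if (any(is.na(v))) stop("mesh vertices contain NA")
  if (any(f < 1L) || any(f > nrow(v)))
    stop("face index out of range [1, ", nrow(v), "]")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("a face repeats a vertex")
  if (any(face_areas(mesh) <= 1e-12))
    stop("mesh contains a degenerate face (area <= 1e-12 mm^2)")
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces [%s]\n",
              nrow(x$vertices), nrow(x$faces), x$units))
  invisible(x)
}

#' Per-face areas and normals
#'
#' @param mesh a `trimesh`.
#' @return `face_areas`: numeric vector of triangle areas (mm^2).
#'   `face_normals`: m x 3 matrix of unit face normals following the stored
#'   winding order. `vertex_normals`: n x 3 matrix of area-weighted unit
#'   vertex normals.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  cr / len
}

#' @rdname face_areas
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  ar <- face_areas(mesh)
  w <- fn * ar                       # area-weighted
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (j in 1:3) {
      acc <- rowsum(w[, j], idx)
      n[as.integer(rownames(acc)), j] <- n[as.integer(rownames(acc)), j] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Clean a raw vertex/face soup
#'
#' Merges vertices that coincide within `tol` (default 1e-6 mm, well below
#' scanner noise; removes the facet-level vertex duplication inherent to
#' STL), drops faces that repeat a vertex after merging, drops degenerate
#' faces (area <= 1e-12 mm^2), and discards unreferenced vertices.
#'
#' @param mesh a `trimesh` (not yet validated).
#' @param tol vertex merge tolerance in mm.
#' @return a cleaned, validated `trimesh`.
#' @export
clean_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices; f <- mesh$faces
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v <- v[first, , drop = FALSE]
  f <- matrix(map[f], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0L) stop("mesh is empty after cleaning")
  m <- trimesh(v, f, units = mesh$units, validate = FALSE)
  ar <- face_areas(m)
  f <- f[ar > 1e-12, , drop = FALSE]
  if (nrow(f) == 0L) stop("mesh is empty after cleaning")
  used <- sort(unique(as.vector(f)))
  f <- matrix(match(f, used), ncol = 3)
  trimesh(v[used, , drop = FALSE], f, units = mesh$units)
}

#' Shortest distance from points to a mesh surface
#'
#' Exact Euclidean point-to-triangle distance, minimised over every face of
#' the mesh (the minimum is attained and reported as a surface point with
#' its containing face and barycentric coordinates). Ties between faces are
#' broken by the lowest face index, so results are deterministic.
#'
#' @param points numeric vector of length 3 or an n x 3 matrix.
#' @param mesh a `trimesh`.
#' @return a list with `distance` (mm), `face` (1-based index), `closest`
#'   (n x 3 matrix) and `barycentric` (n x 3 matrix of nonnegative weights
#'   summing to 1).
#' @export
point_to_surface_distance <- function(points, mesh) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  validate_trimesh(mesh)
  cpp_point_mesh_distance(points, mesh$vertices, mesh$faces)
}

#' Vertex adjacency graph of a mesh
#'
#' Undirected weighted graph over vertex indices, one edge per unique face
#' edge, weighted by Euclidean edge length (mm). This is the substrate for
#' graph-geodesic (shortest path) computations between mesh nodes.
#'
#' @param mesh a `trimesh`.
#' @return an [igraph::graph] with `weight` edge attribute.
#' @export
vertex_adjacency_graph <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  g
}

#' Closed 2-manifold check
#'
#' TRUE when every undirected edge is shared by exactly two faces.
#'
#' @param mesh a `trimesh`.
#' @export
is_closed_manifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Reconstruct a surface point from face + barycentric coordinates
#' @param mesh a `trimesh`.
#' @param face 1-based face indices.
#' @param barycentric n x 3 matrix of barycentric weights.
#' @return n x 3 matrix of positions.
#' @export
surface_point_position <- function(mesh, face, barycentric) {
  if (is.null(dim(barycentric))) barycentric <- matrix(barycentric, ncol = 3)
  f <- mesh$faces[face, , drop = FALSE]
  barycentric[, 1] * mesh$vertices[f[, 1], , drop = FALSE] +
    barycentric[, 2] * mesh$vertices[f[, 2], , drop = FALSE] +
    barycentric[, 3] * mesh$vertices[f[, 3], , drop = FALSE]
}
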