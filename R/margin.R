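#' Margin curves
#'
#' A `margin_curve` is an ordered closed 3D polyline representing a finish
#' line: the boundary curve of the contact area between an abutment and a
#' restoration. Points are stored once (the closing segment from the last
#' point back to the first is implicit) and the arc length is the sum of all
#' segment lengths including the closing segment.
#'
#' @param points n x 3 matrix of ordered curve points (mm), n >= 3.
#' @return a `margin_curve` with fields `points`, `closed` (always TRUE) and
#'   `arc_length` (mm).
#' @export
margin_curve <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("curve points must be n x 3")
  if (nrow(points) < 3L) stop("a closed curve needs at least 3 points")
  seg <- .curve_segments(points)
  len <- sqrt(rowSums((seg$b - seg$a)^2))
  if (any(len < 1e-12)) stop("consecutive curve points coincide")
  structure(list(points = points, closed = TRUE, arc_length = sum(len)),
            class = "margin_curve")
}

.curve_segments <- function(points) {
  n <- nrow(points)
  list(a = points, b = points[c(2:n, 1), , drop = FALSE])
}

#' @export
print.margin_curve <- function(x, ...) {
  cat(sprintf("<margin_curve> %d points, closed, arc length %.4f mm\n",
              nrow(x$points), x$arc_length))
  invisible(x)
}

#' Order margin landmarks into a closed curve
#'
#' Annotated margin landmarks come without a guaranteed ordering. Because
#' crown finish lines are near-planar rings, the order is reconstructed by
#' projecting the points onto their best-fit plane (principal axes of the
#' centred coordinates) and sorting by polar angle about the projected
#' centroid. The result is deterministic: the cycle starts at the landmark
#' with the smallest polar angle and proceeds counter-clockwise in the
#' projection plane.
#'
#' @param landmarks a `landmark_set` or n x 3 matrix of points (mm).
#' @return a `margin_curve`.
#' @section Failure modes: geometry that is not ring-like is rejected rather
#'   than silently mis-ordered: if two landmarks fall at the same polar angle
#'   (within 1e-6 rad) or the ring test fails (sd of projected radius > 0.9
#'   of its mean, as for collinear points), an error advises supplying
#'   manually ordered input.
#' @export
order_landmarks <- function(landmarks) {
  pts <- if (inherits(landmarks, "landmark_set")) landmarks$points
         else landmark_set(landmarks)$points
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  proj <- x %*% sv$v[, 1:2, drop = FALSE]   # best-fit plane coordinates
  r <- sqrt(rowSums(proj^2))
  if (mean(r) < 1e-12 || stats::sd(r) / mean(r) > 0.9)
    stop("landmarks do not form a ring (radius sd/mean > 0.9); ",
         "supply manually ordered landmarks instead")
  ang <- atan2(proj[, 2], proj[, 1])
  ord <- order(ang)
  if (any(diff(ang[ord]) < 1e-6))
    stop("two landmarks share a polar angle within 1e-6 rad; ",
         "supply manually ordered landmarks instead")
  margin_curve(pts[ord, , drop = FALSE])
}

#' Resample a closed curve at equal arc-length spacing
#'
#' Places `n` points along the closed polyline at spacing arc_length / n,
#' starting from the curve's first point. The polyline geometry (and hence
#' the arc length) is preserved to numerical precision because samples lie
#' on the original segments.
#'
#' @param curve a `margin_curve`.
#' @param n number of output points (>= 4).
#' @return a `margin_curve` with `n` points.
#' @export
resample_curve <- function(curve, n = 500L) {
  stopifnot(inherits(curve, "margin_curve"))
  n <- as.integer(n)
  if (n < 4L) stop("n must be >= 4")
  pts <- curve$points
  seg <- .curve_segments(pts)
  len <- sqrt(rowSums((seg$b - seg$a)^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- (seq_len(n) - 1L) * total / n
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > nrow(pts)] <- nrow(pts)
  t <- (s - cum[idx]) / len[idx]
  out <- seg$a[idx, , drop = FALSE] +
    (seg$b[idx, , drop = FALSE] - seg$a[idx, , drop = FALSE]) * t
  margin_curve(out)
}

#' Distance from points to a closed curve
#'
#' Exact point-to-segment distance minimised over every segment of the
#' closed polyline (not point-to-vertex, so the value converges as the curve
#' is densified).
#'
#' @param points vector of length 3 or n x 3 matrix (mm).
#' @param curve a `margin_curve`.
#' @return list with `distance` (mm), `segment` (1-based index of the
#'   realizing segment) and `closest` (n x 3 matrix).
#' @export
point_to_curve_distance <- function(points, curve) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  seg <- .curve_segments(curve$points)
  cpp_point_polyline_distance(points, seg$a, seg$b)
}

#' Extract the marginal region of interest
#'
#' Returns the submesh of all faces whose every vertex lies within
#' `band_height` of the margin curve (3D point-to-polyline distance).
#' The default band of 0.5 mm captures the margin and the abutment surface
#' 0.5 mm above the finish line — the region used for reference best-fit
#' alignment. Vertex coordinates are preserved exactly.
#'
#' @param mesh a `trimesh`.
#' @param curve a `margin_curve` lying on or near the mesh (every curve
#'   point within `curve_tol` of the surface).
#' @param band_height band half-width in mm.
#' @param curve_tol maximum allowed curve-to-surface distance (mm).
#' @return a `trimesh` submesh.
#' @export
extract_margin_roi <- function(mesh, curve, band_height = 0.5,
                               curve_tol = 0.1) {
  stopifnot(inherits(mesh, "trimesh"), inherits(curve, "margin_curve"))
  if (band_height < 0) stop("band_height must be >= 0")
  on_surface <- point_to_surface_distance(curve$points, mesh)$distance
  if (max(on_surface) > curve_tol)
    stop(sprintf(paste0("margin curve lies %.3f mm from the mesh ",
                        "(tolerance %.3f mm); check alignment/units"),
                 max(on_surface), curve_tol))
  vd <- point_to_curve_distance(mesh$vertices, curve)$distance
  ok <- vd <= band_height + 1e-9
  keep <- ok[mesh$faces[, 1]] & ok[mesh$faces[, 2]] & ok[mesh$faces[, 3]]
  if (!any(keep)) stop("empty ROI: no face lies within the band")
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(match(f, used), ncol = 3), units = mesh$units)
}
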