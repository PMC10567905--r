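#' Rigid transforms
#'
#' A `rigid_transform` maps a point p to `R p + t`, with `R` a proper
#' rotation (orthonormal, det +1) and `t` a translation in mm. No scaling is
#' permitted anywhere in the package: fit discrepancies must never be
#' absorbed by a scale factor.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant is not +1 within 1e-9 (reflection?)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' @rdname rigid_transform
#' @param first,second transforms; the composition applies `first`, then
#'   `second`.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Apply a rigid transform
#'
#' Maps every point p to `R p + t`. Lengths, areas and mesh topology are
#' preserved.
#'
#' @param x a point matrix, `trimesh`, `margin_curve` or `landmark_set`.
#' @param transform a `rigid_transform`.
#' @return an object of the same type as `x`.
#' @export
apply_transform <- function(x, transform) UseMethod("apply_transform")

.apply_pts <- function(pts, tr)
  sweep(pts %*% t(tr$rotation), 2, tr$translation, "+")

#' @export
apply_transform.matrix <- function(x, transform) .apply_pts(x, transform)

#' @export
apply_transform.trimesh <- function(x, transform) {
  x$vertices <- .apply_pts(x$vertices, transform)
  x
}

#' @export
apply_transform.margin_curve <- function(x, transform)
  margin_curve(.apply_pts(x$points, transform))

#' @export
apply_transform.landmark_set <- function(x, transform) {
  x$points <- .apply_pts(x$points, transform)
  x
}

#' Least-squares rigid alignment of corresponding points (Kabsch)
#'
#' Finds the proper rotation and translation minimising the summed squared
#' distance between corresponding point pairs, via SVD of the cross-
#' covariance with the determinant sign correction (so reflections are never
#' returned). Used as the coarse initialisation of [trimmed_icp()] when
#' corresponding margin landmarks are available.
#'
#' @param source_points,target_points n x 3 matrices of corresponding points
#'   (n >= 3, not collinear).
#' @return a `rigid_transform` mapping source to target.
#' @export
kabsch_align <- function(source_points, target_points) {
  s <- as.matrix(source_points); t_ <- as.matrix(target_points)
  if (nrow(s) != nrow(t_) || nrow(s) < 3L)
    stop("need >= 3 corresponding point pairs")
  cs <- colMeans(s); ct <- colMeans(t_)
  H <- crossprod(sweep(s, 2, cs), sweep(t_, 2, ct))
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) point configuration: rotation is not ",
         "determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Principal-axes initial alignment
#'
#' Centroid + principal-axes alignment of two point clouds, used to
#' initialise ICP when no landmark correspondences exist. The four proper-
#' rotation sign combinations of the principal axes are tried and the one
#' with the smallest mean squared source-to-target nearest-vertex distance
#' is kept.
#'
#' @param source,target `trimesh` objects.
#' @return a `rigid_transform`.
#' @export
principal_axes_init <- function(source, target) {
  vs <- source$vertices; vt <- target$vertices
  cs <- colMeans(vs); ct <- colMeans(vt)
  es <- svd(sweep(vs, 2, cs))$v
  et <- svd(sweep(vt, 2, ct))$v
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  probe <- vs[seq(1, nrow(vs), length.out = min(200L, nrow(vs))), ,
              drop = FALSE]
  best <- NULL; best_rms <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    flip <- diag(c(s1, s2, s1 * s2))     # proper rotations only
    R <- et %*% flip %*% t(es)
    tr <- rigid_transform(R, ct - as.numeric(R %*% cs))
    d <- cpp_knn(.apply_pts(probe, tr), vt, 1L)$distance
    rms <- sqrt(mean(d^2))
    if (rms < best_rms) { best_rms <- rms; best <- tr }
  }
  best
}

#' Reference best-fit alignment by trimmed ICP
#'
#' Implements the reference best-fit principle — rigid registration driven
#' only by correspondences whose residual falls below a predefined distance
#' threshold — as a trimmed iterative-closest-point loop:
#' source vertices are matched to their exact closest points on the target
#' surface (point-to-triangle, ties broken by lowest face index), pairs with
#' distance above `inlier_threshold` are discarded, and the Kabsch update is
#' applied. Iteration stops when the inlier RMS changes by less than `tol`
#' or `max_iter` is reached; an update that would increase the inlier RMS is
#' rejected and terminates the loop, so the objective is non-increasing
#' across accepted iterations.
#'
#' @param source,target `trimesh` objects (source is moved onto target).
#' @param init initial `rigid_transform`; default is the identity.
#' @param inlier_threshold correspondence rejection distance in mm. The
#'   reference best-fit threshold is a free choice; 0.5 mm is the package
#'   default and is always logged.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the inlier RMS change (mm).
#' @param max_source_points at most this many source vertices are used
#'   (evenly strided, deterministic) to bound cost on dense scans.
#' @return a `registration_result`: `transform`, `inlier_rms` (mm),
#'   `inlier_fraction`, `iterations`, `converged`, and the per-iteration
#'   `rms_trace`.
#' @export
trimmed_icp <- function(source, target, init = rigid_transform(),
                        inlier_threshold = 0.5, max_iter = 100L,
                        tol = 1e-5, max_source_points = 2000L) {
  stopifnot(inherits(source, "trimesh"), inherits(target, "trimesh"))
  if (inlier_threshold <= 0) stop("inlier_threshold must be > 0")
  vs <- source$vertices
  if (nrow(vs) > max_source_points) {
    idx <- unique(round(seq(1, nrow(vs), length.out = max_source_points)))
    vs <- vs[idx, , drop = FALSE]
  }
  transform <- init
  prev_transform <- init
  prev_rms <- Inf
  trace <- numeric(0)
  iterations <- 0L
  converged <- FALSE
  repeat {
    moved <- .apply_pts(vs, transform)
    nn <- cpp_point_mesh_distance(moved, target$vertices, target$faces)
    inl <- nn$distance <= inlier_threshold
    if (!any(inl))
      stop("alignment failure: zero inliers at iteration ", iterations,
           " (threshold ", inlier_threshold, " mm, min distance ",
           signif(min(nn$distance), 4), " mm)")
    rms <- sqrt(mean(nn$distance[inl]^2))
    if (rms > prev_rms + 1e-12) {              # reject worsening update
      transform <- prev_transform
      break
    }
    trace <- c(trace, rms)
    if (is.finite(prev_rms) && prev_rms - rms < tol) {
      converged <- TRUE
      break
    }
    if (iterations >= max_iter) break
    # Kabsch on the absolute source (correspondences were found under the
    # current transform, so the update is the full source->target map)
    upd <- tryCatch(
      kabsch_align(vs[inl, , drop = FALSE],
                   nn$closest[inl, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(upd)) break
    prev_transform <- transform
    prev_rms <- rms
    transform <- upd
    iterations <- iterations + 1L
  }
  # final evaluation under the returned transform
  moved <- .apply_pts(vs, transform)
  nn <- cpp_point_mesh_distance(moved, target$vertices, target$faces)
  inl <- nn$distance <= inlier_threshold
  if (!any(inl)) stop("alignment failure: zero inliers after final update")
  structure(list(transform = transform,
                 inlier_rms = sqrt(mean(nn$distance[inl]^2)),
                 inlier_fraction = mean(inl),
                 iterations = iterations,
                 converged = converged,
                 rms_trace = trace,
                 inlier_threshold = inlier_threshold),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result> inlier RMS %.6g mm, ",
                     "inliers %.1f%%, %d iterations, %s ",
                     "(threshold %g mm)\n"),
              x$inlier_rms, 100 * x$inlier_fraction, x$iterations,
              if (x$converged) "converged" else "not converged",
              x$inlier_threshold))
  invisible(x)
}

#' Serialize a rigid transform as a 12-number text record
#'
#' Row-major rotation followed by the translation, one number per line with
#' a comment header; readable by [read_transform()].
#'
#' @param transform a `rigid_transform`.
#' @param path output file.
#' @export
write_transform <- function(transform, path) {
  vals <- c(t(transform$rotation), transform$translation)
  writeLines(c("# crownfit rigid transform: 9 row-major rotation entries,",
               "# then 3 translation entries (mm)",
               sprintf("%.17g", vals)), path)
  invisible(path)
}

#' @rdname write_transform
#' @param path file written by [write_transform()].
#' @export
read_transform <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- as.numeric(lines)
  if (length(vals) != 12L || anyNA(vals))
    stop("transform file must hold exactly 12 numbers: ", path)
  rigid_transform(matrix(vals[1:9], 3, 3, byrow = TRUE), vals[10:12])
}
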