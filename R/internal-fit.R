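#' Poisson-disk surface sampling by dart throwing
#'
#' Draws candidate points uniformly on the mesh surface (face chosen with
#' probability proportional to area, then uniform barycentric coordinates)
#' and accepts a candidate only if no previously accepted sample lies within
#' `radius`. Sampling stops after `rejected_streak_limit` consecutive
#' rejections, which in practice leaves the surface near-maximally packed.
#' The minimum pairwise spacing >= radius is a hard guarantee and is
#' asserted before returning.
#'
#' @param mesh a `trimesh`.
#' @param radius minimum pairwise sample distance (mm).
#' @param seed integer RNG seed; mandatory so sampling is reproducible.
#' @param rejected_streak_limit consecutive-rejection stopping criterion.
#' @return a `poisson_sample_set`: `positions` (n x 3 mm), `face`,
#'   `barycentric`, plus the sampling parameters.
#' @export
poisson_disk_sample <- function(mesh, radius, seed,
                                rejected_streak_limit = 1000L) {
  stopifnot(inherits(mesh, "trimesh"))
  if (radius <= 0) stop("radius must be > 0")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  raw <- cpp_poisson_disk(mesh$vertices, mesh$faces, radius,
                          as.integer(rejected_streak_limit))
  n <- nrow(raw$positions)
  if (n == 1L)
    .cf_log("poisson_disk_sample: radius ", radius,
            " mm admits only a single sample on this mesh")
  if (n > 1L) {
    dmin <- min(cpp_knn(raw$positions, raw$positions, 2L)$distance[, 2])
    stopifnot("Poisson-disk guarantee violated" = dmin >= radius)
  }
  structure(list(positions = raw$positions, face = raw$face,
                 barycentric = raw$barycentric, radius = radius,
                 seed = as.integer(seed),
                 rejected_streak_limit = as.integer(rejected_streak_limit)),
            class = "poisson_sample_set")
}

#' @export
print.poisson_sample_set <- function(x, ...) {
  cat(sprintf("<poisson_sample_set> %d samples, radius %g mm, seed %d\n",
              nrow(x$positions), x$radius, x$seed))
  invisible(x)
}

.is_consistently_oriented <- function(mesh) {
  f <- mesh$faces
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  !anyDuplicated(paste(de[, 1], de[, 2]))
}

#' Internal gap-distance field between intaglio and abutment
#'
#' Computes per-sample distances between the crown intaglio surface and the
#' prepared-abutment surface, in the common aligned frame, as a measure of
#' internal fit. Two modes are provided:
#'
#' * `nearest_surface` (default, the cement-gap reading): the shortest
#'   Euclidean distance from each intaglio sample to the abutment surface,
#'   signed positive when the sample lies on the outward side of its closest
#'   abutment triangle (a real gap) and negative when the intaglio
#'   penetrates the abutment (diagnostic of alignment faults).
#' * `edge_graph_geodesic`: shortest paths on the union of both meshes'
#'   vertex adjacency graphs, with bridging edges from every sample to its
#'   containing intaglio face corners and to its `k = 3` nearest abutment
#'   vertices (Euclidean weights); the reported value is each sample's
#'   shortest path to any abutment node. Graph paths can never beat the
#'   Euclidean minimum, so this mode is an upper envelope of the first.
#'
#' Distances are reported in micrometres. The headline per-crown internal
#' fit statistic is the mean of the field.
#'
#' @param intaglio `trimesh` the samples were drawn on.
#' @param abutment `trimesh`, consistently outward-oriented for signing.
#' @param samples a `poisson_sample_set` drawn on `intaglio`.
#' @param mode "nearest_surface" or "edge_graph_geodesic".
#' @param n_bins histogram bin count (equal bins from 0 to the 99.5th
#'   percentile; values beyond fall in the last bin).
#' @return a `gap_field`: per-sample `distances` (signed, um), `signs`,
#'   `mean`, `sd`, `max` (um), `histogram` (`breaks_um`, `counts`), `mode`
#'   and the sample set.
#' @export
gap_distances <- function(intaglio, abutment, samples,
                          mode = c("nearest_surface", "edge_graph_geodesic"),
                          n_bins = 50L) {
  mode <- match.arg(mode)
  stopifnot(inherits(samples, "poisson_sample_set"))
  pos <- samples$positions
  if (mode == "nearest_surface") {
    if (!.is_consistently_oriented(abutment))
      stop("abutment mesh winding is inconsistent: cannot orient normals ",
           "for gap signing")
    nn <- cpp_point_mesh_distance(pos, abutment$vertices, abutment$faces)
    fn <- face_normals(abutment)
    outward <- rowSums((pos - nn$closest) * fn[nn$face, , drop = FALSE])
    d_um <- 1000 * nn$distance * ifelse(outward < 0, -1, 1)
  } else {
    d_um <- 1000 * .graph_geodesic_gap(intaglio, abutment, samples)
  }
  hist_edges <- {
    top <- stats::quantile(abs(d_um), 0.995, names = FALSE)
    if (top <= 0) top <- max(abs(d_um), 1)
    seq(0, top, length.out = n_bins + 1L)
  }
  clipped <- pmin(pmax(abs(d_um), 0), hist_edges[n_bins + 1L])
  counts <- tabulate(pmin(findInterval(clipped, hist_edges,
                                       rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  structure(list(samples = samples,
                 distances = d_um,
                 signs = ifelse(d_um < 0, -1, 1),
                 mean = mean(d_um),
                 sd = stats::sd(d_um),
                 max = max(d_um),
                 histogram = list(breaks_um = hist_edges, counts = counts),
                 mode = mode),
            class = "gap_field")
}

.graph_geodesic_gap <- function(intaglio, abutment, samples, k = 3L) {
  na <- nrow(abutment$vertices)
  ni <- nrow(intaglio$vertices)
  ns <- nrow(samples$positions)
  fa <- abutment$faces
  fi <- intaglio$faces + na
  ea <- .mesh_edges(abutment$vertices, fa)
  ei <- .mesh_edges(intaglio$vertices, fi - na)
  ei$edges <- ei$edges + na
  # bridge samples to their k nearest abutment vertices
  knn <- cpp_knn(samples$positions, abutment$vertices, k)
  sid <- na + ni + seq_len(ns)
  bridge_e <- cbind(rep(sid, each = k), as.vector(t(knn$index)))
  bridge_w <- as.vector(t(knn$distance))
  # anchor samples on their containing intaglio face
  fc <- intaglio$faces[samples$face, , drop = FALSE]
  anchor_e <- cbind(rep(sid, 3L), as.vector(fc) + na)
  anchor_w <- sqrt(rowSums((samples$positions[rep(seq_len(ns), 3L), ,
                                              drop = FALSE] -
                            intaglio$vertices[as.vector(fc), ,
                                              drop = FALSE])^2))
  # super node adjacent to every abutment vertex with zero weight
  super <- na + ni + ns + 1L
  super_e <- cbind(rep(super, na), seq_len(na))
  edges <- rbind(ea$edges, ei$edges, bridge_e, anchor_e, super_e)
  weights <- c(ea$weights, ei$weights, bridge_w, anchor_w, rep(0, na))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < super)
    g <- igraph::add_vertices(g, super - igraph::vcount(g))
  d <- igraph::distances(g, v = sid, to = super, weights = weights,
                         algorithm = "dijkstra")
  as.numeric(d)
}

.mesh_edges <- function(v, f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                     v[e[, 2], , drop = FALSE])^2))
  list(edges = e, weights = w)
}

#' @export
print.gap_field <- function(x, ...) {
  cat(sprintf("<gap_field> %d samples (%s mode)\n",
              length(x$distances), x$mode))
  cat(sprintf("  mean %.2f um, sd %.2f um, max %.2f um, %.1f%% negative\n",
              x$mean, x$sd, x$max, 100 * mean(x$signs < 0)))
  invisible(x)
}

#' @export
summary.gap_field <- function(object, ...) {
  print(object)
  q <- stats::quantile(object$distances, c(0, .25, .5, .75, .95, 1))
  cat("  quantiles (um):\n")
  print(round(q, 2))
  invisible(object)
}

#' @export
plot.gap_field <- function(x, ...) {
  h <- x$histogram
  graphics::barplot(h$counts,
                    names.arg = round(h$breaks_um[-1]),
                    xlab = "gap distance (um)", ylab = "samples",
                    main = sprintf("internal gap field (%s)", x$mode), ...)
  invisible(x)
}

#' Diverging deviation colormap
#'
#' Maps values to 8-bit RGB through a fixed blue-white-red diverging map
#' symmetric about zero and clipped at `limit`. The red minus blue channel
#' difference is strictly monotone in the (clipped) value, so orderings are
#' preserved.
#'
#' @param values numeric vector.
#' @param limit clip value; defaults to `max(abs(values))`.
#' @return integer matrix (n x 3) of RGB in 0..255.
#' @export
deviation_colormap <- function(values, limit = NULL) {
  if (is.null(limit)) limit <- max(abs(values), 1e-12)
  t <- pmin(pmax(values / limit, -1), 1)
  r <- ifelse(t >= 0, 255, round(255 * (1 + t)))
  b <- ifelse(t <= 0, 255, round(255 * (1 - t)))
  g <- round(255 * (1 - abs(t)))
  cbind(red = as.integer(r), green = as.integer(g), blue = as.integer(b))
}

#' Render an internal-gap colour map and histogram
#'
#' Interpolates the sampled gap field onto the intaglio vertices by
#' inverse-squared-distance weighting of the 8 nearest samples, writes a
#' colour PLY (diverging map, symmetric about 0, clipped at `limit_um`,
#' default 300 um) and a plain-text histogram file alongside it.
#'
#' @param intaglio the `trimesh` the field was computed on.
#' @param field a `gap_field`.
#' @param path output PLY path; the histogram is written to
#'   `paste0(path, ".hist.txt")`.
#' @param limit_um symmetric colour range limit in micrometres.
#' @param k number of nearest samples used in the interpolation.
#' @return invisibly, the per-vertex interpolated scalars (um).
#' @export
render_gap_map <- function(intaglio, field, path, limit_um = 300, k = 8L) {
  stopifnot(inherits(field, "gap_field"))
  pos <- field$samples$positions
  k <- min(k, nrow(pos))
  nn <- cpp_knn(intaglio$vertices, pos, k)
  w <- 1 / pmax(nn$distance, 1e-9)^2
  vals <- matrix(field$distances[nn$index], nrow = nrow(nn$index))
  scal <- rowSums(w * vals) / rowSums(w)
  write_mesh(intaglio, path, format = "ply", vertex_scalars = scal,
             scalar_limit = limit_um)
  h <- field$histogram
  writeLines(c("# crownfit gap histogram: bin_lo_um bin_hi_um count",
               sprintf("%.6g %.6g %d", h$breaks_um[-length(h$breaks_um)],
                       h$breaks_um[-1], h$counts)),
             paste0(path, ".hist.txt"))
  invisible(scal)
}
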