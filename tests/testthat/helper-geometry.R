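# Geometry fixtures and independent brute-force oracles used across the
# suite. Oracles are deliberately naive: plain R, no shared code with the
# package internals they check.

options(crownfit.quiet = TRUE)

# memoised fixture cache (meshes are deterministic, so rebuild once)
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

unit_triangle <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

# axis-aligned planar grid, faces wound counter-clockwise seen from +z
grid_mesh <- function(nx = 10, ny = nx, xlim = c(0, 1), ylim = c(0, 1),
                      z = 0) {
  xs <- seq(xlim[1], xlim[2], length.out = nx + 1)
  ys <- seq(ylim[1], ylim[2], length.out = ny + 1)
  v <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1), z)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  f <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    f[[length(f) + 1L]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    f[[length(f) + 1L]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  trimesh(v, do.call(rbind, f))
}

# closed latitude/longitude sphere: 2n meridians, n-1 latitude rings + poles
uv_sphere <- function(radius = 5, n = 24, center = c(0, 0, 0)) {
  th <- seq(0, pi, length.out = n + 1)
  m <- 2L * n
  ph <- 2 * pi * (seq_len(m) - 1L) / m
  rings <- lapply(2:n, function(i)
    cbind(radius * sin(th[i]) * cos(ph), radius * sin(th[i]) * sin(ph),
          radius * cos(th[i])))
  v <- rbind(c(0, 0, radius), do.call(rbind, rings), c(0, 0, -radius))
  v <- sweep(v, 2, center, "+")
  ring <- function(i) 1L + (i - 2L) * m + seq_len(m)
  jn <- c(seq_len(m - 1L) + 1L, 1L)
  f <- list(cbind(1L, ring(2), ring(2)[jn]))
  for (i in 2:(n - 1)) {
    a <- ring(i); b <- ring(i + 1)
    f[[length(f) + 1L]] <- rbind(cbind(a, b, b[jn]), cbind(a, b[jn], a[jn]))
  }
  last <- nrow(v)
  f[[length(f) + 1L]] <- cbind(last, ring(n)[jn], ring(n))
  trimesh(v, do.call(rbind, f))
}

# open cylinder tube (no caps), rings at exact multiples of h / n_rings
cylinder_tube <- function(radius = 4, height = 5, res = 0.1) {
  n_theta <- ceiling(2 * pi * radius / res)
  n_rings <- ceiling(height / res)
  ph <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  v <- do.call(rbind, lapply(0:n_rings, function(i)
    cbind(radius * cos(ph), radius * sin(ph), i * height / n_rings)))
  jn <- c(seq_len(n_theta - 1L) + 1L, 1L)
  f <- list()
  for (i in seq_len(n_rings)) {
    a <- (i - 1L) * n_theta + seq_len(n_theta)
    b <- i * n_theta + seq_len(n_theta)
    f[[length(f) + 1L]] <- rbind(cbind(a, b, b[jn]), cbind(a, b[jn], a[jn]))
  }
  trimesh(v, do.call(rbind, f))
}

# random triangle soup with non-degenerate faces (distance queries only)
random_soup <- function(n_faces = 50, seed = 1, scale = 2) {
  set.seed(seed)
  f <- list()
  v <- list()
  while (length(f) < n_faces) {
    tri <- matrix(runif(9, -scale, scale), 3, 3)
    area <- 0.5 * sqrt(sum(crossprod3(tri[2, ] - tri[1, ],
                                      tri[3, ] - tri[1, ])^2))
    if (area > 1e-3) {
      base <- length(v)
      v <- c(v, list(tri[1, ], tri[2, ], tri[3, ]))
      f[[length(f) + 1L]] <- base + 1:3
    }
  }
  trimesh(do.call(rbind, v), do.call(rbind, f))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# --- independent oracles -------------------------------------------------

# exact point-to-triangle distance by candidate enumeration (vertices,
# clamped edge projections, interior plane projection)
pt_tri_dist_bf <- function(p, a, b, c) {
  cand <- list(a, b, c)
  for (e in list(list(a, b), list(b, c), list(c, a))) {
    d <- e[[2]] - e[[1]]
    t <- sum((p - e[[1]]) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    cand[[length(cand) + 1L]] <- e[[1]] + t * d
  }
  n <- crossprod3(b - a, c - a)
  q <- p - n * sum((p - a) * n) / sum(n * n)
  w <- tryCatch(solve(cbind(b - a, c - a, n), q - a), error = function(e) NULL)
  if (!is.null(w) && w[1] >= -1e-12 && w[2] >= -1e-12 &&
      w[1] + w[2] <= 1 + 1e-12)
    cand[[length(cand) + 1L]] <- q
  min(vapply(cand, function(x) sqrt(sum((p - x)^2)), 1.0))
}

point_mesh_dist_bf <- function(p, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  min(vapply(seq_len(nrow(f)), function(i)
    pt_tri_dist_bf(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), 1.0))
}

pt_seg_dist_bf <- function(p, a, b) {
  d <- b - a
  t <- min(max(sum((p - a) * d) / sum(d * d), 0), 1)
  sqrt(sum((p - a - t * d)^2))
}

# directed Hausdorff from the points of closed polyline a to polyline b,
# minimising over every point-segment pair
directed_hausdorff_bf <- function(pa, pb) {
  nb <- nrow(pb)
  segs <- cbind(seq_len(nb), c(seq_len(nb - 1L) + 1L, 1L))
  max(vapply(seq_len(nrow(pa)), function(i)
    min(vapply(seq_len(nb), function(j)
      pt_seg_dist_bf(pa[i, ], pb[segs[j, 1], ], pb[segs[j, 2], ]), 1.0)),
    1.0))
}

random_rotation <- function(max_angle_deg = 360) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -1, 1) * max_angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

random_rigid <- function(max_angle_deg = 360, max_trans = 2) {
  rigid_transform(random_rotation(max_angle_deg),
                  runif(3, -max_trans, max_trans))
}

circle_curve <- function(radius = 5, n = 50, z = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  margin_curve(cbind(radius * cos(th), radius * sin(th), z))
}

test_abutment <- function(res = 0.3) {
  cached(paste0("abutment", res),
         function() make_abutment(abutment_spec(mesh_resolution = res)))
}
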