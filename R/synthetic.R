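#' Synthetic abutment specification
#'
#' Parametric stand-in for a prepared molar: a frustum-like solid of
#' revolution with a concave chamfer band at the base (the finish line is
#' the chamfer's outer rim), an axial wall, a rounded occlusal edge and a
#' flat occlusal table. Anatomy is irrelevant to metric correctness; the
#' simple geometry admits analytic gap oracles. Defaults follow a molar
#' preparation with a 1.0 mm wide chamfer margin.
#'
#' @param base_radius margin rim radius (mm).
#' @param top_radius axial-wall radius at the occlusal end (mm).
#' @param height total preparation height (mm).
#' @param chamfer_width horizontal and vertical extent of the quarter-round
#'   chamfer (mm). The axial wall starts at radius `base_radius -
#'   chamfer_width`.
#' @param mesh_resolution target edge length (mm).
#' @return an `abutment_spec`.
#' @export
abutment_spec <- function(base_radius = 4.5, top_radius = 3.5, height = 5.0,
                          chamfer_width = 1.0, mesh_resolution = 0.1) {
  if (!(top_radius > 0 && top_radius < base_radius))
    stop("need 0 < top_radius < base_radius")
  if (chamfer_width <= 0 || chamfer_width >= base_radius)
    stop("need 0 < chamfer_width < base_radius")
  if (height <= chamfer_width) stop("height must exceed chamfer_width")
  if (mesh_resolution > chamfer_width / 2)
    stop("mesh_resolution (", mesh_resolution, " mm) too coarse to ",
         "represent the chamfer; need <= chamfer_width/2")
  structure(list(base_radius = base_radius, top_radius = top_radius,
                 height = height, chamfer_width = chamfer_width,
                 mesh_resolution = mesh_resolution),
            class = "abutment_spec")
}

.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate the synthetic abutment
#'
#' Builds a watertight solid of revolution from `spec`: base disc at z = 0,
#' quarter-round chamfer from the margin rim (radius `base_radius`) to the
#' axial wall, linear wall to `top_radius`, quarter-round occlusal edge and
#' a flat occlusal table. The margin curve is exactly the rim vertex ring.
#' Deterministic for a fixed spec.
#'
#' @param spec an [abutment_spec()].
#' @return an `abutment_model`: list with `mesh` (`trimesh`), `margin`
#'   (`margin_curve`), `region` (per-face factor: base, margin_band, axial,
#'   occlusal_bevel, occlusal) and `spec`.
#' @export
make_abutment <- function(spec = abutment_spec()) {
  stopifnot(inherits(spec, "abutment_spec"))
  res <- spec$mesh_resolution
  Rb <- spec$base_radius; Rt <- spec$top_radius
  H <- spec$height; w <- spec$chamfer_width
  e <- min(0.5, Rt / 3)                 # occlusal edge rounding radius
  r_joint <- Rb - w                     # wall radius at the chamfer top

  rings <- list(); region <- character(0)  # region of the band BELOW each ring
  add_ring <- function(r, z, reg) {
    rings[[length(rings) + 1L]] <<- c(r, z)
    region <<- c(region, reg)
  }
  # base disc (inner ring first; its inward band is the centre fan)
  radii <- seq(res, Rb - res / 2, by = res)
  for (r in radii) add_ring(r, 0, "base")
  add_ring(Rb, 0, "base")                           # margin rim
  rim_index <- length(rings)
  # chamfer: quarter circle radius w, centre (r_joint, 0)
  nphi <- max(2L, ceiling((pi * w / 2) / res))
  for (phi in seq_len(nphi) * (pi / 2) / nphi)
    add_ring(r_joint + w * cos(phi), w * sin(phi), "margin_band")
  # axial wall
  L <- sqrt((H - e - w)^2 + (r_joint - Rt)^2)
  nw <- max(2L, ceiling(L / res))
  for (t in seq_len(nw) / nw)
    add_ring(r_joint + t * (Rt - r_joint), w + t * (H - e - w), "axial")
  # occlusal edge rounding: quarter circle radius e, centre (Rt - e, H - e)
  ne <- max(2L, ceiling((pi * e / 2) / res))
  for (phi in seq_len(ne) * (pi / 2) / ne)
    add_ring((Rt - e) + e * cos(phi), (H - e) + e * sin(phi),
             "occlusal_bevel")
  # occlusal table (to the centre)
  radii_top <- seq(Rt - e - res, res, by = -res)
  for (r in radii_top) add_ring(r, H, "occlusal")

  prof <- do.call(rbind, rings)
  n_ring <- nrow(prof)
  n_theta <- max(16L, ceiling(2 * pi * Rb / res))
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  ct <- cos(theta); st <- sin(theta)
  V <- matrix(0, n_ring * n_theta + 2L, 3)
  for (i in seq_len(n_ring)) {
    idx <- (i - 1L) * n_theta + seq_len(n_theta)
    V[idx, 1] <- prof[i, 1] * ct
    V[idx, 2] <- prof[i, 1] * st
    V[idx, 3] <- prof[i, 2]
  }
  base_center <- n_ring * n_theta + 1L     # (0,0,0)
  top_center <- n_ring * n_theta + 2L      # (0,0,H)
  V[top_center, 3] <- H

  jn <- c(seq_len(n_theta - 1L) + 1L, 1L)  # next index around the ring
  faces <- vector("list", n_ring + 1L)
  freg <- vector("list", n_ring + 1L)
  # centre fan of the base disc
  r1 <- seq_len(n_theta)
  faces[[1]] <- cbind(base_center, r1, jn)
  freg[[1]] <- rep("base", n_theta)
  for (i in 2:n_ring) {
    a <- (i - 2L) * n_theta + seq_len(n_theta)
    b <- (i - 1L) * n_theta + seq_len(n_theta)
    an <- (i - 2L) * n_theta + jn
    bn <- (i - 1L) * n_theta + jn
    faces[[i]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
    freg[[i]] <- rep(region[i], 2L * n_theta)
  }
  last <- (n_ring - 1L) * n_theta
  faces[[n_ring + 1L]] <- cbind(top_center, last + jn, last + r1)
  freg[[n_ring + 1L]] <- rep("occlusal", n_theta)
  F <- do.call(rbind, faces)
  reg <- unlist(freg)

  mesh <- trimesh(V, F)
  # enforce outward orientation via the signed volume
  vol <- .signed_volume(mesh)
  if (vol < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  }
  margin <- margin_curve(V[(rim_index - 1L) * n_theta + seq_len(n_theta), ,
                           drop = FALSE])
  structure(list(mesh = mesh, margin = margin,
                 region = factor(reg, levels = c("base", "margin_band",
                                                 "axial", "occlusal_bevel",
                                                 "occlusal")),
                 spec = spec),
            class = "abutment_model")
}

.signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' @export
print.abutment_model <- function(x, ...) {
  cat("<abutment_model>\n  ")
  print(x$mesh)
  cat("  ")
  print(x$margin)
  invisible(x)
}

#' Synthetic crown specification
#'
#' Parameters of a virtual crown intaglio: the designed cementation spacer
#' (an outward offset of the abutment surface, zero below
#' `spacer_start_height` above the finish line, blended in over 0.1 mm),
#' plus distortion terms emulating manufacturing error — occlusal doming
#' (sintering distortion lifting the intaglio over the occlusal table),
#' uniform shrinkage about the centroid, margin extension error (the crown
#' margin displaced radially outward), isotropic scanner noise, and a
#' residual seating transform.
#'
#' @param spacer cementation spacer in micrometres.
#' @param spacer_start_height height above the finish line at which the
#'   spacer begins (mm).
#' @param margin_extension_error radial crown-margin displacement (mm).
#' @param occlusal_doming occlusal lift (micrometres).
#' @param radial_shrinkage uniform scale deficit about the centroid
#'   (fraction; |value| < 0.05).
#' @param noise_sd isotropic per-vertex Gaussian noise (micrometres).
#' @param seed RNG seed for the noise.
#' @param seating_transform a `rigid_transform` applied last.
#' @return a `crown_spec`.
#' @export
crown_spec <- function(spacer = 40, spacer_start_height = 0.5,
                       margin_extension_error = 0, occlusal_doming = 0,
                       radial_shrinkage = 0, noise_sd = 0, seed = 1L,
                       seating_transform = rigid_transform()) {
  if (spacer < 0) stop("spacer must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(radial_shrinkage) >= 0.05)
    stop("|radial_shrinkage| must be < 0.05")
  stopifnot(inherits(seating_transform, "rigid_transform"))
  structure(list(spacer = spacer, spacer_start_height = spacer_start_height,
                 margin_extension_error = margin_extension_error,
                 occlusal_doming = occlusal_doming,
                 radial_shrinkage = radial_shrinkage,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 seating_transform = seating_transform),
            class = "crown_spec")
}

#' Generate a synthetic crown intaglio with ground truth
#'
#' Constructs the intaglio by offsetting the abutment surface (excluding
#' the base disc) outward along vertex normals by the blended spacer
#' profile, then applies, in order: occlusal doming (vertical lift, full
#' over the occlusal table, cosine-tapered to zero at the wall), uniform
#' shrinkage about the intaglio centroid, margin extension (radial outward
#' displacement decaying to zero 0.3 mm above the margin), per-vertex
#' Gaussian noise (after the ground truth is captured, so the truth
#' describes the noise-free nominal surface), and the seating transform.
#'
#' @param abutment an `abutment_model` from [make_abutment()].
#' @param spec a [crown_spec()].
#' @return a `crown_model`: `intaglio` (`trimesh`), `margin`
#'   (`margin_curve`, the true noise-free crown margin, seated), `region`
#'   (per intaglio face), and `truth` (list of the analytic contributions:
#'   per-vertex spacer and doming components in um, the spacer-zone height,
#'   the noise-free abutment margin, the seating transform and the spec).
#' @export
make_crown <- function(abutment, spec = crown_spec()) {
  stopifnot(inherits(abutment, "abutment_model"),
            inherits(spec, "crown_spec"))
  mesh <- abutment$mesh
  sel <- abutment$region != "base"
  f <- mesh$faces[sel, , drop = FALSE]
  reg <- droplevels(abutment$region[sel])
  used <- sort(unique(as.vector(f)))
  V0 <- mesh$vertices[used, , drop = FALSE]
  F <- matrix(match(f, used), ncol = 3)
  nrm <- vertex_normals(mesh)[used, , drop = FALSE]

  blend <- 0.1
  h <- V0[, 3]                               # height above the margin plane
  s_mm <- (spec$spacer / 1000) *
    .smoothstep((h - spec$spacer_start_height) / blend)
  V <- V0 + nrm * s_mm

  # occlusal doming: vertical lift, 1 over the table, cosine taper to the wall
  Rt <- abutment$spec$top_radius
  e <- min(0.5, Rt / 3)
  rho <- sqrt(V0[, 1]^2 + V0[, 2]^2)
  taper <- ifelse(rho <= Rt - e, 1,
                  ifelse(rho >= Rt, 0,
                         0.5 * (1 + cos(pi * (rho - (Rt - e)) / e))))
  dome_mm <- (spec$occlusal_doming / 1000) * taper
  V[, 3] <- V[, 3] + dome_mm

  k <- spec$radial_shrinkage
  if (k != 0) {
    violation <- k * rho - s_mm
    if (max(violation) > spec$spacer / 1000)
      stop("generation error: shrinkage collapses the intaglio below the ",
           "abutment by more than the spacer (max violation ",
           signif(max(violation) * 1000, 3), " um)")
  }
  ctr <- colMeans(V)
  V <- sweep(sweep(V, 2, ctr), 2, rep(1 - k, 3), "*")
  V <- sweep(V, 2, ctr, "+")

  emm <- spec$margin_extension_error
  if (emm != 0) {
    decay <- 1 - .smoothstep(h / 0.3)
    rr <- pmax(rho, 1e-9)
    V[, 1] <- V[, 1] + emm * decay * V0[, 1] / rr
    V[, 2] <- V[, 2] + emm * decay * V0[, 2] / rr
  }

  # true crown margin: the transformed rim (h = 0: spacer 0, taper 0, decay 1)
  mpts <- abutment$margin$points
  mpts <- sweep(sweep(sweep(mpts, 2, ctr), 2, rep(1 - k, 3), "*"), 2, ctr,
                "+")
  if (emm != 0) {
    mr <- pmax(sqrt(abutment$margin$points[, 1]^2 +
                    abutment$margin$points[, 2]^2), 1e-9)
    mpts[, 1] <- mpts[, 1] + emm * abutment$margin$points[, 1] / mr
    mpts[, 2] <- mpts[, 2] + emm * abutment$margin$points[, 2] / mr
  }

  truth <- list(spacer_um = spec$spacer,
                spacer_component_um = 1000 * s_mm,
                doming_component_um = 1000 * dome_mm,
                # faces straddling the blend boundary are only partially
                # offset, so the fully-offset zone starts one edge length
                # above the end of the blend
                spacer_zone_height = spec$spacer_start_height + blend +
                  abutment$spec$mesh_resolution,
                vertex_height = h,
                abutment_margin = abutment$margin,
                seating_transform = spec$seating_transform,
                spec = spec)

  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    V <- V + matrix(stats::rnorm(length(V), 0, spec$noise_sd / 1000),
                    ncol = 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  tr <- spec$seating_transform
  intaglio <- trimesh(.apply_pts(V, tr), F)
  crown_margin <- margin_curve(.apply_pts(mpts, tr))
  structure(list(intaglio = intaglio, margin = crown_margin, region = reg,
                 truth = truth),
            class = "crown_model")
}

#' @export
print.crown_model <- function(x, ...) {
  cat("<crown_model>\n  ")
  print(x$intaglio)
  cat(sprintf("  spacer %g um, doming %g um, extension %g mm, shrinkage %g, noise %g um\n",
              x$truth$spec$spacer, x$truth$spec$occlusal_doming,
              x$truth$spec$margin_extension_error,
              x$truth$spec$radial_shrinkage, x$truth$spec$noise_sd))
  invisible(x)
}

#' Cohort parameter distributions
#'
#' Each distortion parameter of [crown_spec()] is drawn per crown from a
#' normal distribution `c(mean, sd)` truncated at +/- 3 sd and at the
#' parameter's physical bounds. Scanner noise and the residual seating
#' perturbation scale are fixed per cohort.
#'
#' @param spacer,margin_extension_error,occlusal_doming,radial_shrinkage
#'   length-2 numeric `c(mean, sd)`; units as in [crown_spec()].
#' @param noise_sd scanner noise sd (um).
#' @param seating_rot_sd_deg,seating_trans_sd_mm sd of the small random
#'   residual seating rotation (degrees, about a random axis) and
#'   translation (mm per component).
#' @param label cohort label.
#' @return a `crown_spec_distribution`.
#' @export
crown_spec_distribution <- function(spacer = c(40, 0),
                                    margin_extension_error = c(0, 0),
                                    occlusal_doming = c(0, 0),
                                    radial_shrinkage = c(0, 0),
                                    noise_sd = 5,
                                    seating_rot_sd_deg = 0.2,
                                    seating_trans_sd_mm = 0.02,
                                    label = "group") {
  as2 <- function(x) if (length(x) == 1L) c(x, 0) else x[1:2]
  structure(list(spacer = as2(spacer),
                 margin_extension_error = as2(margin_extension_error),
                 occlusal_doming = as2(occlusal_doming),
                 radial_shrinkage = as2(radial_shrinkage),
                 noise_sd = noise_sd,
                 seating_rot_sd_deg = seating_rot_sd_deg,
                 seating_trans_sd_mm = seating_trans_sd_mm,
                 label = label),
            class = "crown_spec_distribution")
}

.rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  lo <- max(lo, mean - 3 * sd); hi <- min(hi, mean + 3 * sd)
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

.random_small_transform <- function(rot_sd_deg, trans_sd_mm) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::rnorm(1, 0, rot_sd_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  # re-orthonormalize against accumulated rounding
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  rigid_transform(R, stats::rnorm(3, 0, trans_sd_mm))
}

#' Generate two crown cohorts with known ground truth
#'
#' Draws `n_per_group` crown specs from each distribution, builds the
#' crowns against a shared synthetic abutment, and (optionally) writes the
#' complete study file tree: abutment STL + margin landmarks, and per crown
#' an intaglio STL, 50 margin landmarks sampled at equal arc length from
#' the true crown margin, the seating transform and a plain-text truth
#' record. Fully reproducible from `master_seed`.
#'
#' @param group1,group2 [crown_spec_distribution()] objects.
#' @param n_per_group crowns per cohort (>= 2).
#' @param master_seed integer seed controlling every draw.
#' @param abutment an [abutment_spec()].
#' @param out_dir if non-NULL, the file tree is written here.
#' @param n_landmarks landmarks written per crown margin.
#' @return a `cohort_set`: the `abutment_model`, a list of `crown_model`s
#'   per group, the drawn parameter table, and file paths when written.
#' @export
make_cohorts <- function(group1, group2, n_per_group = 30L,
                         master_seed = 1L,
                         abutment = abutment_spec(),
                         out_dir = NULL, n_landmarks = 50L) {
  stopifnot(inherits(group1, "crown_spec_distribution"),
            inherits(group2, "crown_spec_distribution"))
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  ab <- make_abutment(abutment)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))

  draw_group <- function(dist, gi) {
    crowns <- vector("list", n_per_group)
    params <- vector("list", n_per_group)
    for (i in seq_len(n_per_group)) {
      sp <- crown_spec(
        spacer = .rtrunc(1, dist$spacer[1], dist$spacer[2], lo = 0),
        margin_extension_error = .rtrunc(1, dist$margin_extension_error[1],
                                         dist$margin_extension_error[2]),
        occlusal_doming = .rtrunc(1, dist$occlusal_doming[1],
                                  dist$occlusal_doming[2], lo = 0),
        radial_shrinkage = .rtrunc(1, dist$radial_shrinkage[1],
                                   dist$radial_shrinkage[2],
                                   lo = -0.0499, hi = 0.0499),
        noise_sd = dist$noise_sd,
        seed = sample.int(.Machine$integer.max - 1L, 1L),
        seating_transform = .random_small_transform(dist$seating_rot_sd_deg,
                                                    dist$seating_trans_sd_mm))
      crowns[[i]] <- make_crown(ab, sp)
      params[[i]] <- data.frame(group = dist$label, crown = i,
                                spacer_um = sp$spacer,
                                margin_extension_mm =
                                  sp$margin_extension_error,
                                occlusal_doming_um = sp$occlusal_doming,
                                radial_shrinkage = sp$radial_shrinkage,
                                noise_sd_um = sp$noise_sd,
                                seed = sp$seed)
    }
    list(crowns = crowns, params = do.call(rbind, params))
  }
  g1 <- draw_group(group1, 1L)
  g2 <- draw_group(group2, 2L)
  out <- structure(list(abutment = ab,
                        groups = stats::setNames(
                          list(g1$crowns, g2$crowns),
                          c(group1$label, group2$label)),
                        params = rbind(g1$params, g2$params),
                        master_seed = as.integer(master_seed),
                        out_dir = out_dir),
                   class = "cohort_set")
  if (!is.null(out_dir)) .write_cohort_tree(out, out_dir, n_landmarks)
  out
}

.write_cohort_tree <- function(cohorts, out_dir, n_landmarks) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ab <- cohorts$abutment
  write_mesh(ab$mesh, file.path(out_dir, "abutment.stl"))
  write_landmarks(resample_curve(ab$margin, n_landmarks)$points,
                  file.path(out_dir, "abutment_margin.xyz"))
  for (gname in names(cohorts$groups)) {
    gdir <- file.path(out_dir, gname)
    dir.create(gdir, showWarnings = FALSE)
    crowns <- cohorts$groups[[gname]]
    for (i in seq_along(crowns)) {
      cr <- crowns[[i]]
      stem <- file.path(gdir, sprintf("crown_%02d", i))
      write_mesh(cr$intaglio, paste0(stem, ".stl"))
      write_landmarks(resample_curve(cr$margin, n_landmarks)$points,
                      paste0(stem, "_landmarks.xyz"))
      write_transform(cr$truth$seating_transform,
                      paste0(stem, "_seating.txt"))
      sp <- cr$truth$spec
      writeLines(c("# crownfit synthetic crown ground truth",
                   sprintf("spacer_um = %.9g", sp$spacer),
                   sprintf("spacer_start_height_mm = %.9g",
                           sp$spacer_start_height),
                   sprintf("margin_extension_error_mm = %.9g",
                           sp$margin_extension_error),
                   sprintf("occlusal_doming_um = %.9g", sp$occlusal_doming),
                   sprintf("radial_shrinkage = %.9g", sp$radial_shrinkage),
                   sprintf("noise_sd_um = %.9g", sp$noise_sd),
                   sprintf("seed = %d", sp$seed)),
                 paste0(stem, "_truth.txt"))
    }
  }
  invisible(out_dir)
}

#' @export
print.cohort_set <- function(x, ...) {
  ns <- vapply(x$groups, length, 1L)
  cat(sprintf("<cohort_set> groups: %s (master seed %d)\n",
              paste(sprintf("%s n=%d", names(ns), ns), collapse = ", "),
              x$master_seed))
  invisible(x)
}
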