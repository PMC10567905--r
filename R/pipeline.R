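#' Assess one crown against the reference abutment
#'
#' Runs the single-crown workflow: order the margin landmarks into curves,
#' align the crown into the reference frame by trimmed ICP of its marginal
#' region of interest (the band within `band_height` of the crown margin,
#' where a seated crown coincides with the abutment), then measure
#'
#' * marginal fit: the Hausdorff distance between the abutment margin curve
#'   and the aligned crown margin curve, and
#' * internal fit: the Poisson-disk sampled gap field from the aligned
#'   intaglio to the abutment, excluding samples within
#'   `internal_exclusion` of the margin (that band is the marginal-fit
#'   region, where the designed gap is zero by construction).
#'
#' @param intaglio crown intaglio `trimesh`.
#' @param crown_margin crown margin: a `margin_curve`, `landmark_set` or
#'   n x 3 matrix of landmarks (ordered via [order_landmarks()]).
#' @param abutment_mesh reference abutment `trimesh`.
#' @param abutment_margin abutment margin (same accepted types).
#' @param align "roi_icp" (default) or "none" (inputs already aligned).
#' @param band_height marginal ROI band (mm).
#' @param inlier_threshold trimmed-ICP threshold (mm).
#' @param curve_samples per-curve densification for the Hausdorff metric.
#' @param disk_radius Poisson-disk radius (mm).
#' @param seed sampling seed (mandatory).
#' @param gap_mode "nearest_surface" or "edge_graph_geodesic".
#' @param internal_exclusion samples closer than this to the crown margin
#'   (mm, 3D distance) are excluded from the internal-fit field.
#' @return a `crown_fit` object with the registration result, the
#'   `marginal_fit_report`, the `gap_field`, and the two headline metrics
#'   `marginal_hausdorff_um` and `internal_mean_um`.
#' @export
assess_crown <- function(intaglio, crown_margin, abutment_mesh,
                         abutment_margin, align = c("roi_icp", "none"),
                         band_height = 0.5, inlier_threshold = 0.5,
                         curve_samples = 500L, disk_radius = 0.15, seed,
                         gap_mode = "nearest_surface",
                         internal_exclusion = 0.6) {
  align <- match.arg(align)
  as_curve <- function(x) {
    if (inherits(x, "margin_curve")) x else order_landmarks(x)
  }
  crown_curve <- as_curve(crown_margin)
  ab_curve <- as_curve(abutment_margin)

  if (align == "roi_icp") {
    roi <- extract_margin_roi(intaglio, crown_curve,
                              band_height = band_height)
    reg <- trimmed_icp(roi, abutment_mesh,
                       inlier_threshold = inlier_threshold)
    intaglio <- apply_transform(intaglio, reg$transform)
    crown_curve <- apply_transform(crown_curve, reg$transform)
  } else {
    reg <- NULL
  }

  marginal <- hausdorff_margin(ab_curve, crown_curve,
                               n_samples = curve_samples)
  samples <- poisson_disk_sample(intaglio, radius = disk_radius, seed = seed)
  dmargin <- point_to_curve_distance(samples$positions, crown_curve)$distance
  keep <- dmargin > internal_exclusion
  if (!any(keep))
    stop("internal-fit sampling left no samples outside the margin band")
  inner <- samples
  inner$positions <- samples$positions[keep, , drop = FALSE]
  inner$face <- samples$face[keep]
  inner$barycentric <- samples$barycentric[keep, , drop = FALSE]
  gap <- gap_distances(intaglio, abutment_mesh, inner, mode = gap_mode)
  structure(list(registration = reg,
                 marginal = marginal,
                 gap = gap,
                 marginal_hausdorff_um = marginal$hausdorff,
                 internal_mean_um = gap$mean,
                 params = list(align = align, band_height = band_height,
                               inlier_threshold = inlier_threshold,
                               curve_samples = curve_samples,
                               disk_radius = disk_radius, seed = seed,
                               gap_mode = gap_mode,
                               internal_exclusion = internal_exclusion)),
            class = "crown_fit")
}

#' @export
print.crown_fit <- function(x, ...) {
  cat("<crown_fit>\n")
  cat(sprintf("  marginal Hausdorff: %.2f um; internal mean gap: %.2f um (%s)\n",
              x$marginal_hausdorff_um, x$internal_mean_um, x$gap$mode))
  if (!is.null(x$registration)) { cat("  "); print(x$registration) }
  invisible(x)
}

#' Run configuration
#'
#' `run_pipeline()` accepts either a named list or a path to a plain-text
#' key = value file ('#' comments allowed) with the keys:
#' `abutment_mesh`, `abutment_landmarks`, `group1_dir`, `group2_dir`
#' (directories of crown `*.stl` files with sibling `*_landmarks.xyz`),
#' optional `group1_label`, `group2_label`, `alignment_threshold` (mm,
#' default 0.5), `band_height` (0.5), `curve_samples` (500), `disk_radius`
#' (0.15), `gap_mode` (nearest_surface), `alpha` (0.05),
#' `internal_exclusion` (0.6), `out_dir`, and a mandatory integer `seed`.
#'
#' @param path key = value file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad)) stop("config parse error at line: ", lines[bad[1]])
  out <- stats::setNames(lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[`, "", 2))
  out
}

.cfg_get <- function(config, field, default = NULL, required = FALSE) {
  v <- config[[field]]
  if (is.null(v)) {
    if (required) stop("config validation error: missing field '", field, "'")
    return(default)
  }
  v
}

#' Run the full two-cohort fit study
#'
#' End-to-end workflow: for every crown of both cohorts — align (marginal
#' ROI trimmed ICP), measure marginal fit (Hausdorff between margin curves)
#' and internal fit (Poisson-disk gap field mean) — then summarize each
#' cohort and compare the cohorts with pooled two-sample t tests on both
#' endpoints. Deterministic given the config: crown `i` of group `g` uses
#' sampling seed `seed + 1000 * g + i`.
#'
#' @param config named list or path to a key = value file; see
#'   [read_run_config()].
#' @return a `crownfit_report`: `per_crown` (data frame of per-crown
#'   metrics), `marginal_test` and `internal_test` (`group_comparison`),
#'   and the effective `config`. When `out_dir` is set, the per-crown table
#'   (TSV) and a summary text report are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  if (!is.list(config)) stop("config must be a list or a file path")
  ab_mesh_path <- .cfg_get(config, "abutment_mesh", required = TRUE)
  ab_lm_path <- .cfg_get(config, "abutment_landmarks", required = TRUE)
  dirs <- c(.cfg_get(config, "group1_dir", required = TRUE),
            .cfg_get(config, "group2_dir", required = TRUE))
  labels <- c(.cfg_get(config, "group1_label", "group1"),
              .cfg_get(config, "group2_label", "group2"))
  seed <- .cfg_get(config, "seed", required = TRUE)
  if (seed != round(seed)) stop("config validation error: seed must be ",
                                "an integer")
  opts <- list(
    inlier_threshold = .cfg_get(config, "alignment_threshold", 0.5),
    band_height = .cfg_get(config, "band_height", 0.5),
    curve_samples = .cfg_get(config, "curve_samples", 500),
    disk_radius = .cfg_get(config, "disk_radius", 0.15),
    gap_mode = .cfg_get(config, "gap_mode", "nearest_surface"),
    internal_exclusion = .cfg_get(config, "internal_exclusion", 0.6),
    alpha = .cfg_get(config, "alpha", 0.05))
  for (p in c(ab_mesh_path, ab_lm_path, dirs)) {
    if (!file.exists(p))
      stop("config validation error: path does not exist: ", p)
  }
  .cf_log("pipeline parameters: ",
          paste(names(opts), unlist(opts), sep = "=", collapse = ", "),
          ", seed=", seed)
  abutment_mesh <- read_mesh(ab_mesh_path)
  ab_curve <- order_landmarks(read_landmarks(ab_lm_path, "abutment"))

  rows <- list()
  for (g in 1:2) {
    stls <- sort(list.files(dirs[g], pattern = "\\.stl$", full.names = TRUE))
    if (length(stls) < 2L)
      stop("config validation error: fewer than 2 crown meshes in ",
           dirs[g])
    for (i in seq_along(stls)) {
      lm_path <- sub("\\.stl$", "_landmarks.xyz", stls[i])
      if (!file.exists(lm_path))
        stop("missing landmark file for crown mesh: ", lm_path)
      fit <- tryCatch(
        assess_crown(read_mesh(stls[i]),
                     read_landmarks(lm_path, "crown"),
                     abutment_mesh, ab_curve,
                     inlier_threshold = opts$inlier_threshold,
                     band_height = opts$band_height,
                     curve_samples = opts$curve_samples,
                     disk_radius = opts$disk_radius,
                     seed = as.integer(seed + 1000 * g + i),
                     gap_mode = opts$gap_mode,
                     internal_exclusion = opts$internal_exclusion),
        error = function(e) stop("stage failure for crown '",
                                 basename(stls[i]), "': ",
                                 conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = labels[g], crown = basename(stls[i]),
        marginal_hausdorff_um = fit$marginal_hausdorff_um,
        internal_mean_um = fit$internal_mean_um,
        internal_sd_um = fit$gap$sd,
        icp_rms_mm = if (is.null(fit$registration)) NA_real_
                     else fit$registration$inlier_rms,
        n_gap_samples = length(fit$gap$distances))
    }
  }
  per_crown <- do.call(rbind, rows)
  m1 <- per_crown$marginal_hausdorff_um[per_crown$group == labels[1]]
  m2 <- per_crown$marginal_hausdorff_um[per_crown$group == labels[2]]
  i1 <- per_crown$internal_mean_um[per_crown$group == labels[1]]
  i2 <- per_crown$internal_mean_um[per_crown$group == labels[2]]
  marginal_test <- student_t_from_raw(m1, m2, labels, alpha = opts$alpha)
  internal_test <- student_t_from_raw(i1, i2, labels, alpha = opts$alpha)
  report <- structure(list(per_crown = per_crown,
                           marginal_test = marginal_test,
                           internal_test = internal_test,
                           config = c(list(abutment_mesh = ab_mesh_path,
                                           abutment_landmarks = ab_lm_path,
                                           group1_dir = dirs[1],
                                           group2_dir = dirs[2],
                                           seed = seed), opts)),
                      class = "crownfit_report")
  out_dir <- .cfg_get(config, "out_dir")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(per_crown, file.path(out_dir, "per_crown.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sink(file.path(out_dir, "summary.txt")); print(report); sink()
  }
  report
}

#' @export
print.crownfit_report <- function(x, ...) {
  cat("<crownfit_report>\n")
  agg <- stats::aggregate(
    cbind(marginal_hausdorff_um, internal_mean_um) ~ group,
    data = x$per_crown, function(v) c(mean = mean(v), sd = stats::sd(v)))
  cat("per-cohort metrics (um):\n")
  print(agg)
  cat("\nmarginal fit (maximum absolute marginal discrepancy, Hausdorff):\n")
  print(x$marginal_test)
  cat("\ninternal fit (mean gap,", x$config$gap_mode, "mode):\n")
  print(x$internal_test)
  invisible(x)
}
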