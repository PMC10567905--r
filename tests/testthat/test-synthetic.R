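# Synthetic abutment/crown generator and its analytic ground truth.

test_that("the default abutment is a closed 2-manifold with the specified margin", {
  ab <- test_abutment(0.3)
  expect_true(is_closed_manifold(ab$mesh))
  expect_gt(crownfit:::.signed_volume(ab$mesh), 0)  # outward orientation
  expect_equal(ab$margin$arc_length, 2 * pi * 4.5, tolerance = 0.01)
  expect_setequal(levels(ab$region),
                  c("base", "margin_band", "axial", "occlusal_bevel",
                    "occlusal"))
  expect_identical(make_abutment(ab$spec)$mesh$vertices, ab$mesh$vertices)
})

test_that("a chamfer-wide wall gives vertical axial faces (cylindrical limit)", {
  sp <- abutment_spec(base_radius = 4.5, top_radius = 3.5,
                      chamfer_width = 1.0, mesh_resolution = 0.3)
  ab <- make_abutment(sp)
  fn <- face_normals(ab$mesh)[ab$region == "axial", , drop = FALSE]
  expect_lt(max(abs(fn[, 3])), 1e-6)
})

test_that("halving the target edge length halves the mean edge length within 20%", {
  mean_edge <- function(res) {
    m <- make_abutment(abutment_spec(mesh_resolution = res))$mesh
    e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
    mean(sqrt(rowSums((m$vertices[e[, 1], ] - m$vertices[e[, 2], ])^2)))
  }
  r <- mean_edge(0.2) / mean_edge(0.4)
  expect_gt(r, 0.4)
  expect_lt(r, 0.6)
})

test_that("too-coarse resolution and invalid crown parameters are rejected", {
  expect_error(abutment_spec(mesh_resolution = 0.6), "too coarse")
  expect_error(abutment_spec(top_radius = 5), "top_radius")
  expect_error(crown_spec(radial_shrinkage = 0.06), "radial_shrinkage")
  expect_error(crown_spec(spacer = -1), "spacer")
  # shrinkage collapsing the intaglio below the abutment by > spacer
  ab <- test_abutment(0.3)
  expect_error(make_crown(ab, crown_spec(spacer = 10,
                                         radial_shrinkage = 0.04)),
               "generation error")
})

test_that("the spacer is recovered by the gap field across a spacer grid", {
  ab <- test_abutment(0.2)
  for (sp in c(20, 40, 80)) {
    cr <- make_crown(ab, crown_spec(spacer = sp))
    s <- poisson_disk_sample(cr$intaglio, radius = 0.25, seed = 16)
    g <- gap_distances(cr$intaglio, ab$mesh, s)
    zone <- s$positions[, 3] >= cr$truth$spacer_zone_height
    expect_equal(mean(g$distances[zone]), sp, tolerance = 0.02)
  }
})

test_that("margin extension error is recovered by the Hausdorff metric", {
  ab <- test_abutment(0.3)
  for (e in c(0.1, 0.2, 0.4)) {
    cr <- make_crown(ab, crown_spec(margin_extension_error = e))
    h <- hausdorff_margin(ab$margin, cr$margin)
    expect_equal(h$hausdorff, 1000 * e, tolerance = 0.02)
  }
})

test_that("occlusal doming raises the occlusal-region gap by its magnitude", {
  ab <- test_abutment(0.2)
  cr <- make_crown(ab, crown_spec(spacer = 40, occlusal_doming = 150))
  s <- poisson_disk_sample(cr$intaglio, radius = 0.25, seed = 17)
  g <- gap_distances(cr$intaglio, ab$mesh, s)
  reg <- cr$region[s$face]
  occ <- mean(g$distances[reg == "occlusal"])
  axial_zone <- reg == "axial" &
    s$positions[, 3] >= cr$truth$spacer_zone_height
  expect_equal(occ - mean(g$distances[axial_zone]), 150, tolerance = 0.05)
})

test_that("increasing doming strictly increases the measured mean gap", {
  ab <- test_abutment(0.3)
  means <- vapply(c(0, 60, 120, 180), function(d) {
    cr <- make_crown(ab, crown_spec(spacer = 40, occlusal_doming = d))
    s <- poisson_disk_sample(cr$intaglio, radius = 0.3, seed = 18)
    gap_distances(cr$intaglio, ab$mesh, s)$mean
  }, 1.0)
  expect_true(all(diff(means) > 0))
})

test_that("crown meshes satisfy the container invariants and noise follows the seed", {
  ab <- test_abutment(0.3)
  c1 <- make_crown(ab, crown_spec(noise_sd = 10, seed = 77))
  c2 <- make_crown(ab, crown_spec(noise_sd = 10, seed = 77))
  c3 <- make_crown(ab, crown_spec(noise_sd = 10, seed = 78))
  expect_identical(c1$intaglio$vertices, c2$intaglio$vertices)
  expect_false(identical(c1$intaglio$vertices, c3$intaglio$vertices))
  expect_silent(validate_trimesh(c1$intaglio))
})

test_that("cohort generation is byte-identical under a fixed master seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  dist1 <- crown_spec_distribution(occlusal_doming = c(150, 20),
                                   label = "a")
  dist2 <- crown_spec_distribution(occlusal_doming = c(100, 15),
                                   label = "b")
  for (d in c(d1, d2))
    make_cohorts(dist1, dist2, n_per_group = 2, master_seed = 31,
                 abutment = abutment_spec(mesh_resolution = 0.35),
                 out_dir = d)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_true(length(f1) >= 13)
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             n = file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             n = file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("drawn cohort parameters respect truncation bounds", {
  co <- make_cohorts(
    crown_spec_distribution(occlusal_doming = c(30, 40), label = "a"),
    crown_spec_distribution(radial_shrinkage = c(0, 0.001), label = "b"),
    n_per_group = 5, master_seed = 8,
    abutment = abutment_spec(mesh_resolution = 0.35))
  expect_true(all(co$params$occlusal_doming_um >= 0))
  expect_true(all(abs(co$params$radial_shrinkage) < 0.003 + 1e-12))
  expect_equal(nrow(co$params), 10L)
})
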