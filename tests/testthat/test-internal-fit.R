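# Poisson-disk sampling and the internal gap-distance field.

test_that("Poisson-disk sampling honours the spacing guarantee and packing bounds", {
  sq <- grid_mesh(10, 10)
  for (seed in c(1, 7, 99)) {
    s <- poisson_disk_sample(sq, radius = 0.1, seed = seed)
    n <- nrow(s$positions)
    dmin <- min(dist(s$positions))
    expect_gte(dmin, 0.1)
    # area / (pi r^2) lower-ish bound and hexagonal-packing upper bound
    expect_gte(n, 30)
    expect_lte(n, 100)
  }
})

test_that("a radius larger than the surface admits exactly one sample", {
  sq <- grid_mesh(4, 4)
  s <- poisson_disk_sample(sq, radius = 2, seed = 3)
  expect_equal(nrow(s$positions), 1L)
})

test_that("sampling is reproducible for a fixed seed and all samples lie on the mesh", {
  ab <- test_abutment(0.4)
  s1 <- poisson_disk_sample(ab$mesh, radius = 0.3, seed = 42)
  s2 <- poisson_disk_sample(ab$mesh, radius = 0.3, seed = 42)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$face, s2$face)
  rec <- surface_point_position(ab$mesh, s1$face, s1$barycentric)
  expect_lt(max(abs(rec - s1$positions)), 1e-9)
  expect_true(all(s1$barycentric >= 0) &&
                max(abs(rowSums(s1$barycentric) - 1)) < 1e-12)
})

test_that("samples cover the surface within twice the disk radius", {
  ab <- test_abutment(0.4)
  s <- poisson_disk_sample(ab$mesh, radius = 0.2, seed = 5)
  nn <- crownfit:::cpp_knn(ab$mesh$vertices, s$positions, 1L)
  expect_lt(max(nn$distance), 2 * 0.2)
})

test_that("parallel planes 40 um apart give a constant 40 um gap field", {
  abut <- grid_mesh(12, 12, c(-0.2, 1.2), c(-0.2, 1.2), z = 0)
  intag <- grid_mesh(10, 10, c(0, 1), c(0, 1), z = 0.04)
  s <- poisson_disk_sample(intag, radius = 0.08, seed = 8)
  g <- gap_distances(intag, abut, s)
  expect_equal(g$mean, 40, tolerance = 1e-9)
  expect_lt(g$sd, 1e-9)
  expect_true(all(g$signs == 1))
  expect_equal(sum(g$histogram$counts), nrow(s$positions))
})

test_that("concentric spheres recover the 40 um radial gap within 2%", {
  inner <- cached("sph_in", function() uv_sphere(5.00, 40))
  outer <- cached("sph_out", function() uv_sphere(5.04, 40))
  s <- poisson_disk_sample(outer, radius = 0.25, seed = 9)
  g <- gap_distances(outer, inner, s)
  expect_equal(g$mean, 40, tolerance = 0.02)
  expect_true(all(g$signs == 1))
})

test_that("an intaglio coincident with the abutment measures zero gap", {
  ab <- test_abutment(0.4)
  s <- poisson_disk_sample(ab$mesh, radius = 0.3, seed = 10)
  g <- gap_distances(ab$mesh, ab$mesh, s)
  expect_lt(max(abs(g$distances)), 1e-9)
})

test_that("interpenetration is signed negative", {
  abut <- grid_mesh(12, 12, c(-0.2, 1.2), c(-0.2, 1.2), z = 0)
  below <- grid_mesh(10, 10, c(0, 1), c(0, 1), z = -0.02)
  s <- poisson_disk_sample(below, radius = 0.1, seed = 11)
  g <- gap_distances(below, abut, s)
  expect_true(all(g$signs == -1))
  expect_equal(g$mean, -20, tolerance = 1e-9)
})

test_that("inconsistent winding is rejected before signing", {
  abut <- grid_mesh(4, 4)
  f <- abut$faces
  f[1, ] <- f[1, c(1, 3, 2)]
  bad <- trimesh(abut$vertices, f)
  intag <- grid_mesh(4, 4, z = 0.04)
  s <- poisson_disk_sample(intag, radius = 0.2, seed = 12)
  expect_error(gap_distances(intag, bad, s), "winding")
})

test_that("gap distances are invariant under a joint rigid transform", {
  set.seed(23)
  abut <- grid_mesh(12, 12, c(-0.2, 1.2), c(-0.2, 1.2), z = 0)
  intag <- grid_mesh(8, 8, z = 0.04)
  s <- poisson_disk_sample(intag, radius = 0.1, seed = 13)
  g0 <- gap_distances(intag, abut, s)
  tr <- random_rigid()
  s2 <- s
  s2$positions <- apply_transform(s$positions, tr)
  g1 <- gap_distances(apply_transform(intag, tr), apply_transform(abut, tr),
                      s2)
  expect_equal(g1$distances, g0$distances, tolerance = 1e-9)
})

test_that("edge-graph geodesic distances dominate nearest-surface distances", {
  ab <- test_abutment(0.4)
  cr <- make_crown(ab, crown_spec(spacer = 40))
  s <- poisson_disk_sample(cr$intaglio, radius = 0.35, seed = 14)
  gn <- gap_distances(cr$intaglio, ab$mesh, s, mode = "nearest_surface")
  gg <- gap_distances(cr$intaglio, ab$mesh, s, mode = "edge_graph_geodesic")
  expect_true(all(gg$distances >= abs(gn$distances) - 1e-9))
})

test_that("gap map rendering writes a colour PLY and a conserving histogram", {
  ab <- test_abutment(0.4)
  cr <- make_crown(ab, crown_spec(spacer = 40, occlusal_doming = 150))
  s <- poisson_disk_sample(cr$intaglio, radius = 0.3, seed = 15)
  g <- gap_distances(cr$intaglio, ab$mesh, s)
  path <- withr::local_tempfile(fileext = ".ply")
  scal <- render_gap_map(cr$intaglio, g, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".hist.txt")))
  hist_tab <- read.table(paste0(path, ".hist.txt"))
  expect_equal(sum(hist_tab[, 3]), length(g$distances))
  # the doming maximum localizes on occlusal-table vertices
  occ_verts <- unique(as.vector(
    cr$intaglio$faces[cr$region == "occlusal", ]))
  expect_true(which.max(scal) %in% occ_verts)
  # uniform field renders a single colour
  gu <- g
  gu$distances <- rep(40, length(g$distances))
  p2 <- withr::local_tempfile(fileext = ".ply")
  render_gap_map(cr$intaglio, gu, p2)
  lines <- readLines(p2)
  vstart <- match("end_header", lines) + 1L
  nv <- nrow(cr$intaglio$vertices)
  cols <- unique(vapply(strsplit(lines[vstart:(vstart + nv - 1L)], " "),
                        function(x) paste(x[4:6], collapse = ","), ""))
  expect_equal(length(cols), 1L)
})
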