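# Mesh container, STL/PLY codecs and core geometric queries.

test_that("ASCII STL of a single triangle parses to 3 vertices / 1 face", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t",
               "  facet normal 0 0 1",
               "    outer loop",
               "      vertex 0 0 0",
               "      vertex 1 0 0",
               "      vertex 0 1 0",
               "    endloop",
               "  endfacet",
               "endsolid t"), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_equal(sort(m$vertices[, 1]), c(0, 0, 1))
})

test_that("binary and ASCII STL round-trips preserve structure within 1e-6 mm", {
  ab <- test_abutment(0.4)
  for (bin in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_mesh(ab$mesh, path, binary = bin)
    m <- read_mesh(path)
    expect_equal(nrow(m$vertices), nrow(ab$mesh$vertices))
    expect_equal(nrow(m$faces), nrow(ab$mesh$faces))
    # vertex sets match within float32 quantisation (well below 1e-6 of
    # the ~10 mm coordinate scale for binary; exact text for ASCII)
    nn <- crownfit:::cpp_knn(m$vertices, ab$mesh$vertices, 1L)
    expect_lt(max(nn$distance), 1e-5)
  }
})

test_that("coincident duplicated triangles are merged to shared vertices", {
  # two facets over identical coordinates: the STL soup has 6 vertices,
  # the cleaned mesh 3 vertices and 2 faces (brute-force dedup oracle)
  path <- withr::local_tempfile(fileext = ".stl")
  tri <- c("  facet normal 0 0 1", "    outer loop",
           "      vertex 0 0 0", "      vertex 1 0 0", "      vertex 0 1 0",
           "    endloop", "  endfacet")
  writeLines(c("solid t", tri, tri, "endsolid t"), path)
  m <- read_mesh(path)
  key <- unique(paste(round(m$vertices[, 1], 9), round(m$vertices[, 2], 9),
                      round(m$vertices[, 3], 9)))
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(length(key), 3L)
  expect_equal(nrow(m$faces), 2L)
})

test_that("malformed STL files raise format errors locating the problem", {
  p1 <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0", "    endloop", "  endfacet",
               "endsolid x"), p1)
  expect_error(read_mesh(p1), "format error.*line", ignore.case = TRUE)
  p2 <- withr::local_tempfile(fileext = ".stl")
  con <- file(p2, "wb")
  writeBin(raw(80), con)
  writeBin(1000L, con, size = 4, endian = "little")  # declares 1000 facets
  writeBin(raw(50), con)                             # but holds one
  close(con)
  expect_error(read_mesh(p2), "byte offset|bytes")
  expect_error(read_mesh(withr::local_tempfile(fileext = ".stl")),
               "not found")
})

test_that("PLY export carries vertex colors and round-trips geometry", {
  ab <- test_abutment(0.4)
  path <- withr::local_tempfile(fileext = ".ply")
  z <- ab$mesh$vertices[, 3]
  write_mesh(ab$mesh, path, format = "ply", vertex_scalars = z)
  m <- read_mesh(path, format = "ply")
  expect_equal(nrow(m$faces), nrow(ab$mesh$faces))
  # constant scalars give a single color
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(ab$mesh, p2, format = "ply",
             vertex_scalars = rep(0, nrow(ab$mesh$vertices)))
  lines <- readLines(p2)
  vstart <- match("end_header", lines) + 1L
  cols <- unique(vapply(strsplit(
    lines[vstart:(vstart + 50)], " "), function(x)
      paste(x[4:6], collapse = ","), ""))
  expect_equal(length(cols), 1L)
})

test_that("deviation colormap is monotone: red-blue difference follows value", {
  z <- sort(runif(100, -200, 200))
  rgb <- deviation_colormap(z, limit = 250)
  expect_true(all(diff(rgb[, "red"] - rgb[, "blue"]) >= 0))
  expect_true(all(rgb >= 0 & rgb <= 255))
})

test_that("point_to_surface_distance matches analytic single-triangle cases", {
  tri <- unit_triangle()
  r <- point_to_surface_distance(c(0, 0, 1), tri)
  expect_equal(r$distance, 1)
  r2 <- point_to_surface_distance(c(2, 0, 0), tri)
  expect_equal(r2$distance, 1)
  expect_equal(r2$closest[1, ], c(1, 0, 0))
  expect_equal(r2$barycentric[1, ], c(0, 1, 0))
})

test_that("point_to_surface_distance equals the brute-force oracle on random instances", {
  set.seed(42)
  mesh <- random_soup(n_faces = 50, seed = 7)
  pts <- matrix(runif(300, -3, 3), ncol = 3)
  fast <- point_to_surface_distance(pts, mesh)$distance
  slow <- vapply(seq_len(nrow(pts)), function(i)
    point_mesh_dist_bf(pts[i, ], mesh), 1.0)
  expect_lt(max(abs(fast - slow)), 1e-9)
  # barycentric reconstruction reproduces the closest point
  r <- point_to_surface_distance(pts, mesh)
  rec <- surface_point_position(mesh, r$face, r$barycentric)
  expect_lt(max(abs(rec - r$closest)), 1e-9)
})

test_that("every mesh vertex is at distance zero from its own mesh", {
  ab <- test_abutment(0.4)
  idx <- seq(1, nrow(ab$mesh$vertices), by = 37)
  d <- point_to_surface_distance(ab$mesh$vertices[idx, , drop = FALSE],
                                 ab$mesh)$distance
  expect_lt(max(d), 1e-12)
})

test_that("vertex adjacency graph has one weighted edge per unique face edge", {
  tri <- unit_triangle()
  g <- vertex_adjacency_graph(tri)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(sort(igraph::E(g)$weight), sort(c(1, 1, sqrt(2))))
  two <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                 rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_equal(igraph::ecount(vertex_adjacency_graph(two)), 5L)
  # closed 2-manifold: E = 3F/2 and Euler characteristic 2
  sph <- uv_sphere(2, 12)
  gs <- vertex_adjacency_graph(sph)
  expect_true(is_closed_manifold(sph))
  expect_equal(igraph::ecount(gs), 3L * nrow(sph$faces) / 2L)
  expect_equal(nrow(sph$vertices) - igraph::ecount(gs) + nrow(sph$faces), 2L)
})

test_that("degenerate and invalid meshes are rejected", {
  expect_error(trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                       rbind(c(1, 2, 3))), "degenerate")
  expect_error(trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 4))), "out of range")
  expect_error(trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 2))), "repeats")
})
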