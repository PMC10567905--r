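# Kabsch alignment, trimmed ICP and rigid-transform plumbing.

test_that("kabsch recovers exact correspondences and synthesized transforms", {
  set.seed(10)
  pts <- matrix(runif(60, -3, 3), ncol = 3)
  id <- kabsch_align(pts, pts)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(id$translation)), 1e-12)
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  target <- sweep(pts %*% t(R), 2, c(1, 2, 3), "+")
  tr <- kabsch_align(pts, target)
  expect_lt(max(abs(tr$rotation - R)), 1e-9)
  expect_lt(max(abs(tr$translation - c(1, 2, 3))), 1e-9)
})

test_that("kabsch residual RMS on noisy correspondences is of the noise scale", {
  set.seed(11)
  sigma <- 0.01
  pts <- matrix(runif(150, -4, 4), ncol = 3)
  tr <- random_rigid()
  target <- apply_transform(pts, tr) + matrix(rnorm(150, 0, sigma), ncol = 3)
  est <- kabsch_align(pts, target)
  rms <- sqrt(mean(rowSums((apply_transform(pts, est) - target)^2)) / 3)
  expect_gt(rms, sigma / 2)
  expect_lt(rms, 2 * sigma)
  # independent oracle: direct SVD of the cross-covariance
  cs <- colMeans(pts); ct <- colMeans(target)
  H <- crossprod(sweep(pts, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  Ro <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  expect_lt(max(abs(est$rotation - Ro)), 1e-9)
})

test_that("collinear correspondences raise a rank error", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_align(line, line + 1), "collinear|degenerate")
})

test_that("rigid transforms preserve lengths and invert exactly", {
  set.seed(12)
  tr <- random_rigid()
  curve <- circle_curve(4.2, 50)
  moved <- apply_transform(curve, tr)
  expect_equal(moved$arc_length, curve$arc_length, tolerance = 1e-12)
  back <- apply_transform(moved, invert_transform(tr))
  expect_lt(max(abs(back$points - curve$points)), 1e-9)
  # reflections are rejected
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("transform text serialization round-trips at full precision", {
  set.seed(13)
  tr <- random_rigid()
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, path)
  tr2 <- read_transform(path)
  expect_equal(tr2$rotation, tr$rotation, tolerance = 1e-15)
  expect_equal(tr2$translation, tr$translation, tolerance = 1e-15)
})

test_that("ICP on an identical copy converges immediately to near-zero RMS", {
  ab <- test_abutment(0.4)
  reg <- trimmed_icp(ab$mesh, ab$mesh, inlier_threshold = 1)
  expect_lt(reg$inlier_rms, 1e-12)
  expect_true(reg$converged)
  expect_lte(reg$iterations, 2L)
  expect_equal(reg$inlier_fraction, 1)
})

test_that("ICP recovers a small translation of the frustum within 1e-4 mm", {
  ab <- test_abutment(0.4)
  shift <- c(0.2, 0, 0)
  src <- apply_transform(ab$mesh, rigid_transform(diag(3), shift))
  reg <- trimmed_icp(src, ab$mesh, inlier_threshold = 1.0, tol = 1e-10,
                     max_iter = 150, max_source_points = 1000)
  expect_lt(max(abs(reg$transform$translation + shift)), 1e-4)
  expect_lt(max(abs(reg$transform$rotation - diag(3))), 1e-4)
})

test_that("ICP inlier RMS trace is non-increasing and runs are deterministic", {
  ab <- test_abutment(0.4)
  src <- apply_transform(ab$mesh, rigid_transform(diag(3), c(0.1, -0.15, 0.1)))
  reg1 <- trimmed_icp(src, ab$mesh, inlier_threshold = 1.0,
                      max_source_points = 800)
  expect_true(all(diff(reg1$rms_trace) <= 1e-12))
  reg2 <- trimmed_icp(src, ab$mesh, inlier_threshold = 1.0,
                      max_source_points = 800)
  expect_identical(reg1$transform$rotation, reg2$transform$rotation)
  expect_identical(reg1$inlier_rms, reg2$inlier_rms)
})

test_that("principal-axes init plus ICP aligns a rotated asymmetric surface exactly", {
  sph <- uv_sphere(5, 16)
  ell <- sph
  ell$vertices <- sweep(sph$vertices, 2, c(1, 0.7, 0.45), "*")
  set.seed(14)
  tr <- random_rigid(max_angle_deg = 15, max_trans = 1)
  src <- apply_transform(ell, tr)
  reg <- trimmed_icp(src, ell, init = principal_axes_init(src, ell),
                     inlier_threshold = 1.0, tol = 1e-12)
  expect_lt(reg$inlier_rms, 1e-6)
})

test_that("zero inliers raise an alignment failure", {
  ab <- test_abutment(0.4)
  far <- apply_transform(ab$mesh, rigid_transform(diag(3), c(50, 0, 0)))
  expect_error(trimmed_icp(far, ab$mesh, inlier_threshold = 0.5),
               "zero inliers")
})
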