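# Core geometry containers and the two fit metrics.

test_that("mesh3 and contour2 enforce their invariants", {
  expect_error(mesh3(matrix(1, 3, 3), matrix(1L, 1, 3)), "4 vertices")
  expect_error(mesh3(matrix(c(1, NA, rep(1, 10)), 4, 3), rbind(c(1, 2, 3))),
               "finite")
  expect_error(mesh3(diag(4)[, 1:3] * 5, rbind(c(1, 2, 9))), "out of range")

  # duplicate removal + CCW normalization
  p <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  ct <- contour2(p)
  expect_equal(nrow(ct$points), 4)
  expect_gt(tkrsize:::polygon_signed_area(ct$points), 0)
  cw <- contour2(p[c(5, 4, 3, 1), ])
  expect_gt(tkrsize:::polygon_signed_area(cw$points), 0)
  expect_error(contour2(rbind(c(0, 0), c(1, 1))), "3 distinct")
})

test_that("rigid transforms compose, invert and validate", {
  R <- rot3(c(0, 0, 1), 0.4) %*% rot3(c(1, 0, 0), -0.2)
  tf <- rigid3(R, c(1, -2, 3))
  inv <- invert_rigid3(tf)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_rigid3(inv, apply_rigid3(tf, P)), P, tolerance = 1e-12)
  id <- compose_rigid3(inv, tf)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_error(rigid3(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  # theta normalization into (-pi, pi]
  expect_equal(rigid2(3 * pi)$theta, pi)
})

test_that("rmse_points_to_surface matches analytic cases", {
  cube <- unit_cube_mesh()
  # samples exactly on the surface
  on_surf <- rbind(c(0.5, 0.5, 0), c(1, 0.3, 0.7), c(0.2, 1, 0.1))
  expect_equal(rmse_points_to_surface(on_surf, cube), 0, tolerance = 1e-12)
  # single point above the top face
  expect_equal(rmse_points_to_surface(rbind(c(0.5, 0.5, 1.5)), cube), 0.5,
               tolerance = 1e-12)
  expect_error(rmse_points_to_surface(matrix(0, 0, 3), cube), "no sample")
})

test_that("degenerate faces are skipped, all-degenerate errors", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  m_ok <- mesh3(V, rbind(c(1, 2, 3), c(1, 2, 4)))  # first face zero-area
  expect_equal(rmse_points_to_surface(rbind(c(0, 0, 1)), m_ok), 1,
               tolerance = 1e-12)
  m_bad <- mesh3(V, rbind(c(1, 2, 3)))
  expect_error(rmse_points_to_surface(rbind(c(0, 0, 1)), m_bad), "degenerate")
})

test_that("directed Hausdorff matches analytic cases and is asymmetric", {
  c30 <- circle_contour(30)
  c33 <- circle_contour(33)
  expect_equal(directed_hausdorff(c30, c30), 0, tolerance = 1e-9)
  expect_equal(directed_hausdorff(c33, c30), 3, tolerance = 0.01)
  # asymmetric pair: a circle vs the same circle plus a distant spur
  spur <- contour2(rbind(circle_contour(30)$points, c(45, 0)), closed = FALSE)
  base <- contour2(circle_contour(30)$points, closed = FALSE)
  h_ab <- directed_hausdorff(spur, base)
  h_ba <- directed_hausdorff(base, spur)
  expect_gt(h_ab, 10)
  expect_lt(h_ba, 1)
  expect_error(directed_hausdorff(matrix(1, 2, 2), matrix(1, 2, 3)), "mixed")
})

test_that("metrics agree with exhaustive brute-force oracles", {
  set.seed(7)
  mesh <- random_convex_mesh(seed = 7)
  P <- matrix(rnorm(60 * 3, sd = 8), 60, 3)
  expect_equal(rmse_points_to_surface(P, mesh), oracle_rmse_points_mesh(P, mesh),
               tolerance = 1e-9)
  A <- matrix(rnorm(150 * 2, sd = 10), 150, 2)
  B <- matrix(rnorm(150 * 2, sd = 10), 150, 2)
  expect_equal(directed_hausdorff(A, B), oracle_directed_hausdorff(A, B),
               tolerance = 1e-12)
})

test_that("contour densification respects the spacing bound", {
  sq <- contour2(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  d <- densify_contour(sq, 0.2)
  steps <- sqrt(rowSums((rbind(d[-1, ], d[1, ]) - d)^2))
  expect_lte(max(steps), 0.2 + 1e-12)
  expect_equal(nrow(d), 200)
})

test_that("mirroring flips ML and preserves outward normals", {
  m <- generate_bone("femur", 68, 58)
  mm <- mirror_mesh(m)
  expect_equal(mm$vertices[, 1], -m$vertices[, 1])
  # outward test: normals point away from the centroid on average
  vn <- mesh_vertex_normals(mm)
  ctr <- colMeans(mm$vertices)
  outward <- rowSums(vn * sweep(mm$vertices, 2, ctr))
  expect_gt(mean(outward > 0), 0.95)
})
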