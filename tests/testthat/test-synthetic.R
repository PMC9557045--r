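# Synthetic bone generator, silhouette projection and cohort sampling.

test_that("generated bones hit requested dimensions exactly at zero noise", {
  for (bone in c("femur", "tibia")) {
    m <- generate_bone(bone, 68, 58)
    ext <- mesh_extents(m)
    expect_equal(as.numeric(ext[c("ML", "AP")]), c(68, 58), tolerance = 0.1)
    # also under shape deformation
    m2 <- generate_bone(bone, 61.5, 47.2, shape_coeffs = c(1.5, -1, 0.7, 0.4))
    ext2 <- mesh_extents(m2)
    expect_equal(as.numeric(ext2[c("ML", "AP")]), c(61.5, 47.2),
                 tolerance = 0.1)
  }
  expect_error(generate_bone("femur", 30, 58), "within")
})

test_that("generation is deterministic in the seed", {
  a <- generate_bone("femur", 66, 57, c(1, 0, 0, 0), noise_sd = 0.8, seed = 9)
  b <- generate_bone("femur", 66, 57, c(1, 0, 0, 0), noise_sd = 0.8, seed = 9)
  c <- generate_bone("femur", 66, 57, c(1, 0, 0, 0), noise_sd = 0.8, seed = 10)
  expect_identical(a$vertices, b$vertices)
  expect_false(identical(a$vertices, c$vertices))
})

test_that("mean noise displacement follows the half-normal mean", {
  m0 <- generate_bone("tibia", 70, 46, noise_sd = 0)
  m1 <- generate_bone("tibia", 70, 46, noise_sd = 1, seed = 3)
  disp <- sqrt(rowSums((m1$vertices - m0$vertices)^2))
  expect_equal(mean(disp), sqrt(2 / pi), tolerance = 0.08)
})

test_that("deformation basis is orthonormal with unit RMS displacement", {
  m <- generate_bone("femur", 66, 60)
  U <- tkrsize:::deformation_basis(m$vertices)
  G <- crossprod(U)
  expect_equal(G / nrow(m$vertices), diag(4) * (G[1, 1] / nrow(m$vertices)),
               tolerance = 1e-9)
  rms1 <- sqrt(mean(rowSums(matrix(U[, 1], ncol = 3, byrow = TRUE)^2)))
  expect_equal(rms1, 1, tolerance = 1e-9)
})

test_that("silhouette area matches analytic and is resolution-consistent", {
  sph <- random_convex_mesh(seed = 1)  # roughly a sphere of radius 10-13
  # use an analytic cylinder seen along its axis instead: disc area
  cyl <- cylinder_mesh(r = 20, h = 30, n = 240)
  mk <- project_silhouette(cyl, "AP", spacing = 0.5)
  # AP view of an upright cylinder is a rectangle 2r x h
  expect_equal(sum(mk$pixels) * 0.5^2, 40 * 30, tolerance = 40 * 30 * 0.02)
  m <- generate_bone("femur", 66, 58)
  a1 <- sum(project_silhouette(m, "AP", 0.5)$pixels) * 0.25
  a2 <- sum(project_silhouette(m, "AP", 0.25)$pixels) * 0.0625
  expect_equal(a1, a2, tolerance = a2 * 0.01)
  expect_error(project_silhouette(m, "AP", spacing = 2), "spacing")
})

test_that("mask -> contour round trip preserves extents", {
  m <- generate_bone("tibia", 64, 44)
  for (view in c("AP", "lateral")) {
    mk <- project_silhouette(m, view, 0.5)
    ct <- mask_to_contour(mk)
    rng <- apply(ct$points, 2, range)
    want <- if (view == "AP") mesh_extents(m)[c("ML", "Z")]
            else mesh_extents(m)[c("AP", "Z")]
    expect_equal(as.numeric(rng[2, ] - rng[1, ]), as.numeric(want),
                 tolerance = 1)
  }
})

test_that("cohorts are reproducible and dimension marginals are honest", {
  p1 <- generate_population(3, seed = 5)
  p2 <- generate_population(3, seed = 5)
  expect_identical(p1[[2]]$femur_mesh$vertices, p2[[2]]$femur_mesh$vertices)
  expect_identical(p1[[3]]$masks$tibia_AP$pixels, p2[[3]]$masks$tibia_AP$pixels)
  expect_length(p1[[1]]$masks, 4)
  expect_s3_class(p1[[1]]$masks$femur_AP, "mask_image")
  # extents of each mesh match stored true dims
  expect_equal(as.numeric(mesh_extents(p1[[1]]$femur_mesh)["ML"]),
               p1[[1]]$true_ML_femur, tolerance = 1)

  big <- generate_population(400, seed = 6, masks = FALSE)
  ml <- vapply(big, `[[`, 0, "true_ML_femur")
  sex <- vapply(big, `[[`, "", "sex")
  expect_equal(mean(ml[sex == "F"]), 62, tolerance = 1)
  expect_equal(mean(ml[sex == "M"]), 70, tolerance = 1)
  ages <- vapply(big, `[[`, 0, "age")
  expect_true(all(ages >= 46 & ages <= 79))
})
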