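# Mask-to-contour extraction, bi-planar alignment, depth models, SSM fit.

test_that("filled square mask traces to a square contour in mm", {
  px <- matrix(FALSE, 120, 120)
  px[11:110, 11:110] <- TRUE
  mk <- mask_image(px, spacing = 0.5)
  ct <- mask_to_contour(mk)
  rng <- apply(ct$points, 2, range)
  expect_equal(as.numeric(rng[2, ] - rng[1, ]), c(50, 50), tolerance = 0.01)
  expect_equal(polygon_area(ct), 2500, tolerance = 2500 * 0.02)
})

test_that("contour area matches the pixel-count oracle within 2%", {
  m <- generate_bone("femur", 66, 58)
  mk <- project_silhouette(m, "AP", 0.5)
  ct <- mask_to_contour(mk)
  expect_equal(polygon_area(ct), sum(mk$pixels) * 0.25,
               tolerance = sum(mk$pixels) * 0.25 * 0.02)
})

test_that("degenerate masks are rejected", {
  expect_error(mask_to_contour(mask_image(matrix(FALSE, 10, 10), 0.5)),
               "empty mask")
  px <- matrix(FALSE, 20, 20)
  px[2:4, 2:4] <- TRUE
  px[10:12, 10:12] <- TRUE  # two equal components
  expect_error(mask_to_contour(mask_image(px, 0.5)), "equal-size")
})

test_that("grayscale fallback segments a synthetic projection", {
  m <- generate_bone("tibia", 66, 44)
  mk <- project_silhouette(m, "AP", 0.5)
  gray <- ifelse(mk$pixels, 0.75, 0.2) +
    matrix(stats::runif(length(mk$pixels), -0.1, 0.1), nrow(mk$pixels))
  mk2 <- mask_from_grayscale(gray, 0.5)
  expect_gt(mean(mk2$pixels == mk$pixels), 0.98)
})

test_that("bi-planar alignment registers datum and extents", {
  rect <- function(w) contour2(rbind(c(0, 0), c(w, 0), c(w, 80), c(0, 80)))
  al <- align_contours_3d(rect(40), rect(30), bone = "femur")
  expect_equal(min(al$ap$points[, 2]), min(al$lat$points[, 2]))
  expect_equal(diff(range(al$ap$points[, 2])),
               diff(range(al$lat$points[, 2])))
  expect_equal(mean(range(al$ap$points[, 1])), 0)
  # projections of one synthetic bone share the datum
  m <- generate_bone("femur", 66, 58)
  ap <- mask_to_contour(project_silhouette(m, "AP", 0.5))
  lat <- mask_to_contour(project_silhouette(m, "lateral", 0.5))
  al2 <- align_contours_3d(ap, lat, bone = "femur")
  expect_lt(abs(min(al2$ap$points[, 2]) - min(al2$lat$points[, 2])), 0.5)
  # inconsistent vertical extents are rejected
  tall <- contour2(rbind(c(0, 0), c(40, 0), c(40, 160), c(0, 160)))
  expect_error(align_contours_3d(tall, rect(40), bone = "femur"),
               "inconsistent")
})

test_that("depth model application scales with contour size", {
  train <- lapply(1:6, function(i)
    generate_bone("femur", 66, 58, shape_coeffs = stats::rnorm(4, 0, 0.5),
                  seed = i))
  pdm <- build_pdm(train, "AP", "femur")
  ct <- mask_to_contour(project_silhouette(train[[1]], "AP", 0.5))
  # express the contour in the mesh frame (mask origins are arbitrary)
  V2 <- train[[1]]$vertices[, c(1, 3)]
  for (k in 1:2) {
    ct$points[, k] <- ct$points[, k] - mean(range(ct$points[, k])) +
      mean(range(V2[, k]))
  }
  p1 <- apply_pdm(ct, pdm)
  # scaling the contour by 1.2 scales the depths by 1.2
  big <- ct
  big$points <- big$points * 1.2
  p2 <- apply_pdm(big, pdm)
  expect_equal(p2$points[, 2], p1$points[, 2] * 1.2, tolerance = 1e-9)
  # training-set round trip: depths near the true silhouette generators
  d <- closest_point_mesh(p1, train[[1]])$dist
  expect_lt(sqrt(mean(d^2)), 1.5)
})

test_that("SSM fit of mean-shape samples returns near-zero coefficients", {
  set.seed(42)
  bones <- lapply(1:12, function(i)
    generate_bone("femur", 66, 58, shape_coeffs = stats::rnorm(4, 0, c(1.2, 0.9, 0.7, 0.5)),
                  seed = i))
  clouds <- establish_correspondence(bones, bones[[1]])
  ssm <- build_ssm(clouds, faces = bones[[1]]$faces, bone = "femur")
  refs <- pcloud3(ssm$mean_shape[seq(1, nrow(ssm$mean_shape), by = 2), ])
  fit <- fit_ssm(refs, ssm)
  b <- attr(fit, "coefficients")
  expect_lt(abs(b[1]), 1e-3 * sqrt(ssm$eigenvalues[1]) + 1e-6)
  expect_lt(rmse_points_to_surface(refs, fit), 0.05)
  # objective trace non-increasing
  expect_true(all(diff(attr(fit, "trace")) <= 1e-8))
})

test_that("SSM fit recovers a known first-mode coefficient", {
  set.seed(43)
  bones <- lapply(1:25, function(i)
    generate_bone("femur", 66, 58, shape_coeffs = stats::rnorm(4, 0, c(1.2, 0.9, 0.7, 0.5)),
                  seed = 100 + i))
  clouds <- establish_correspondence(bones, bones[[1]])
  ssm <- build_ssm(clouds, faces = bones[[1]]$faces, bone = "femur")
  amp <- 2 * sqrt(ssm$eigenvalues[1])
  shape <- ssm$mean_shape + matrix(ssm$modes[, 1] * amp, ncol = 3, byrow = TRUE)
  fit <- fit_ssm(pcloud3(shape), ssm)
  expect_equal(abs(attr(fit, "coefficients")[1]), amp, tolerance = amp * 0.05)
})
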