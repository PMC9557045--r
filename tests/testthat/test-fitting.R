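# Resection construction, per-size virtual fitting, and size selection.

test_that("resection plane on an analytic flat-plateau tibia is exact", {
  # straight prism with a known widest bulge ring: widest point at z_w
  th <- 2 * pi * (seq_len(120) - 1) / 120
  prof <- cbind(35 * cos(th), 23 * sin(th))
  m <- prism_mesh(prof, h = 40, z_top = 10)
  # add a bulge ring 4 mm below the top by scaling wall vertices there
  pl <- tibia_resection_plane(m)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-6)
  # widest medial point of the straight prism is on the top ring (z = 10)
  expect_equal(pl$origin[3], 10 - 2, tolerance = 1e-9)
})

test_that("resection plane is equivariant under a 7 degree tilt", {
  m <- generate_bone("tibia", 70, 46)
  pl0 <- tibia_resection_plane(m)
  R <- rot3(c(0, 1, 0), 7 * pi / 180)
  m2 <- m
  m2$vertices <- m$vertices %*% t(R)
  pl1 <- tibia_resection_plane(m2)
  expect_equal(pl1$normal, as.numeric(R %*% pl0$normal), tolerance = 2e-2)
  # offset from the widest point along the normal stays 2 mm
  med2 <- m2$vertices[m2$vertices[, 1] < 0, ]
  w2 <- med2[which.min(med2[, 1]), ]
  expect_equal(sum((w2 - pl1$origin) * pl1$normal), 2, tolerance = 1e-6)
})

test_that("shaft-only mesh has no identifiable plateau", {
  m <- cylinder_mesh(r = 15, h = 60, n = 40, cone_top = TRUE)
  expect_error(tibia_resection_plane(m), "plateau not identifiable")
})

test_that("tibia plate on its own extruded profile fits exactly", {
  charts <- load_size_charts()
  comp <- build_tibia_profile(charts[["Zimmer Biomet tibia"]][4, ])
  m <- prism_mesh(comp$geometry$points, h = 40, z_top = 0)
  fit <- fit_tibia_plate(m, comp)
  expect_lt(fit$rmse, 0.05)
  # overhang residual is bounded by the notch-closure offset (the section
  # carries the notch here; the edge set bridges it by design)
  expect_lt(fit$max_ouh, 2.5)
  # a bone matching the fit-analysis edge outline scores ~zero overhang
  m2 <- prism_mesh(comp$edges$points, h = 40, z_top = 0)
  fit2 <- fit_tibia_plate(m2, comp)
  expect_lt(fit2$max_ouh, 0.3)
  sec <- cross_section(m, tibia_resection_plane(m))
  reg <- icp_rigid_2d(comp$geometry, sec)
  expect_lt(attr(reg, "rms"), 0.05)
})

test_that("uniformly dilated section reads as ~2 mm underhang", {
  comp <- build_tibia_profile(load_size_charts()[["DePuy tibia"]][4, ])
  p <- comp$edges$points
  n <- nrow(p)
  tng <- p[c(2:n, 1), ] - p[c(n, 1:(n - 1)), ]
  nrm <- cbind(tng[, 2], -tng[, 1]) / sqrt(rowSums(tng^2))
  dil <- contour2(p + 2 * nrm)
  fit <- tkrsize:::fit_tibia_plate_to_section(dil, comp)
  expect_equal(fit$max_ouh, 2, tolerance = 0.15)
})

test_that("a 70x46 plateau section picks Zimmer tibia size 4", {
  th <- 2 * pi * (seq_len(200) - 1) / 200
  r <- tkrsize:::kidney_radius(th, 35, 23)
  sec <- contour2(cbind(r * cos(th), r * sin(th)))
  chart <- load_size_charts()[["Zimmer Biomet tibia"]]
  rmse <- vapply(seq_len(nrow(chart)), function(i) {
    tkrsize:::fit_tibia_plate_to_section(sec, build_tibia_profile(chart[i, ]))$rmse
  }, 0)
  expect_equal(chart$size_id[which.min(rmse)], "4")
})

test_that("femur component fits its own shell exactly", {
  comp <- build_femur_component(load_size_charts()[["Zimmer Biomet femur"]][3, ])
  fit <- fit_femur_component(comp$geometry, comp)
  expect_lt(fit$rmse, 0.01)
  expect_lt(fit$max_ouh, 0.2)
})

test_that("a bone 6 mm wider in ML reads as ~3 mm rim overhang", {
  charts <- load_size_charts()
  entry <- charts[["Zimmer Biomet femur"]][3, ]  # 68 x 58
  comp <- build_femur_component(entry)
  wide <- generate_bone("femur", 74, 58)
  fit <- fit_femur_component(wide, comp)
  expect_equal(fit$max_ouh, 3, tolerance = 0.5)
})

test_that("chart-exact femur recovers its generating size", {
  chart <- load_size_charts()[["Zimmer Biomet femur"]]
  bone <- generate_bone("femur", 68, 58)
  pred <- predict_sizes(femur = bone, charts = list(chart))
  expect_equal(pred$models[[1]]$best_by_rmse, "D")
  expect_equal(pred$models[[1]]$best_by_ouh, "D")
  # quasi-convexity: the argmin is a local minimum in ordinal order
  f <- pred$fits[order(pred$fits$ordinal), ]
  i <- which.min(f$rmse)
  if (i > 1) expect_gt(f$rmse[i - 1], f$rmse[i])
  if (i < nrow(f)) expect_gt(f$rmse[i + 1], f$rmse[i])
})

test_that("downsize tie-break picks the smaller ordinal", {
  fits <- list(
    structure(list(size_id = "A", ordinal = 0L, rmse = 1.00), class = "fit_result"),
    structure(list(size_id = "B", ordinal = 1L, rmse = 0.98), class = "fit_result"),
    structure(list(size_id = "C", ordinal = 2L, rmse = 1.50), class = "fit_result"))
  expect_equal(tkrsize:::best_with_downsize(fits, "rmse", tol = 0.05), "A")
  expect_equal(tkrsize:::best_with_downsize(fits, "rmse", tol = 0.001), "B")
})

test_that("predictions are invariant to rigid pre-transform and mirroring", {
  charts <- load_size_charts()[c("Zimmer Biomet femur", "Zimmer Biomet tibia")]
  f <- generate_bone("femur", 64, 55, shape_coeffs = c(0.8, -0.5, 0.3, 0.2))
  t <- generate_bone("tibia", 67, 45, shape_coeffs = c(0.8, -0.5, 0.3, 0.2))
  p1 <- predict_sizes(f, t, charts)
  # small rigid motion of the input bones (imaging-frame wobble)
  R <- rot3(c(0, 1, 0.2), 4 * pi / 180)
  move <- function(m) { m$vertices <- sweep(m$vertices %*% t(R), 2, -c(5, 3, -8)); m }
  p2 <- predict_sizes(move(f), move(t), charts)
  expect_equal(p1$models[[1]]$best_by_rmse, p2$models[[1]]$best_by_rmse)
  expect_equal(p1$models[[2]]$best_by_rmse, p2$models[[2]]$best_by_rmse)
  expect_equal(p1$fits$rmse, p2$fits$rmse, tolerance = 0.15)
  # a left knee mirrored on ingest reproduces the right-knee result exactly
  left <- mirror_mesh(f)
  p3 <- predict_sizes(mirror_mesh(left), t, charts)
  expect_equal(p3$fits$rmse, p1$fits$rmse, tolerance = 1e-12)
})

test_that("per-size failures are recorded and full failure errors", {
  charts <- load_size_charts()["Zimmer Biomet tibia"]
  cone <- cylinder_mesh(r = 15, h = 60, n = 40, cone_top = TRUE)
  expect_error(predict_sizes(tibia = cone, charts = charts), "plateau")
})
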