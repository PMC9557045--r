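# Generic implant templates scaled to chart sizes.

test_that("femur components reproduce chart dimensions and the Z rule", {
  charts <- load_size_charts()
  entry <- charts[["Zimmer Biomet femur"]][3, ]  # ML 68 / AP 58
  comp <- build_femur_component(entry)
  ext <- mesh_extents(comp$geometry)
  expect_equal(as.numeric(ext["ML"]), 68, tolerance = 0.05)
  expect_equal(as.numeric(ext["AP"]), 58, tolerance = 0.05)
  expect_gte(nrow(comp$surface_samples), 2000)
  # native-dimension entry reproduces the template unchanged
  tpl <- tkrsize:::femur_template_cached()
  native <- entry
  native$ML <- tkrsize:::FEMUR_TEMPLATE_DIMS[["ML"]]
  native$AP <- tkrsize:::FEMUR_TEMPLATE_DIMS[["AP"]]
  comp0 <- build_femur_component(native)
  expect_equal(comp0$geometry$vertices, tpl$mesh$vertices, tolerance = 1e-12)
  # Z extent scales by the mean of the X and Y scale factors
  sx <- 68 / tkrsize:::FEMUR_TEMPLATE_DIMS[["ML"]]
  sy <- 58 / tkrsize:::FEMUR_TEMPLATE_DIMS[["AP"]]
  z_tpl <- diff(range(tpl$mesh$vertices[, 3]))
  expect_equal(as.numeric(ext["Z"]), z_tpl * (sx + sy) / 2, tolerance = 1e-9)
  expect_error(build_femur_component(charts[["DePuy tibia"]][1, ]),
               "not a femur")
})

test_that("femur surface samples lie on the component surface", {
  comp <- build_femur_component(load_size_charts()[["DePuy femur"]][2, ])
  d <- closest_point_mesh(comp$surface_samples, comp$geometry)$dist
  expect_lt(max(d), 1e-9)
})

test_that("tibia profiles reproduce chart dimensions and the area law", {
  charts <- load_size_charts()
  entry <- charts[["Stryker tibia"]][3, ]  # ML 66 / AP 44
  prof <- build_tibia_profile(entry)
  rng <- apply(prof$geometry$points, 2, range)
  expect_equal(as.numeric(rng[2, ] - rng[1, ]), c(66, 44), tolerance = 0.05)
  # affine area law
  e2 <- entry; e2$ML <- 2 * entry$ML; e2$AP <- 1.5 * entry$AP
  p2 <- build_tibia_profile(e2)
  expect_equal(polygon_area(p2$geometry), 3 * polygon_area(prof$geometry),
               tolerance = 1e-9)
  # native dims give the unchanged template
  e0 <- entry
  e0$ML <- tkrsize:::TIBIA_TEMPLATE_DIMS[["ML"]]
  e0$AP <- tkrsize:::TIBIA_TEMPLATE_DIMS[["AP"]]
  p0 <- build_tibia_profile(e0)
  expect_equal(p0$geometry$points,
               contour2(tkrsize:::tibia_template_cached()$profile)$points,
               tolerance = 1e-12)
  expect_error(build_tibia_profile(charts[["DePuy femur"]][1, ]), "not a tibia")
})

test_that("tibia edge contour closes the posterior notch smoothly", {
  prof <- build_tibia_profile(load_size_charts()[["Zimmer Biomet tibia"]][4, ])
  # the edge contour never dips inside the notch: its posterior extent
  # matches the un-notched envelope and it has no notch indentation
  h_notch <- directed_hausdorff(prof$geometry, prof$edges)
  expect_gt(h_notch, 1)  # real notch depth present in the geometry
  # edges stay within the profile's bounding box
  rg <- apply(prof$geometry$points, 2, range)
  re <- apply(prof$edges$points, 2, range)
  expect_lt(max(abs(re - rg)), 0.6)
})

test_that("all 73 chart entries rebuild to their dimensions within 0.05 mm", {
  charts <- load_size_charts()
  for (ch in charts) {
    for (i in seq_len(nrow(ch))) {
      entry <- ch[i, ]
      if (entry$component == "femur") {
        ext <- mesh_extents(build_femur_component(entry)$geometry)
        expect_equal(as.numeric(ext[c("ML", "AP")]), c(entry$ML, entry$AP),
                     tolerance = 0.05)
      } else {
        rng <- apply(build_tibia_profile(entry)$geometry$points, 2, range)
        expect_equal(as.numeric(rng[2, ] - rng[1, ]), c(entry$ML, entry$AP),
                     tolerance = 0.05)
      }
    }
  }
})
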