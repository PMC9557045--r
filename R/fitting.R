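# Virtual implant fitting: tibial resection construction, per-size fits of
# both components, metric evaluation and best-size selection.

#' Tibial resection plane
#'
#' Locates the flat proximal-tibia resection: parallel to the medial
#' plateau surface (least-squares plane through upward-facing vertices on
#' the medial half) and 2 mm below the widest point of the medial condyle
#' (the most medial vertex), measured along the plateau normal.
#'
#' @param tibia a `mesh3` in the canonical right-knee frame (medial = -X).
#' @param offset resection depth below the widest medial point (mm).
#' @param min_plateau_vertices minimum number of upward-facing medial
#'   vertices required to identify the plateau.
#' @return A `plane3` (normal pointing proximally).
#' @export
tibia_resection_plane <- function(tibia, offset = 2,
                                  min_plateau_vertices = 50L) {
  stopifnot(inherits(tibia, "mesh3"))
  vn <- mesh_vertex_normals(tibia)
  V <- tibia$vertices
  # medial = negative-X half, measured from the bounding-box centre so the
  # rule tolerates a translated imaging frame
  x_c <- V[, 1] - mean(range(V[, 1]))
  medial <- x_c < 0
  plateau <- medial & vn[, 3] > 0.8
  if (sum(plateau) < min_plateau_vertices) stop("plateau not identifiable")
  P <- V[plateau, , drop = FALSE]
  # restrict to the medial plateau facet (clear of the intercondylar
  # eminence near the midline) when enough vertices remain
  halfwidth <- diff(range(V[, 1])) / 2
  facet <- x_c[plateau] < -0.35 * halfwidth
  if (sum(facet) >= min_plateau_vertices / 2) P <- P[facet, , drop = FALSE]
  fit_plane <- function(Q) {
    ctr <- colMeans(Q)
    ev <- eigen(stats::cov(Q), symmetric = TRUE)
    n <- ev$vectors[, 3]
    if (n[3] < 0) n <- -n
    list(ctr = ctr, n = n)
  }
  pf <- fit_plane(P)
  # one guarded trim pass against gross outliers
  res <- abs(as.numeric(sweep(P, 2, pf$ctr) %*% pf$n))
  keep <- res < 1.5
  if (sum(keep) >= min_plateau_vertices / 2)
    pf <- fit_plane(P[keep, , drop = FALSE])
  n <- pf$n
  widest <- V[medial, , drop = FALSE]
  wpt <- widest[which.min(widest[, 1]), ]
  plane3(wpt - offset * n, n)
}

# Fit one tibia plate to a precomputed resection section: 3-DOF in-plane
# ICP of the plate profile onto the section, then the global RMSE (profile
# points to section polyline) and the maximum-OUH directed Hausdorff
# distance (plate edge contour to section boundary).
fit_tibia_plate_to_section <- function(section, component, spacing = 0.2) {
  reg <- icp_rigid_2d(component$geometry, section, corr_spacing = 1)
  center <- attr(reg, "center")
  prof_t <- apply_rigid2(reg, component$geometry, center = center)
  edges_t <- apply_rigid2(reg, component$edges, center = center)
  rmse <- rmse_points_to_contour(densify_contour(prof_t, 0.5), section)
  ouh <- directed_hausdorff(edges_t, section, spacing = spacing)
  list(transform = reg, rmse = rmse, max_ouh = ouh)
}

#' Fit a tibia plate to a tibia
#'
#' Cuts the bone at the tibial resection plane and registers the plate's
#' 2D profile onto the section with in-plane ICP (rotation about the
#' plate's central axis only; no flexion/extension). Returns the global
#' RMSE (profile to section) and the maximum over/underhang (directed
#' Hausdorff from the plate's fit-analysis edges to the section boundary).
#'
#' @param tibia a `mesh3`.
#' @param component a tibia `implant_component` from [build_tibia_profile()].
#' @return A `fit_result`: list with `manufacturer`, `model`, `size_id`,
#'   `transform`, `rmse`, `max_ouh`.
#' @export
fit_tibia_plate <- function(tibia, component) {
  stopifnot(identical(component$component, "tibia"))
  section <- cross_section(tibia, tibia_resection_plane(tibia))
  res <- fit_tibia_plate_to_section(section, component)
  fit_result(component, res)
}

fit_result <- function(component, res) {
  structure(list(manufacturer = component$size$manufacturer,
                 model = component$size$model,
                 component = component$component,
                 size_id = component$size$size_id,
                 ordinal = component$size$ordinal,
                 transform = res$transform,
                 rmse = res$rmse, max_ouh = res$max_ouh),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s %s '%s' (%s) rmse %.3f mm, max OUH %.3f mm\n",
              x$manufacturer, x$model, x$size_id, x$component, x$rmse,
              x$max_ouh))
  invisible(x)
}

#' Fit a femur component to a femur
#'
#' Registers the component's outer-surface samples onto the bone with
#' unconstrained 6-DOF ICP, initialized by translating the component onto
#' the centroid of the distal femur with axes aligned. The global RMSE is
#' the closest-point RMSE of all surface samples to the bone; the maximum
#' over/underhang is the directed Hausdorff distance from the component's
#' peripheral rim to the bone's boundary at the rim's resection level (the
#' bone cross-section in the rim plane), both expressed in that plane.
#'
#' @param femur a `mesh3`.
#' @param component a femur `implant_component` from
#'   [build_femur_component()].
#' @param icp_samples number of surface samples used for ICP
#'   correspondences (the full sample set is always used for the RMSE).
#' @param max_iter,tol ICP controls.
#' @return A `fit_result`.
#' @export
fit_femur_component <- function(femur, component, icp_samples = 200L,
                                max_iter = 25L, tol = 1e-4) {
  stopifnot(identical(component$component, "femur"))
  S <- component$surface_samples
  idx <- unique(as.integer(round(seq(1, nrow(S), length.out = icp_samples))))
  # init: distal-femur centroid, axes aligned
  V <- femur$vertices
  zmid <- mean(range(V[, 3]))
  distal <- V[V[, 3] <= zmid, , drop = FALSE]
  t0 <- colMeans(distal) - colMeans(S)
  init <- rigid3(diag(3), t0)
  tf <- icp_rigid_3d(S[idx, , drop = FALSE], femur, init = init,
                     max_iter = max_iter, tol = tol)
  rmse <- rmse_points_to_surface(apply_rigid3(tf, S), femur)

  # overhang at the rim's resection level
  rim_t <- apply_rigid3(tf, component$rim)
  n <- as.numeric(tf$rotation %*% c(0, 0, 1))
  origin <- colMeans(rim_t)
  pl <- plane3(origin, n)
  section <- cross_section(femur, pl)
  # express the rim in the same in-plane basis as the section
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * pl$normal) * pl$normal
  if (sqrt(sum(ex^2)) < 1e-6)
    ex <- c(0, 1, 0) - sum(c(0, 1, 0) * pl$normal) * pl$normal
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(pl$normal[2] * ex[3] - pl$normal[3] * ex[2],
          pl$normal[3] * ex[1] - pl$normal[1] * ex[3],
          pl$normal[1] * ex[2] - pl$normal[2] * ex[1])
  rim_c <- sweep(rim_t, 2, pl$origin)
  rim2 <- contour2(cbind(rim_c %*% ex, rim_c %*% ey))
  ouh <- directed_hausdorff(rim2, section)
  fit_result(component, list(transform = tf, rmse = rmse, max_ouh = ouh))
}

best_with_downsize <- function(fits, metric, tol) {
  vals <- vapply(fits, `[[`, 0, metric)
  ords <- vapply(fits, `[[`, 0L, "ordinal")
  o <- order(ords)
  vals <- vals[o]
  ok <- which(vals < min(vals) + tol)
  fits[[o[ok[1]]]]$size_id
}

#' Predict the best implant sizes for a knee
#'
#' Systematically fits every size of every supplied chart to the femur and
#' tibia, records both fit metrics for each, and selects per chart and
#' metric the size with the lowest error. When two sizes differ by less
#' than `downsize_tiebreak_tol` the smaller (lower-ordinal) size is chosen,
#' mirroring the surgical preference to downsize on a marginal call.
#'
#' @param femur,tibia `mesh3` bone surfaces (either may be `NULL` to skip
#'   that component).
#' @param charts list of `size_chart`s (default: packaged charts).
#' @param downsize_tiebreak_tol metric difference (mm) below which the
#'   smaller size wins (default 0.05).
#' @param verbose log per-size metrics to stderr.
#' @return A `size_prediction`: per chart, `best_by_rmse` and `best_by_ouh`
#'   size ids plus `all_fits`, also flattened into the data frame `fits`.
#' @export
predict_sizes <- function(femur = NULL, tibia = NULL,
                          charts = load_size_charts(),
                          downsize_tiebreak_tol = 0.05, verbose = FALSE) {
  tib_section <- NULL
  if (!is.null(tibia)) {
    tib_section <- cross_section(tibia, tibia_resection_plane(tibia))
  }
  out <- list()
  for (ch in charts) {
    comp <- ch$component[1]
    if (comp == "femur" && is.null(femur)) next
    if (comp == "tibia" && is.null(tibia)) next
    fits <- list()
    errs <- character(0)
    for (i in seq_len(nrow(ch))) {
      entry <- ch[i, , drop = FALSE]
      f <- tryCatch({
        if (comp == "femur") {
          fit_femur_component(femur, build_femur_component(entry))
        } else {
          fit_result(build_tibia_profile(entry),
                     fit_tibia_plate_to_section(tib_section,
                                                build_tibia_profile(entry)))
        }
      }, error = function(e) e)
      if (inherits(f, "error")) {
        errs <- c(errs, sprintf("%s '%s': %s", ch$manufacturer[1],
                                entry$size_id, conditionMessage(f)))
      } else {
        if (verbose)
          message(sprintf("  %s %s '%s': rmse %.3f, ouh %.3f",
                          ch$manufacturer[1], comp, entry$size_id, f$rmse,
                          f$max_ouh))
        fits[[length(fits) + 1L]] <- f
      }
    }
    if (!length(fits))
      stop("all sizes failed for chart ", ch$manufacturer[1], " ", comp,
           ": ", paste(errs, collapse = "; "))
    out[[paste(ch$manufacturer[1], comp)]] <- list(
      manufacturer = ch$manufacturer[1], model = ch$model[1],
      component = comp,
      best_by_rmse = best_with_downsize(fits, "rmse", downsize_tiebreak_tol),
      best_by_ouh = best_with_downsize(fits, "max_ouh", downsize_tiebreak_tol),
      all_fits = fits, errors = errs)
  }
  if (!length(out)) stop("no applicable charts")
  fits_df <- do.call(rbind, lapply(out, function(m)
    data.frame(manufacturer = m$manufacturer, model = m$model,
               component = m$component,
               size_id = vapply(m$all_fits, `[[`, "", "size_id"),
               ordinal = vapply(m$all_fits, `[[`, 0L, "ordinal"),
               rmse = vapply(m$all_fits, `[[`, 0, "rmse"),
               max_ouh = vapply(m$all_fits, `[[`, 0, "max_ouh"))))
  rownames(fits_df) <- NULL
  structure(list(models = out, fits = fits_df,
                 downsize_tiebreak_tol = downsize_tiebreak_tol),
            class = "size_prediction")
}

#' @export
print.size_prediction <- function(x, ...) {
  cat("Implant size prediction\n")
  for (m in x$models) {
    cat(sprintf("  %-18s %-8s %-6s best rmse: '%s'  best max-OUH: '%s'\n",
                m$manufacturer, m$model, m$component, m$best_by_rmse,
                m$best_by_ouh))
  }
  invisible(x)
}

#' @export
summary.size_prediction <- function(object, ...) {
  df <- object$fits
  best <- do.call(rbind, lapply(object$models, function(m)
    data.frame(manufacturer = m$manufacturer, model = m$model,
               component = m$component, best_by_rmse = m$best_by_rmse,
               best_by_ouh = m$best_by_ouh)))
  rownames(best) <- NULL
  structure(list(best = best, fits = df), class = "summary.size_prediction")
}

#' @export
print.summary.size_prediction <- function(x, ...) {
  cat("Best sizes per model and metric:\n")
  print(x$best, row.names = FALSE)
  cat("\nPer-size fit metrics (mm):\n")
  print(x$fits, row.names = FALSE, digits = 4)
  invisible(x)
}
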