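# Synthetic bone generator: parametric distal femora and proximal tibiae
# with controllable ML/AP dimensions, a fixed 4-mode smooth deformation
# basis, Gaussian surface noise, and orthographic silhouette projection.
# Stands in for the clinical MRI-derived ground truth so the whole pipeline
# runs offline.

# Evaluate a function with a private RNG state (restores .Random.seed).
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Fixed smooth 4-mode deformation basis for a vertex set: four scalar
# fields (axial bulge, two axial skews, ML-AP coupling) displacing vertices
# radially, orthonormalized and scaled to 1 mm RMS displacement per unit
# coefficient. Deterministic for a given vertex grid.
deformation_basis <- function(V) {
  rng <- apply(V, 2, range)
  ctr <- colMeans(rng)
  hw <- pmax((rng[2, ] - rng[1, ]) / 2, 1e-9)
  Q <- sweep(sweep(V, 2, ctr), 2, hw, "/")
  P <- sweep(V, 2, ctr)
  len <- sqrt(rowSums(P^2))
  len[len < 1e-9] <- 1
  rhat <- P / len
  g <- cbind(sin(pi / 2 * Q[, 3]),
             Q[, 1] * Q[, 3],
             Q[, 2] * Q[, 3],
             Q[, 1] * Q[, 2])
  n <- nrow(V)
  U <- matrix(0, 3 * n, 4)
  for (k in 1:4) U[, k] <- as.numeric(t(rhat * g[, k]))
  # Gram-Schmidt, then scale columns to RMS 1 mm per-vertex displacement
  for (k in 1:4) {
    if (k > 1) for (j in 1:(k - 1))
      U[, k] <- U[, k] - sum(U[, k] * U[, j]) / sum(U[, j]^2) * U[, j]
    U[, k] <- U[, k] / sqrt(mean(rowSums(matrix(U[, k], ncol = 3,
                                                byrow = TRUE)^2)))
  }
  U
}

#' Generate a synthetic bone surface
#'
#' Builds a parametric distal femur (ellipsoidal condyles, trochlear/
#' intercondylar groove, shaft stub) or proximal tibia (extruded kidney
#' plateau tapering to a shaft) in the canonical right-knee frame, scaled so
#' the medial-lateral (X) and anterior-posterior (Y) extents equal `ML` and
#' `AP` exactly, deformed by a fixed 4-mode smooth basis weighted by
#' `shape_coeffs` (mm RMS per unit), with optional Gaussian vertex noise
#' along outward normals. Fully deterministic given the arguments and
#' `seed`.
#'
#' @param bone `"femur"` or `"tibia"`.
#' @param ML,AP target extents in mm; both must lie in `[35, 100]`
#'   (covering the packaged size-chart range).
#' @param shape_coeffs numeric vector (up to 4) of deformation-mode weights.
#' @param noise_sd standard deviation (mm) of surface noise along normals.
#' @param seed integer seed for the noise draw.
#' @param n_theta,n_phi mesh resolution (azimuthal and polar/vertical).
#' @return A `mesh3`, bounding-box centred at the origin.
#' @export
generate_bone <- function(bone = c("femur", "tibia"), ML, AP,
                          shape_coeffs = numeric(0), noise_sd = 0,
                          seed = 1L, n_theta = 36L, n_phi = 18L) {
  bone <- match.arg(bone)
  if (ML < 35 || ML > 100 || AP < 35 || AP > 100)
    stop("ML and AP must be within [35, 100] mm")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  s_mean <- (ML / 66 + AP / 60) / 2
  mesh <- if (bone == "femur") {
    canonical_femur_mesh(ML / 2, AP / 2, 31 * s_mean,
                         n_theta = n_theta, n_phi = n_phi)
  } else {
    canonical_tibia_mesh(ML / 2, AP / 2, depth = 52 * s_mean,
                         n_theta = n_theta, n_z = n_phi - 7L)
  }
  if (length(shape_coeffs) > 0) {
    if (length(shape_coeffs) > 4L) stop("at most 4 shape coefficients")
    U <- deformation_basis(mesh$vertices)
    disp <- U[, seq_along(shape_coeffs), drop = FALSE] %*% shape_coeffs
    mesh$vertices <- mesh$vertices +
      matrix(disp, ncol = 3, byrow = TRUE)
  }
  mesh$vertices <- rescale_to_dims(mesh$vertices, ML, AP, scale_z = TRUE)
  if (noise_sd > 0) {
    vn <- mesh_vertex_normals(mesh)
    d <- with_local_seed(seed, smooth_noise_field(mesh$vertices, noise_sd))
    mesh$vertices <- mesh$vertices + vn * d
  }
  mesh
}

# Smooth correlated surface noise: a sum of random plane-wave harmonics
# (wavelengths ~20-40 mm), scaled to standard deviation `sd`. Marginally
# close to N(0, sd^2) per vertex but spatially smooth, emulating
# segmentation error on a smooth anatomical surface rather than white
# per-vertex jitter.
smooth_noise_field <- function(V, sd, n_waves = 8L) {
  f <- numeric(nrow(V))
  for (j in seq_len(n_waves)) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    lambda <- stats::runif(1, 20, 40)
    phase <- stats::runif(1, 0, 2 * pi)
    f <- f + cos(as.numeric(V %*% dir) * (2 * pi / lambda) + phase)
  }
  f * sd / sqrt(n_waves / 2)
}

#' Orthographic silhouette of a mesh
#'
#' Projects a mesh along +Y (AP view: image axes X, Z) or +X (lateral view:
#' image axes Y, Z) and rasterizes the filled triangle projections into a
#' binary mask at the requested pixel spacing.
#'
#' @param mesh a `mesh3`.
#' @param view `"AP"` or `"lateral"`.
#' @param spacing pixel spacing in mm/px, in `(0.1, 1]`.
#' @param bone,side metadata tags carried on the mask.
#' @param margin empty border (mm) around the silhouette.
#' @return A `mask_image` whose pixel `[i, j]` covers image coordinates
#'   `((i - 0.5) * spacing, (j - 0.5) * spacing)` mm from the mask origin.
#' @export
project_silhouette <- function(mesh, view = c("AP", "lateral"), spacing = 0.5,
                               bone = "femur", side = "right", margin = 3) {
  view <- match.arg(view)
  if (spacing <= 0.1 || spacing > 1) stop("spacing must be in (0.1, 1] mm/px")
  V2 <- if (view == "AP") mesh$vertices[, c(1, 3)] else mesh$vertices[, c(2, 3)]
  umin <- min(V2[, 1]) - margin
  vmin <- min(V2[, 2]) - margin
  nx <- ceiling((max(V2[, 1]) + margin - umin) / spacing)
  ny <- ceiling((max(V2[, 2]) + margin - vmin) / spacing)
  img <- cpp_rasterize_silhouette(V2, mesh$faces - 1L, umin, vmin, spacing,
                                  as.integer(nx), as.integer(ny))
  if (!any(img > 0)) stop("empty projection")
  mask_image(img > 0, spacing = spacing, view = view, bone = bone, side = side)
}

#' Generate a synthetic test cohort
#'
#' Draws subjects with sex-conditional bone dimensions (normal
#' distributions spanning the union of the packaged size-chart ranges),
#' ages uniform on 46-79, random side, per-subject shape-mode coefficients
#' and surface noise, and renders the four silhouette masks (AP + lateral
#' for femur and tibia). Deterministic per seed.
#'
#' @param n number of subjects.
#' @param config list overriding defaults: `femur_ML_mean` (named F/M),
#'   `tibia_ML_mean` (named F/M), `ML_sd`, `femur_AP_ratio`,
#'   `tibia_AP_ratio`, `AP_resid_sd`, `mode_sd` (length 4), `noise_sd`,
#'   `spacing`.
#' @param seed integer seed.
#' @param masks render silhouette masks (set `FALSE` to skip for speed).
#' @return List of `synthetic_subject` objects: each has `subject_id`,
#'   `sex`, `age`, `side`, `femur_mesh`, `tibia_mesh`, true dimensions, the
#'   four masks (if rendered) and the per-subject `seed`.
#' @export
generate_population <- function(n, config = list(), seed = 1L, masks = TRUE) {
  stopifnot(n >= 1)
  cfg <- utils::modifyList(list(
    femur_ML_mean = c(F = 62, M = 70), tibia_ML_mean = c(F = 66, M = 74),
    ML_sd = 3.2, femur_AP_ratio = 0.88, tibia_AP_ratio = 0.655,
    AP_resid_sd = 1.0, mode_sd = c(1.2, 0.9, 0.7, 0.5), noise_sd = 0.3,
    spacing = 0.5), config)
  draws <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      sex <- sample(c("F", "M"), 1)
      fML <- stats::rnorm(1, cfg$femur_ML_mean[[sex]], cfg$ML_sd)
      tML <- stats::rnorm(1, cfg$tibia_ML_mean[[sex]], cfg$ML_sd)
      list(sex = sex,
           age = round(stats::runif(1, 46, 79)),
           side = sample(c("left", "right"), 1),
           fML = min(95, max(45, fML)),
           fAP = min(95, max(45, cfg$femur_AP_ratio * fML +
                               stats::rnorm(1, 0, cfg$AP_resid_sd))),
           tML = min(95, max(45, tML)),
           tAP = min(95, max(40, cfg$tibia_AP_ratio * tML +
                               stats::rnorm(1, 0, cfg$AP_resid_sd))),
           coeffs = stats::rnorm(4, 0, cfg$mode_sd),
           sub_seed = sample.int(2^30, 1))
    })
  })
  lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    femur <- generate_bone("femur", d$fML, d$fAP, d$coeffs,
                           noise_sd = cfg$noise_sd, seed = d$sub_seed)
    tibia <- generate_bone("tibia", d$tML, d$tAP, d$coeffs,
                           noise_sd = cfg$noise_sd, seed = d$sub_seed + 1L)
    msk <- NULL
    if (masks) {
      msk <- list(
        femur_AP = project_silhouette(femur, "AP", cfg$spacing, "femur", d$side),
        femur_lat = project_silhouette(femur, "lateral", cfg$spacing, "femur", d$side),
        tibia_AP = project_silhouette(tibia, "AP", cfg$spacing, "tibia", d$side),
        tibia_lat = project_silhouette(tibia, "lateral", cfg$spacing, "tibia", d$side))
    }
    structure(list(
      subject_id = sprintf("S%03d", i), sex = d$sex, age = d$age,
      side = d$side, femur_mesh = femur, tibia_mesh = tibia,
      true_ML_femur = d$fML, true_AP_femur = d$fAP,
      true_ML_tibia = d$tML, true_AP_tibia = d$tAP,
      masks = msk, seed = d$sub_seed), class = "synthetic_subject")
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("synthetic_subject %s: %s, age %d, %s knee\n", x$subject_id,
              x$sex, x$age, x$side))
  cat(sprintf("  femur ML/AP %.1f/%.1f mm, tibia ML/AP %.1f/%.1f mm\n",
              x$true_ML_femur, x$true_AP_femur, x$true_ML_tibia,
              x$true_AP_tibia))
  invisible(x)
}
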