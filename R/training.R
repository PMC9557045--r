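# Shape-model training: dense correspondence by template projection,
# statistical shape models (generalized Procrustes + PCA) and per-view
# point depth models.

#' Establish dense correspondence across bone meshes
#'
#' Aligns a template mesh to each target (uniform scale from centroid size,
#' then rigid ICP) and projects every template vertex to its closest point
#' on the target surface, yielding point clouds with identical vertex count
#' and ordering across the set.
#'
#' @param meshes list of `mesh3` (at least 3).
#' @param template a `mesh3` whose vertex layout defines the
#'   correspondence.
#' @return List of n x 3 matrices (template vertex order); meshes whose
#'   alignment fails are skipped with a warning.
#' @export
establish_correspondence <- function(meshes, template) {
  if (length(meshes) < 3L) stop("need at least 3 meshes")
  TV <- template$vertices
  csize <- function(P) sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))
  out <- list()
  for (i in seq_along(meshes)) {
    cl <- tryCatch({
      m <- meshes[[i]]
      s <- csize(m$vertices) / csize(TV)
      V <- TV * s
      init <- rigid3(diag(3), colMeans(m$vertices) - colMeans(V))
      tf <- icp_rigid_3d(V, m, init = init, max_iter = 15L, tol = 1e-4)
      cp <- closest_point_mesh(apply_rigid3(tf, V), m)
      cp$closest
    }, error = function(e) {
      warning("skipping mesh ", i, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(cl)) out[[length(out) + 1L]] <- cl
  }
  if (length(out) < 3L) stop("fewer than 3 meshes aligned successfully")
  out
}

procrustes_similarity <- function(X, Yref) {
  cx <- colMeans(X); cy <- colMeans(Yref)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Yref, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  s <- sum(sv$d * c(1, 1, d)) / sum(Xc^2)
  sweep(s * Xc %*% t(R), 2, -cy)
}

#' Build a statistical shape model from correspondent point clouds
#'
#' Generalized Procrustes alignment (similarity: rotation, translation,
#' uniform scale) followed by PCA of the centred shape vectors. Shapes stay
#' in mm (aligned to the evolving mean), so mode coefficients carry mm
#' units.
#'
#' @param clouds list of n x 3 matrices with identical point counts.
#' @param n_modes number of modes to retain (default all, i.e. n - 1).
#' @param faces optional triangulation shared by all clouds (carried for
#'   surface evaluation of fitted instances).
#' @param bone tag, `"femur"` or `"tibia"`.
#' @return A `knee_ssm`: `mean_shape` (V x 3), `modes` (3V x M, orthonormal
#'   columns, vertex-major xyz stacking), `eigenvalues` (non-increasing),
#'   `faces`, `bone`, `n_train`.
#' @export
build_ssm <- function(clouds, n_modes = NULL, faces = NULL, bone = "femur") {
  if (length(clouds) < 3L) stop("need at least 3 clouds")
  np <- vapply(clouds, nrow, 0L)
  if (length(unique(np)) != 1L) stop("clouds have unequal point counts")
  # generalized Procrustes: iterate similarity alignment to the evolving
  # mean until it stabilizes (scale pinned to the average centroid size so
  # the result does not depend on input order)
  csize <- function(P) sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))
  size0 <- mean(vapply(clouds, csize, 0))
  mean_shape <- clouds[[1]]
  for (iter in 1:50) {
    aligned <- lapply(clouds, procrustes_similarity, Yref = mean_shape)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    if (csize(new_mean) < 1e-12) break  # no common shape signal
    new_mean <- new_mean * (size0 / csize(new_mean))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < 1e-9) break
  }
  aligned <- lapply(clouds, procrustes_similarity, Yref = mean_shape)
  X <- do.call(rbind, lapply(aligned, function(p) as.numeric(t(p))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  n <- nrow(X)
  maxm <- min(n - 1L, ncol(sv$v))
  M <- if (is.null(n_modes)) maxm else min(n_modes, maxm)
  structure(list(
    mean_shape = matrix(mu, ncol = 3, byrow = TRUE),
    modes = sv$v[, seq_len(M), drop = FALSE],
    eigenvalues = (sv$d[seq_len(M)]^2) / (n - 1),
    total_variance = sum(sv$d^2) / (n - 1),
    faces = faces, bone = bone, n_train = n), class = "knee_ssm")
}

#' @export
print.knee_ssm <- function(x, ...) {
  cat(sprintf("knee_ssm (%s): %d landmarks, %d training shapes, %d modes\n",
              x$bone, nrow(x$mean_shape), x$n_train, ncol(x$modes)))
  if (x$total_variance > 0) {
    cum <- cumsum(x$eigenvalues) / x$total_variance
    cat("  cumulative variance:",
        paste(sprintf("%.1f%%", 100 * utils::head(cum, 5)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Build a per-view point depth model
#'
#' For each training mesh: take its orthographic silhouette contour for the
#' view, resample to `P` arc-length-uniform points from the anatomical
#' start, and record each contour point's out-of-plane coordinate (that of
#' the mesh vertex projecting closest to it, i.e. the silhouette-generator
#' point). The model is the pointwise mean depth profile plus PCA modes of
#' the residuals, with the training-mean vertical extent for size scaling.
#'
#' @param meshes list of `mesh3` in the canonical frame (at least 3).
#' @param view `"AP"` or `"lateral"`.
#' @param bone `"femur"` or `"tibia"`.
#' @param P contour resampling count (default 200).
#' @param spacing silhouette rasterization spacing (mm/px).
#' @return A `depth_model`: `view`, `bone`, `P`, `mean_depth` (length P),
#'   `depth_modes` (P x K), `depth_variances`, `train_mean_zext`.
#' @export
build_pdm <- function(meshes, view = c("AP", "lateral"),
                      bone = c("femur", "tibia"), P = 200L, spacing = 0.5) {
  view <- match.arg(view)
  bone <- match.arg(bone)
  if (length(meshes) < 3L) stop("need at least 3 meshes")
  inplane <- if (view == "AP") c(1L, 3L) else c(2L, 3L)
  outplane <- if (view == "AP") 2L else 1L
  profs <- list()
  zexts <- numeric(0)
  for (i in seq_along(meshes)) {
    pr <- tryCatch({
      m <- meshes[[i]]
      ct <- mask_to_contour(project_silhouette(m, view, spacing, bone))
      # put the mask-frame contour back into mesh coordinates (bbox centres)
      V2 <- m$vertices[, inplane, drop = FALSE]
      for (k in 1:2) {
        ct$points[, k] <- ct$points[, k] - mean(range(ct$points[, k])) +
          mean(range(V2[, k]))
      }
      q <- resample_contour_arclength(ct, P, bone = bone)
      nn <- max.col(-(outer(rowSums(q^2), rowSums(V2^2), "+") -
                        2 * q %*% t(V2)), ties.method = "first")
      list(depth = m$vertices[nn, outplane], zext = diff(range(q[, 2])))
    }, error = function(e) {
      warning("skipping mesh ", i, " (silhouette failed): ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(pr)) {
      profs[[length(profs) + 1L]] <- pr$depth
      zexts <- c(zexts, pr$zext)
    }
  }
  if (length(profs) < 3L) stop("fewer than 3 usable meshes")
  D <- do.call(rbind, profs)
  mu <- colMeans(D)
  Dc <- sweep(D, 2, mu)
  sv <- svd(Dc, nu = 0)
  K <- min(nrow(D) - 1L, ncol(sv$v))
  structure(list(view = view, bone = bone, P = P, mean_depth = mu,
                 depth_modes = sv$v[, seq_len(K), drop = FALSE],
                 depth_variances = (sv$d[seq_len(K)]^2) / (nrow(D) - 1),
                 train_mean_zext = mean(zexts), n_train = nrow(D)),
            class = "depth_model")
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf("depth_model: %s %s view, P = %d, %d training silhouettes\n",
              x$bone, x$view, x$P, x$n_train))
  invisible(x)
}

#' Train the full reconstruction model bundle for one bone
#'
#' Builds the statistical shape model from a training set of meshes
#' (template correspondence + Procrustes + PCA) and the two per-view depth
#' models.
#'
#' @param meshes list of training `mesh3` (canonical frame). The first mesh
#'   is used as the correspondence template unless `template` is given.
#' @param bone `"femur"` or `"tibia"`.
#' @param n_modes SSM modes to retain.
#' @param n_pdm number of meshes used for the depth models (default: up to
#'   20, from the head of the list).
#' @param template optional template `mesh3`.
#' @return A `bone_models` bundle: `ssm`, `pdm_ap`, `pdm_lat`, `bone`.
#' @export
train_bone_models <- function(meshes, bone = c("femur", "tibia"),
                              n_modes = NULL, n_pdm = 20L, template = NULL) {
  bone <- match.arg(bone)
  if (is.null(template)) template <- meshes[[1]]
  clouds <- establish_correspondence(meshes, template)
  ssm <- build_ssm(clouds, n_modes = n_modes, faces = template$faces,
                   bone = bone)
  sub <- meshes[seq_len(min(n_pdm, length(meshes)))]
  structure(list(ssm = ssm,
                 pdm_ap = build_pdm(sub, "AP", bone),
                 pdm_lat = build_pdm(sub, "lateral", bone),
                 bone = bone), class = "bone_models")
}

#' @export
print.bone_models <- function(x, ...) {
  cat("bone_models bundle (", x$bone, ")\n", sep = "")
  print(x$ssm)
  print(x$pdm_ap)
  print(x$pdm_lat)
  invisible(x)
}
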