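# Rigid registration by iterative closest point, 3D (6 DOF) and in-plane
# (3 DOF) variants. Correspondences are exact closest points (point to
# triangle in 3D, point to segment in 2D); the update is the least-squares
# absolute-orientation solution, so the matched objective is non-increasing.

kabsch3 <- function(src, dst) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cd - R %*% cs))
}

principal_axes <- function(P) {
  C <- stats::cov(P)
  eigen(C, symmetric = TRUE)$vectors
}

# Initial pose: translate source centroid onto target centroid and align
# principal axes (signs chosen to keep the rotation closest to identity).
init_centroid_axes <- function(srcP, tgtP) {
  As <- principal_axes(srcP)
  At <- principal_axes(tgtP)
  best <- NULL
  best_score <- -Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    Ats <- At %*% diag(c(s1, s2, 1))
    R <- Ats %*% t(As)
    if (det(R) < 0) R <- (At %*% diag(c(s1, s2, -1))) %*% t(As)
    score <- sum(diag(R))
    if (score > best_score) { best_score <- score; best <- R }
  }
  t <- colMeans(tgtP) - as.numeric(best %*% colMeans(srcP))
  rigid3(best, t)
}

#' Rigid 3D registration of a point cloud onto a mesh (ICP)
#'
#' Iterative closest point with exact point-to-triangle correspondences and
#' a closed-form least-squares rigid update. The objective (RMS
#' closest-point distance) is non-increasing over iterations.
#'
#' @param source a `pcloud3` (or n x 3 matrix) of points to register.
#' @param target a `mesh3` registration target.
#' @param init optional `rigid3` initial pose; `NULL` uses centroid +
#'   principal-axes alignment against the target vertices.
#' @param max_iter maximum iterations (default 50).
#' @param tol convergence tolerance on the change in RMS distance (mm).
#' @return A `rigid3` with attributes `rms` (final RMS, mm), `trace` (RMS
#'   per iteration) and `iterations`.
#' @export
icp_rigid_3d <- function(source, target, init = NULL, max_iter = 50L,
                         tol = 1e-4) {
  P0 <- if (inherits(source, "pcloud3")) source$points else as.matrix(source)
  stopifnot(inherits(target, "mesh3"))
  if (nrow(P0) < 3L) stop("rank-deficient correspondence")
  sv <- svd(sweep(P0, 2, colMeans(P0)))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) stop("rank-deficient correspondence")

  tf <- if (is.null(init)) init_centroid_axes(P0, target$vertices) else init
  stopifnot(inherits(tf, "rigid3"))
  trace <- numeric(0)
  best <- tf
  best_rms <- Inf
  prev <- Inf
  F0 <- target$faces - 1L
  for (it in seq_len(max_iter)) {
    P <- apply_rigid3(tf, P0)
    cp <- cpp_closest_point_mesh(P, target$vertices, F0)
    rms <- sqrt(mean(cp$dist^2))
    trace <- c(trace, rms)
    if (rms < best_rms) { best_rms <- rms; best <- tf }
    if (is.finite(prev) && abs(prev - rms) < tol) break
    prev <- rms
    up <- kabsch3(P0, cp$closest)
    tf <- rigid3(up$R, up$t)
  }
  structure(best, rms = best_rms, trace = trace, iterations = length(trace))
}

#' In-plane rigid registration of one contour onto another (ICP, 3 DOF)
#'
#' Used for the tibia plate: rotation is restricted to the plane (about the
#' profile's central axis) with in-plane translation; no out-of-plane tilt.
#' For rotationally symmetric contours (e.g. circles) the rotation angle is
#' unidentifiable and resolves to 0 by the least-squares tie-break.
#'
#' @param source,target closed `contour2` objects.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the change in RMS distance (mm).
#' @param corr_spacing spacing (mm) at which the source contour is resampled
#'   for correspondences.
#' @return A `rigid2` with attributes `rms`, `trace`, `iterations`. The
#'   rotation is about the source centroid.
#' @export
icp_rigid_2d <- function(source, target, max_iter = 100L, tol = 1e-5,
                         corr_spacing = 1) {
  stopifnot(inherits(source, "contour2"), inherits(target, "contour2"))
  if (!source$closed || !target$closed) stop("contours must be closed")
  P0 <- densify_contour(source, corr_spacing)
  center <- colMeans(P0)
  seg <- contour_segments(target)

  theta <- 0
  tvec <- colMeans(densify_contour(target, corr_spacing)) - center
  trace <- numeric(0)
  best <- c(theta, tvec)
  best_rms <- Inf
  prev <- Inf
  for (it in seq_len(max_iter)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    P <- sweep(sweep(P0, 2, center) %*% t(R), 2, -(center + tvec))
    cp <- cpp_closest_point_polyline(P, seg$a, seg$b)
    rms <- sqrt(mean(cp$dist^2))
    trace <- c(trace, rms)
    if (rms < best_rms) { best_rms <- rms; best <- c(theta, tvec) }
    if (is.finite(prev) && abs(prev - rms) < tol) break
    prev <- rms
    # closed-form 2D least squares about the source centroid
    S <- sweep(P0, 2, center)
    D <- sweep(cp$foot, 2, colMeans(cp$foot))
    num <- sum(S[, 1] * D[, 2] - S[, 2] * D[, 1])
    den <- sum(S[, 1] * D[, 1] + S[, 2] * D[, 2])
    theta <- if (abs(num) < 1e-12 && abs(den) < 1e-12) 0 else atan2(num, den)
    tvec <- colMeans(cp$foot) - center
  }
  structure(rigid2(best[1], best[2], best[3]),
            center = center, rms = best_rms, trace = trace,
            iterations = length(trace))
}
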