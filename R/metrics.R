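#' Root-mean-squared closest-point distance from sample points to a surface
#'
#' The global-fit metric: for each sample point the Euclidean distance to its
#' nearest point on the target triangulated surface is computed
#' (point-to-triangle, not point-to-vertex), and the root mean square of
#' those distances is returned.
#'
#' @param samples a `pcloud3` (or n x 3 matrix) of points on the component
#'   surface.
#' @param target a `mesh3` bone surface.
#' @return RMSE in mm (non-negative scalar).
#' @export
rmse_points_to_surface <- function(samples, target) {
  P <- if (inherits(samples, "pcloud3")) samples$points else as.matrix(samples)
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  if (nrow(P) < 1L) stop("no sample points")
  stopifnot(inherits(target, "mesh3"))
  res <- cpp_closest_point_mesh(P, target$vertices, target$faces - 1L)
  sqrt(mean(res$dist^2))
}

#' Closest points on a mesh for a set of query points
#'
#' @param points n x 3 matrix or `pcloud3`.
#' @param mesh a `mesh3`.
#' @return List with `dist` (n), `closest` (n x 3) and `face` (n, 1-based).
#' @export
closest_point_mesh <- function(points, mesh) {
  P <- if (inherits(points, "pcloud3")) points$points else as.matrix(points)
  cpp_closest_point_mesh(P, mesh$vertices, mesh$faces - 1L)
}

#' RMSE from 2D points to a contour (point-to-segment)
#'
#' 2D analogue of [rmse_points_to_surface()] used for the tibia plate fit:
#' each point's distance to the closest point on the target polyline.
#'
#' @param points n x 2 matrix or `contour2` supplying sample points.
#' @param target a `contour2` polyline/polygon.
#' @return RMSE in mm.
#' @export
rmse_points_to_contour <- function(points, target) {
  P <- if (inherits(points, "contour2")) points$points else as.matrix(points)
  if (nrow(P) < 1L) stop("no sample points")
  stopifnot(inherits(target, "contour2"))
  seg <- contour_segments(target)
  res <- cpp_closest_point_polyline(P, seg$a, seg$b)
  sqrt(mean(res$dist^2))
}

contour_segments <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  if (contour$closed) {
    list(a = p, b = p[c(2:n, 1L), , drop = FALSE])
  } else {
    list(a = p[-n, , drop = FALSE], b = p[-1L, , drop = FALSE])
  }
}

#' Resample a contour's edges to a maximum point spacing
#'
#' Inserts points along each edge so consecutive points are at most
#' `spacing` mm apart. Used to densify edges before Hausdorff evaluation so
#' discrete sampling cannot dominate the clinical 3 mm threshold.
#'
#' @param contour a `contour2`.
#' @param spacing maximum spacing (mm), default 0.2.
#' @return Matrix of densified points (n x 2).
#' @export
densify_contour <- function(contour, spacing = 0.2) {
  seg <- contour_segments(contour)
  densify_segments(seg$a, seg$b, spacing)
}

densify_segments <- function(a, b, spacing) {
  d <- ncol(a)
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    L <- sqrt(sum((b[i, ] - a[i, ])^2))
    k <- max(1L, ceiling(L / spacing))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- matrix(a[i, ], k, d, byrow = TRUE) +
      outer(t, b[i, ] - a[i, ])
  }
  do.call(rbind, out)
}

# Resample a 3D polyline (closed) to max spacing.
densify_polyline3 <- function(p, spacing = 0.2, closed = TRUE) {
  n <- nrow(p)
  a <- p
  b <- if (closed) p[c(2:n, 1L), , drop = FALSE] else {
    a <- p[-n, , drop = FALSE]
    p[-1L, , drop = FALSE]
  }
  densify_segments(a, b, spacing)
}

#' Directed Hausdorff distance between component edges and bone edges
#'
#' The maximum over/underhang metric: h(C, B) = max over c in C of the
#' minimum over b in B of d(c, b). Over- and underhang are both reported as
#' positive distances (the metric is unsigned), and the distance is directed
#' - h(C, B) generally differs from h(B, C). Contour inputs are densified to
#' at most `spacing` mm point spacing before evaluation; point-cloud inputs
#' are used as given.
#'
#' @param component_edges a `contour2` or `pcloud3` (edges of the implant
#'   component, C).
#' @param bone_edges a `contour2` or `pcloud3` of the same dimensionality
#'   (edges of the resected bone, B).
#' @param spacing densification spacing in mm (default 0.2).
#' @return Directed Hausdorff distance in mm.
#' @export
directed_hausdorff <- function(component_edges, bone_edges, spacing = 0.2) {
  as_pts <- function(x) {
    if (inherits(x, "contour2")) densify_contour(x, spacing)
    else if (inherits(x, "pcloud3")) x$points
    else as.matrix(x)
  }
  A <- as_pts(component_edges)
  B <- as_pts(bone_edges)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("empty edge set")
  if (ncol(A) != ncol(B)) stop("mixed 2D/3D edge sets")
  max(cpp_min_dists(A, B))
}

#' Surface RMSE between two meshes after rigid alignment
#'
#' Samples one surface, rigidly registers the samples onto the other
#' (centroid-initialized ICP), and returns the closest-point RMSE. Used to
#' benchmark reconstructions against ground-truth anatomy, which live in
#' different frames (image vs canonical).
#'
#' @param mesh a `mesh3` to evaluate (e.g. a reconstruction).
#' @param reference the reference `mesh3`.
#' @param n_samples number of surface samples.
#' @param align rigidly align before evaluating (default `TRUE`).
#' @return RMSE in mm.
#' @export
surface_rmse <- function(mesh, reference, n_samples = 800L, align = TRUE) {
  s <- sample_mesh_surface(mesh, n_samples)
  if (align) {
    init <- rigid3(diag(3), colMeans(reference$vertices) - colMeans(s))
    tf <- icp_rigid_3d(s, reference, init = init, max_iter = 30L, tol = 1e-5)
    s <- apply_rigid3(tf, s)
  }
  rmse_points_to_surface(s, reference)
}
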