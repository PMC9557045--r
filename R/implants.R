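# Generic implant component templates and their scaling to the size charts.
# The exact commercial geometries are proprietary; these templates are
# version-pinned parametric stand-ins: the femur component is an articular
# shell over the distal condylar surface (with five nominal planar mating
# faces implied by its rim), the tibia plate is a 2D kidney profile with a
# shallow posterior notch. Both reproduce their chart (ML, AP) exactly.

FEMUR_TEMPLATE_DIMS <- c(ML = 66, AP = 60)
TIBIA_TEMPLATE_DIMS <- c(ML = 70, AP = 47)
FEMUR_BAND_PHI0 <- 65 * pi / 180  # proximal limit of the articular shell

# Femur template: distal band of the canonical condylar surface, as an open
# shell mesh, at the native template dimensions (bbox-exact).
femur_template <- function(n_theta = 40L, n_band = 12L) {
  a <- FEMUR_TEMPLATE_DIMS[["ML"]] / 2
  b <- FEMUR_TEMPLATE_DIMS[["AP"]] / 2
  c <- 31  # native Z semi-axis, consistent with the bone generator
  phi <- FEMUR_BAND_PHI0 + (pi - FEMUR_BAND_PHI0) *
    seq_len(n_band) / (n_band + 1L)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  grid <- expand.grid(theta = th, phi = phi)
  V <- femur_surface_points(grid$theta, grid$phi, a, b, c, shaft = FALSE)
  pole <- femur_surface_points(0, pi, a, b, c, shaft = FALSE)
  V <- rbind(V, pole)
  faces <- list()
  idx <- function(j, i) (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  for (j in seq_len(n_band - 1L)) for (i in seq_len(n_theta)) {
    faces[[length(faces) + 1L]] <- c(idx(j, i), idx(j + 1L, i), idx(j + 1L, i + 1L))
    faces[[length(faces) + 1L]] <- c(idx(j, i), idx(j + 1L, i + 1L), idx(j, i + 1L))
  }
  sp <- n_band * n_theta + 1L
  for (i in seq_len(n_theta))
    faces[[length(faces) + 1L]] <- c(sp, idx(n_band, i + 1L), idx(n_band, i))
  F <- do.call(rbind, faces)
  # bbox-exact in ML/AP at native dims (Z left as constructed)
  rng <- apply(V, 2, range)
  ctr <- colMeans(rng)
  V <- sweep(V, 2, ctr)
  V[, 1] <- V[, 1] * FEMUR_TEMPLATE_DIMS[["ML"]] / (rng[2, 1] - rng[1, 1])
  V[, 2] <- V[, 2] * FEMUR_TEMPLATE_DIMS[["AP"]] / (rng[2, 2] - rng[1, 2])
  mesh <- mesh3(V, F)
  # peripheral rim: per azimuth, the vertex of maximal in-plane radius
  ring_j <- matrix(seq_len(n_band * n_theta), n_theta, n_band)
  rim_idx <- integer(n_theta)
  rad <- sqrt(V[, 1]^2 + V[, 2]^2)
  for (i in seq_len(n_theta)) rim_idx[i] <- ring_j[i, which.max(rad[ring_j[i, ]])]
  list(mesh = mesh, rim_idx = rim_idx, n_theta = n_theta)
}

# Deterministic area-weighted surface sampling (golden-ratio barycentric
# sequence) of a mesh; all samples lie exactly on the surface.
sample_mesh_surface <- function(mesh, n = 2000L) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  cnt <- pmax(1L, round(n * area / sum(area)))
  out <- matrix(0, sum(cnt), 3)
  pos <- 0L
  g1 <- 0.7548777; g2 <- 0.5698403  # 2D golden-ratio sequence
  for (t in seq_along(cnt)) {
    k <- seq_len(cnt[t])
    u <- (k * g1 + t * 0.123) %% 1
    v <- (k * g2 + t * 0.456) %% 1
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    out[pos + k, ] <- matrix(V[F[t, 1], ], cnt[t], 3, byrow = TRUE) +
      outer(u, e1[t, ]) + outer(v, e2[t, ])
    pos <- pos + cnt[t]
  }
  out
}

# Tibia plate template profile at native dims: kidney outline (bilobed
# posteriorly) with a shallow central posterior notch. Returns the full
# profile, the fit-analysis edge contour (the notch detail is excluded:
# closed by the profile's smooth un-notched continuation), and the notch
# membership flags. Both curves share one bbox-exact affine rescale.
tibia_template <- function(n = 160L) {
  a <- TIBIA_TEMPLATE_DIMS[["ML"]] / 2
  b <- TIBIA_TEMPLATE_DIMS[["AP"]] / 2
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- kidney_radius(th, a, b, notch_depth = 0.09, notch_width = 0.20)
  r0 <- kidney_radius(th, a, b, notch_depth = 0)
  p <- cbind(r * cos(th), r * sin(th))
  p0 <- cbind(r0 * cos(th), r0 * sin(th))
  in_notch <- (r0 - r) / r0 > 0.004
  rng <- apply(p, 2, range)
  ctr <- colMeans(rng)
  sx <- TIBIA_TEMPLATE_DIMS[["ML"]] / (rng[2, 1] - rng[1, 1])
  sy <- TIBIA_TEMPLATE_DIMS[["AP"]] / (rng[2, 2] - rng[1, 2])
  tf <- function(q) sweep(q, 2, ctr) %*% diag(c(sx, sy))
  list(profile = tf(p), closure = tf(p0), in_notch = in_notch)
}

#' Build a femur component at a chart size
#'
#' Scales the generic femur template anisotropically so the X extent equals
#' the entry's ML and the Y extent its AP; the Z scale factor is the mean
#' of the X and Y factors, keeping component height proportional. The
#' component carries its outer-surface mesh, its peripheral rim contour
#' (edge set for the overhang metric) and >= `n_samples` uniform-area
#' surface samples (points for the RMSE metric).
#'
#' @param entry one row of a femur `size_chart`.
#' @param n_samples minimum surface sample count (default 2000).
#' @return An `implant_component` (component = "femur").
#' @export
build_femur_component <- function(entry, n_samples = 2000L) {
  entry <- as.list(as.data.frame(entry))
  if (!identical(entry$component, "femur")) stop("entry is not a femur size")
  tpl <- femur_template_cached()
  sx <- entry$ML / FEMUR_TEMPLATE_DIMS[["ML"]]
  sy <- entry$AP / FEMUR_TEMPLATE_DIMS[["AP"]]
  sz <- (sx + sy) / 2
  mesh <- tpl$mesh
  mesh$vertices <- mesh$vertices %*% diag(c(sx, sy, sz))
  rim <- mesh$vertices[tpl$rim_idx, , drop = FALSE]
  structure(list(
    component = "femur", size = entry, geometry = mesh,
    rim = rim,  # ordered 3D peripheral rim (closed ring)
    surface_samples = sample_mesh_surface(mesh, n_samples),
    scale = c(sx, sy, sz)), class = "implant_component")
}

#' Build a tibia plate profile at a chart size
#'
#' Scales the generic 2D kidney plate profile so its bounding box equals
#' the entry's (ML, AP). The posterior-notch detail is excluded from the
#' fit analysis: in the edge contour the notch is closed by the profile's
#' smooth un-notched continuation. The central axis (rotation reference)
#' is the bounding-box centroid.
#'
#' @param entry one row of a tibia `size_chart`.
#' @return An `implant_component` (component = "tibia") with `geometry` the
#'   full profile (`contour2`), `edges` the fit-analysis contour and
#'   `central_axis` the rotation reference point.
#' @export
build_tibia_profile <- function(entry) {
  entry <- as.list(as.data.frame(entry))
  if (!identical(entry$component, "tibia")) stop("entry is not a tibia size")
  tpl <- tibia_template_cached()
  sx <- entry$ML / TIBIA_TEMPLATE_DIMS[["ML"]]
  sy <- entry$AP / TIBIA_TEMPLATE_DIMS[["AP"]]
  p <- tpl$profile %*% diag(c(sx, sy))
  edges <- tpl$closure %*% diag(c(sx, sy))
  edges[!tpl$in_notch, ] <- p[!tpl$in_notch, ]
  structure(list(
    component = "tibia", size = entry, geometry = contour2(p),
    edges = contour2(edges),
    central_axis = colMeans(apply(p, 2, range)),
    scale = c(sx, sy)), class = "implant_component")
}

#' @export
print.implant_component <- function(x, ...) {
  cat(sprintf("implant_component: %s %s size '%s' (ML %.1f, AP %.1f mm)\n",
              x$size$manufacturer, x$component, x$size$size_id, x$size$ML,
              x$size$AP))
  invisible(x)
}

# memoised templates (built once per session)
.tkr_cache <- new.env(parent = emptyenv())
femur_template_cached <- function() {
  if (is.null(.tkr_cache$femur_tpl)) .tkr_cache$femur_tpl <- femur_template()
  .tkr_cache$femur_tpl
}
tibia_template_cached <- function() {
  if (is.null(.tkr_cache$tibia_tpl)) .tkr_cache$tibia_tpl <- tibia_template()
  .tkr_cache$tibia_tpl
}
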