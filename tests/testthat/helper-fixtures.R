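# Shared fixtures and independent oracles. Oracles are deliberately written
# as direct formulations (feature enumeration, exhaustive double loops) so
# they share no code path with the package kernels they check.

# --- simple meshes -----------------------------------------------------------

unit_cube_mesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward orientation
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  mesh3(V, F)
}

cylinder_mesh <- function(r = 10, h = 30, n = 48, cone_top = FALSE) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  bot <- cbind(r * cos(th), r * sin(th), 0)
  top <- cbind(r * cos(th), r * sin(th), h)
  V <- rbind(c(0, 0, if (cone_top) h * 2 else h), top, bot, c(0, 0, 0))
  F <- list()
  idx_t <- function(i) 1 + ((i - 1) %% n) + 1
  idx_b <- function(i) 1 + n + ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    F[[length(F) + 1]] <- c(1, idx_t(i), idx_t(i + 1))
    F[[length(F) + 1]] <- c(idx_t(i), idx_b(i), idx_b(i + 1))
    F[[length(F) + 1]] <- c(idx_t(i), idx_b(i + 1), idx_t(i + 1))
    F[[length(F) + 1]] <- c(2 + 2 * n, idx_b(i + 1), idx_b(i))
  }
  mesh3(V, do.call(rbind, F))
}

random_convex_mesh <- function(n = 40, seed = 1) {
  # convex hull of random sphere points via internal fan triangulation:
  # use a jittered UV sphere (star-shaped, valid triangulation)
  set.seed(seed)
  n_th <- 10; n_ph <- 8
  th <- 2 * pi * (seq_len(n_th) - 1) / n_th
  ph <- pi * seq_len(n_ph - 1) / n_ph
  g <- expand.grid(theta = th, phi = ph)
  r <- 10 + stats::runif(nrow(g), 0, 3)
  V <- cbind(r * sin(g$phi) * cos(g$theta), r * sin(g$phi) * sin(g$theta),
             r * cos(g$phi))
  V <- rbind(c(0, 0, 11), V, c(0, 0, -11))
  mesh3(V, tkrsize:::uv_sphere_faces(n_th, n_ph - 1))
}

rot3 <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# --- independent oracles -----------------------------------------------------

# Point-to-triangle distance by feature enumeration: interior projection
# (checked via barycentric coordinates), the three clamped edge
# projections, and the three vertices.
oracle_point_tri <- function(p, a, b, c) {
  cand <- list(a, b, c)
  seg <- function(u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w^2)
    u + min(1, max(0, t)) * w
  }
  cand <- c(cand, list(seg(a, b), seg(b, c), seg(c, a)))
  nrm <- c(crossprod_vec(b - a, c - a))
  if (sum(nrm^2) > 0) {
    q <- p - sum((p - a) * nrm) / sum(nrm^2) * nrm
    # barycentric containment
    m <- cbind(b - a, c - a)
    uv <- tryCatch(qr.solve(crossprod(m), crossprod(m, q - a)),
                   error = function(e) NULL)
    if (!is.null(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
      cand <- c(cand, list(q))
  }
  sqrt(min(vapply(cand, function(x) sum((p - x)^2), 0)))
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

oracle_rmse_points_mesh <- function(P, mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- vapply(seq_len(nrow(P)), function(i) {
    min(vapply(seq_len(nrow(F)), function(t)
      oracle_point_tri(P[i, ], V[F[t, 1], ], V[F[t, 2], ], V[F[t, 3], ]), 0))
  }, 0)
  sqrt(mean(d^2))
}

# Exhaustive directed Hausdorff on point sets (any dimension)
oracle_directed_hausdorff <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  max(sqrt(apply(d2, 1, min)))
}

# Midrank Spearman rho from first principles
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Circle contour fixture
circle_contour <- function(r = 30, n = 180, centre = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour2(cbind(centre[1] + r * cos(th), centre[2] + r * sin(th)))
}

# Closed prism mesh extruded from a 2D profile (flat top/bottom), used to
# build tibias whose resection section is a prescribed polygon.
prism_mesh <- function(profile, h = 30, z_top = 0, taper = 1) {
  # straight-walled prism with ringed flat caps (so cap vertices carry
  # upward normals for plateau detection)
  p <- profile
  ctr <- colMeans(p)
  ring <- function(f, z) cbind(ctr[1] + f * (p[, 1] - ctr[1]),
                               ctr[2] + f * (p[, 2] - ctr[2]), z)
  pb <- cbind(ctr[1] + taper * (p[, 1] - ctr[1]),
              ctr[2] + taper * (p[, 2] - ctr[2]))
  ringb <- function(f, z) cbind(ctr[1] + f * (pb[, 1] - ctr[1]),
                                ctr[2] + f * (pb[, 2] - ctr[2]), z)
  V <- rbind(c(ctr, z_top),
             ring(1 / 3, z_top), ring(2 / 3, z_top), ring(1, z_top),
             ringb(1, z_top - h),
             ringb(2 / 3, z_top - h), ringb(1 / 3, z_top - h),
             c(ctr, z_top - h))
  mesh3(V, tkrsize:::uv_sphere_faces(nrow(p), 6L))
}
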