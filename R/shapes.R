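# Parametric shape family shared by the synthetic bone generator and the
# generic implant templates. Femora are star-shaped radial surfaces on a
# theta/phi grid (two condyles + trochlear/intercondylar groove + shaft
# stub); tibiae are extruded kidney profiles tapering to a shaft. Frames are
# canonical right-knee: X medial->lateral, Y posterior->anterior, Z
# distal->proximal.

smoothstep <- function(t, e0, e1) {
  u <- pmin(1, pmax(0, (t - e0) / (e1 - e0)))
  u * u * (3 - 2 * u)
}

# Kidney cross-section radius at polar angles `theta` for semi-axes a (ML/2)
# and b (AP/2): elliptical anteriorly, superelliptical (flattened, bilobed
# once notched) posteriorly, with an optional central posterior notch
# (relative depth, angular sd). The posterior flattening keeps the AP
# extent at the lobes even when the notch is carved out.
kidney_radius <- function(theta, a, b, notch_depth = 0, notch_width = 0.20,
                          p_post = 3.5) {
  ct <- cos(theta)
  st <- sin(theta)
  p <- ifelse(st < 0, p_post, 2)
  r <- a * b / ((abs(b * ct))^p + (abs(a * st))^p)^(1 / p)
  if (notch_depth > 0) {
    dth <- atan2(sin(theta + pi / 2), cos(theta + pi / 2))  # 0 at posterior
    r <- r * (1 - notch_depth * exp(-(dth / notch_width)^2))
  }
  r
}

# Femur radial modulation for unit-sphere parameter (theta azimuth about Z,
# phi polar from +Z). Returns a multiplicative factor applied to the
# ellipsoidal radius: trochlear/intercondylar groove carved near the
# mid-sagittal plane on the distal half, mild condylar bulges at +/- ML.
femur_modulation <- function(theta, phi) {
  xn <- sin(phi) * cos(theta)
  yn <- sin(phi) * sin(theta)
  zn <- cos(phi)
  distal <- pmax(0, -zn)^0.8
  groove <- 0.16 * exp(-(xn / 0.28)^2) * distal * (0.35 + 0.65 * pmax(0, yn))
  condyle <- 0.06 * exp(-((abs(xn) - 0.5) / 0.25)^2) * pmax(0, -zn)
  1 - groove + condyle
}

# Evaluate the canonical femur surface point for grid parameters and
# semi-axes (a, b, c). `shaft` enables the proximal shaft-stub modulation
# (narrowed ML/AP, elongated Z); the distal band (phi >= ~60 deg) is
# unaffected so implant templates share the articular surface exactly.
femur_surface_points <- function(theta, phi, a, b, c, shaft = TRUE) {
  m <- femur_modulation(theta, phi)
  x <- a * sin(phi) * cos(theta) * m
  y <- b * sin(phi) * sin(theta) * m
  z <- c * cos(phi)
  if (shaft) {
    w <- smoothstep(cos(phi), 0.5, 0.9)
    x <- x * (1 - 0.38 * w)
    y <- y * (1 - 0.30 * w)
    z <- z * (1 + 0.30 * w)
  }
  cbind(x, y, z)
}

# Closed UV-sphere-style triangulation over theta (n_theta, periodic) and
# phi (n_phi interior rings + 2 poles). Returns faces for the given ring
# vertex layout: pole_n (index 1), rings row-major, pole_s (last).
uv_sphere_faces <- function(n_theta, n_rings) {
  faces <- list()
  idx <- function(j, i) 1L + (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  # north cap
  for (i in seq_len(n_theta))
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, i), idx(1L, i + 1L))
  # bands
  if (n_rings > 1L) {
    for (j in seq_len(n_rings - 1L)) for (i in seq_len(n_theta)) {
      faces[[length(faces) + 1L]] <- c(idx(j, i), idx(j + 1L, i), idx(j + 1L, i + 1L))
      faces[[length(faces) + 1L]] <- c(idx(j, i), idx(j + 1L, i + 1L), idx(j, i + 1L))
    }
  }
  # south cap
  sp <- 1L + n_rings * n_theta + 1L
  for (i in seq_len(n_theta))
    faces[[length(faces) + 1L]] <- c(sp, idx(n_rings, i + 1L), idx(n_rings, i))
  do.call(rbind, faces)
}

# Canonical femur mesh at semi-axes (a, b, c) on an n_theta x n_phi grid.
canonical_femur_mesh <- function(a, b, c, n_theta = 36L, n_phi = 18L) {
  phi_r <- pi * seq_len(n_phi - 1L) / n_phi
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  grid <- expand.grid(theta = th, phi = phi_r)  # theta varies fastest
  ring_pts <- femur_surface_points(grid$theta, grid$phi, a, b, c)
  pole_n <- femur_surface_points(0, 0, a, b, c)
  pole_s <- femur_surface_points(0, pi, a, b, c)
  V <- rbind(pole_n, ring_pts, pole_s)
  F <- uv_sphere_faces(n_theta, n_phi - 1L)
  mesh3(V, F)
}

# Affinely rescale X and Y (about the bounding-box centre) so the extents
# are exactly (ML, AP); Z is rescaled by the mean of the X and Y factors
# unless scale_z is FALSE.
rescale_to_dims <- function(V, ML, AP, scale_z = TRUE) {
  rng <- apply(V, 2, range)
  ctr <- colMeans(rng)
  sx <- ML / (rng[2, 1] - rng[1, 1])
  sy <- AP / (rng[2, 2] - rng[1, 2])
  sz <- if (scale_z) (sx + sy) / 2 else 1
  V <- sweep(V, 2, ctr)
  V <- V %*% diag(c(sx, sy, sz))
  V
}

# Canonical proximal tibia mesh: kidney cross-section extruded from the
# plateau (z = 0 at the rim) down `depth` mm, tapering toward the shaft.
# The plateau cap rises centrally by `dome` mm (intercondylar eminence),
# keeping the resection plane clear of the articular surface; the widest
# cross-section is the plateau rim. `dome = 0` gives a flat plateau.
canonical_tibia_mesh <- function(a, b, depth = 55, n_theta = 40L,
                                 n_z = 11L, n_cap = 4L, dome = 2.5) {
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  r0 <- kidney_radius(th, a, b, notch_depth = 0)
  # depth levels below the rim: the metaphyseal flare peaks at d = 5 mm
  # (the widest ring sits below the articular rim, as on real tibiae),
  # then the wall tapers toward the shaft
  d_b <- 5
  d <- c(0, d_b / 2, d_b, d_b + (depth - d_b) * seq_len(n_z - 3L) / (n_z - 3L))
  dd <- pmax(0, d - d_b)
  s <- (1 - 0.0008 * dd - 0.45 * (dd / depth)^2.2) *
    (1 - 0.03 * ((d_b - pmin(d, d_b)) / d_b)^2)
  rings <- lapply(seq_len(n_z), function(j)
    cbind(r0 * s[j] * cos(th), r0 * s[j] * sin(th), -d[j]))
  # cap rings (top: z=0 rim with a midline intercondylar eminence of height
  # `dome` that leaves the medial/lateral plateau facets flat; bottom flat)
  capfrac <- (n_cap - seq_len(n_cap) + 1) / (n_cap + 1)
  eminence <- function(x, f) dome * exp(-(x / (0.25 * a))^2) * (1 - f^4)
  top_caps <- lapply(capfrac, function(f) {
    x <- r0 * f * cos(th)
    cbind(x, r0 * f * sin(th), eminence(x, f))
  })
  bot_caps <- lapply(capfrac, function(f)
    cbind(r0 * s[n_z] * f * cos(th), r0 * s[n_z] * f * sin(th), -depth))
  V <- rbind(c(0, 0, dome), do.call(rbind, rev(top_caps)),
             # (pole carries the full eminence height)
             do.call(rbind, rings), do.call(rbind, bot_caps),
             c(0, 0, -depth))
  n_rings_total <- n_cap + n_z + n_cap
  F <- uv_sphere_faces(n_theta, n_rings_total)
  mesh3(V, F)
}
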