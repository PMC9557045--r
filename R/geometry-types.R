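#' Triangulated surface mesh in millimetres
#'
#' Canonical container for bone and implant surfaces. The axis convention is
#' a right-knee frame: X runs medial to lateral (+X lateral), Y posterior to
#' anterior (+Y anterior), Z distal to proximal (+Z proximal). Left knees are
#' mirrored about the YZ plane on ingest so all downstream code sees a right
#' knee.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based triangle vertex indices.
#' @param frame_note character tag recording the axis convention.
#' @return An object of class `mesh3` with elements `vertices`, `faces`,
#'   `frame_note`.
#' @export
mesh3 <- function(vertices, faces, frame_note = "right-knee:X=ML,Y=PA,Z=DP") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(faces) != 3L) stop("faces must be m x 3")
  if (nrow(vertices) < 4L) stop("a mesh needs at least 4 vertices")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range")
  structure(list(vertices = vertices, faces = faces, frame_note = frame_note),
            class = "mesh3")
}

#' @export
print.mesh3 <- function(x, ...) {
  ext <- mesh_extents(x)
  cat(sprintf("mesh3: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extents (mm): ML %.2f, AP %.2f, Z %.2f\n",
              ext["ML"], ext["AP"], ext["Z"]))
  cat("  frame:", x$frame_note, "\n")
  invisible(x)
}

#' Bounding-box extents of a mesh
#'
#' @param mesh a `mesh3`.
#' @return Named numeric vector `c(ML, AP, Z)`: the X, Y and Z spans in mm.
#' @export
mesh_extents <- function(mesh) {
  rng <- apply(mesh$vertices, 2, range)
  ext <- rng[2, ] - rng[1, ]
  names(ext) <- c("ML", "AP", "Z")
  ext
}

#' Closed or open planar contour in millimetres
#'
#' Consecutive duplicate points are removed; closed contours are normalized
#' to counter-clockwise orientation (positive signed area).
#'
#' @param points numeric n x 2 matrix of ordered points (mm).
#' @param closed logical; closed contours are treated as simple polygons.
#' @return An object of class `contour2`.
#' @export
contour2 <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("contour points must be n x 2")
  if (!all(is.finite(points))) stop("non-finite contour coordinates")
  # drop consecutive duplicates (and closing repeat of the first point)
  if (nrow(points) > 1L) {
    d <- rowSums(abs(diff(points)))
    keep <- c(TRUE, d > 1e-12)
    points <- points[keep, , drop = FALSE]
  }
  if (closed && nrow(points) > 1L &&
      sum(abs(points[nrow(points), ] - points[1L, ])) < 1e-12) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  if (nrow(points) < 3L) stop("a contour needs at least 3 distinct points")
  if (closed && polygon_signed_area(points) < 0) {
    points <- points[nrow(points):1L, , drop = FALSE]
  }
  structure(list(points = points, closed = closed), class = "contour2")
}

#' @export
print.contour2 <- function(x, ...) {
  cat(sprintf("contour2: %d points, %s", nrow(x$points),
              if (x$closed) "closed" else "open"))
  if (x$closed) cat(sprintf(", area %.2f mm^2", polygon_area(x)))
  cat("\n")
  invisible(x)
}

polygon_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

#' Area enclosed by a closed contour
#' @param contour a closed `contour2`.
#' @return Area in mm^2 (positive).
#' @export
polygon_area <- function(contour) {
  stopifnot(inherits(contour, "contour2"), contour$closed)
  abs(polygon_signed_area(contour$points))
}

#' Unstructured 3D point cloud in millimetres
#' @param points numeric n x 3 matrix.
#' @return An object of class `pcloud3`.
#' @export
pcloud3 <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (nrow(points) < 1L) stop("empty point cloud")
  if (!all(is.finite(points))) stop("non-finite point coordinates")
  structure(list(points = points), class = "pcloud3")
}

#' Rigid transform in 3D
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1 within 1e-9).
#' @param translation length-3 translation (mm).
#' @return An object of class `rigid3`.
#' @export
rigid3 <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid3")
}

#' In-plane rigid transform (rotation angle + translation)
#'
#' Three degrees of freedom: used for the tibia plate, whose rotation is
#' restricted to its central axis (no flexion/extension).
#'
#' @param theta rotation angle in radians, normalized to (-pi, pi].
#' @param tx,ty translation components (mm).
#' @return An object of class `rigid2`.
#' @export
rigid2 <- function(theta = 0, tx = 0, ty = 0) {
  theta <- as.numeric(theta)
  theta <- atan2(sin(theta), cos(theta))
  if (theta <= -pi) theta <- pi
  structure(list(theta = theta, tx = as.numeric(tx), ty = as.numeric(ty)),
            class = "rigid2")
}

#' Oriented plane in 3D
#' @param origin point on the plane (mm).
#' @param normal plane normal; normalized to unit length.
#' @return An object of class `plane3`.
#' @export
plane3 <- function(origin, normal) {
  origin <- as.numeric(origin)
  normal <- as.numeric(normal)
  stopifnot(length(origin) == 3L, length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("zero-length plane normal")
  structure(list(origin = origin, normal = normal / nn), class = "plane3")
}

#' Apply a rigid 3D transform
#' @param tf a `rigid3`.
#' @param x a `mesh3`, `pcloud3` or n x 3 matrix.
#' @return The transformed object, same type as `x`.
#' @export
apply_rigid3 <- function(tf, x) {
  stopifnot(inherits(tf, "rigid3"))
  tp <- function(p) sweep(p %*% t(tf$rotation), 2, -tf$translation)
  if (inherits(x, "mesh3")) {
    x$vertices <- tp(x$vertices)
    x
  } else if (inherits(x, "pcloud3")) {
    x$points <- tp(x$points)
    x
  } else {
    tp(as.matrix(x))
  }
}

#' Compose two rigid 3D transforms (`a` applied after `b`)
#' @param a,b `rigid3` objects.
#' @return A `rigid3` equal to applying `b` then `a`.
#' @export
compose_rigid3 <- function(a, b) {
  rigid3(a$rotation %*% b$rotation,
         as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid 3D transform
#' @param tf a `rigid3`.
#' @return The inverse `rigid3`.
#' @export
invert_rigid3 <- function(tf) {
  rigid3(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' Apply an in-plane rigid transform to 2D points
#' @param tf a `rigid2`.
#' @param x a `contour2` or n x 2 matrix.
#' @param center optional rotation center (default origin).
#' @return Transformed object, same type as `x`.
#' @export
apply_rigid2 <- function(tf, x, center = c(0, 0)) {
  stopifnot(inherits(tf, "rigid2"))
  R <- matrix(c(cos(tf$theta), sin(tf$theta),
                -sin(tf$theta), cos(tf$theta)), 2, 2)
  tp <- function(p) {
    p <- sweep(as.matrix(p), 2, center)
    sweep(p %*% t(R), 2, -(center + c(tf$tx, tf$ty)))
  }
  if (inherits(x, "contour2")) {
    x$points <- tp(x$points)
    x
  } else tp(x)
}

#' Mirror a mesh about the YZ plane (left-to-right knee conversion)
#'
#' Flips the X (medial-lateral) axis and reverses face winding so outward
#' normals are preserved.
#'
#' @param mesh a `mesh3`.
#' @return Mirrored `mesh3`.
#' @export
mirror_mesh <- function(mesh) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Per-vertex area-weighted outward normals
#' @param mesh a `mesh3`.
#' @return n x 3 matrix of unit vertex normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (j in 1:3) {
      acc <- tapply(fn[, j], F[, k], sum)
      idx <- as.integer(names(acc))
      vn[idx, j] <- vn[idx, j] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-30] <- 1
  vn / len
}
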