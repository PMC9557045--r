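# 2D -> 3D reconstruction: silhouette masks to contours, bi-planar
# alignment, per-view depth estimation (PDM) and statistical-shape-model
# fitting of the pooled sparse reference points.

#' Extract the bone contour from a silhouette mask
#'
#' Keeps the largest foreground connected component, traces its outer
#' boundary to a closed ordered contour, offsets it by half a pixel so the
#' polygon encloses the full foreground area, and converts to mm. AP-view
#' masks of left knees are mirrored into the right-knee convention.
#'
#' @param mask a `mask_image`.
#' @return A closed `contour2` in mm (image-plane coordinates).
#' @export
mask_to_contour <- function(mask) {
  stopifnot(inherits(mask, "mask_image"))
  px <- mask$pixels
  if (!any(px)) stop("empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(px * 1))
  sizes <- table(lab[lab > 0])
  if (!length(sizes)) stop("empty mask")
  biggest <- max(sizes)
  winners <- names(sizes)[sizes == biggest]
  if (length(winners) > 1L)
    stop("ambiguous mask: multiple equal-size foreground components")
  keep <- lab == as.integer(winners[1])
  oc <- EBImage::ocontour(EBImage::Image(keep * 1))[[1]]
  pts <- (oc + 0.5) * mask$spacing  # pixel centres, mm
  ct <- contour2(pts, closed = TRUE)
  # half-pixel outward offset along the CCW outward normal
  p <- ct$points
  n <- nrow(p)
  tng <- p[c(2:n, 1L), ] - p[c(n, 1:(n - 1L)), ]
  len <- sqrt(rowSums(tng^2)); len[len < 1e-12] <- 1
  nrm <- cbind(tng[, 2], -tng[, 1]) / len
  p <- p + 0.5 * mask$spacing * nrm
  if (mask$side == "left" && mask$view == "AP") p[, 1] <- -p[, 1]
  contour2(p, closed = TRUE)
}

#' Binarize a grayscale projection (Otsu threshold fallback)
#'
#' Classical stand-in for CNN segmentation on synthetic grayscale
#' projections: Otsu threshold, then largest connected component.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @inheritParams mask_image
#' @return A `mask_image`.
#' @export
mask_from_grayscale <- function(img, spacing, view = "AP", bone = "femur",
                                side = "right") {
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  mask_image(img > thr, spacing, view, bone, side)
}

#' Align AP and lateral contours in 3D
#'
#' Embeds the AP contour in the XZ plane (Y = 0) and the lateral contour in
#' the YZ plane (X = 0), centres each horizontally, equalizes the vertical
#' extents by uniformly scaling the lateral contour, and registers both
#' vertically on a shared anatomical datum (femur: most distal point;
#' tibia: most proximal point).
#'
#' @param ap,lat closed `contour2` objects (mm) of the same bone.
#' @param bone `"femur"` or `"tibia"`.
#' @param max_extent_ratio views whose Z-extent ratio falls outside
#'   `[1/max_extent_ratio, max_extent_ratio]` are rejected as inconsistent.
#' @return List with `ap` and `lat` (centred, datum-registered `contour2`s;
#'   AP in (x, z), lateral in (y, z)) and `bone`.
#' @export
align_contours_3d <- function(ap, lat, bone = c("femur", "tibia"),
                              max_extent_ratio = 1.25) {
  bone <- match.arg(bone)
  stopifnot(inherits(ap, "contour2"), inherits(lat, "contour2"))
  zext <- function(p) diff(range(p[, 2]))
  ratio <- zext(ap$points) / zext(lat$points)
  if (ratio > max_extent_ratio || ratio < 1 / max_extent_ratio)
    stop(sprintf("views inconsistent: AP/lateral Z-extent ratio %.3f", ratio))
  lat$points <- lat$points * ratio  # equalize magnification
  centre_h <- function(p) { p[, 1] <- p[, 1] - mean(range(p[, 1])); p }
  ap$points <- centre_h(ap$points)
  lat$points <- centre_h(lat$points)
  datum <- function(p) if (bone == "femur") min(p[, 2]) else max(p[, 2])
  lat$points[, 2] <- lat$points[, 2] + datum(ap$points) - datum(lat$points)
  list(ap = ap, lat = lat, bone = bone)
}

# Arc-length-uniform resampling of a closed contour to P points, starting
# at the anatomical start point (femur: most distal, tibia: most proximal;
# ties broken by the larger first coordinate), walking counter-clockwise.
resample_contour_arclength <- function(contour, P, bone = "femur") {
  p <- contour$points
  v2 <- p[, 2]
  extreme <- if (bone == "femur") min(v2) else max(v2)
  cand <- which(abs(v2 - extreme) < 1e-9)
  start <- cand[which.max(p[cand, 1])]
  n <- nrow(p)
  p <- p[c(start:n, seq_len(start - 1L)), , drop = FALSE]
  seg <- sqrt(rowSums((p[c(2:n, 1L), ] - p)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n + 1L]
  s <- total * (seq_len(P) - 1L) / P
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i > n] <- n
  t <- (s - cum[i]) / pmax(seg[i], 1e-12)
  p[i, , drop = FALSE] + (p[c(2:n, 1L), , drop = FALSE][i, , drop = FALSE] -
                            p[i, , drop = FALSE]) * t
}

#' Estimate 3D reference points from an aligned contour via a depth model
#'
#' Resamples the contour to the model's fixed point count (arc-length
#' uniform from the anatomical start point) and assigns each point its
#' out-of-plane coordinate from the model's mean depth profile, scaled by
#' the contour's vertical size relative to the training mean.
#'
#' @param contour an aligned `contour2` from [align_contours_3d()] (AP view
#'   in (x, z); lateral in (y, z)).
#' @param pdm a `depth_model` from [build_pdm()] matching the view/bone.
#' @return A `pcloud3` of P reference points in the canonical frame.
#' @export
apply_pdm <- function(contour, pdm) {
  stopifnot(inherits(contour, "contour2"), inherits(pdm, "depth_model"))
  q <- resample_contour_arclength(contour, pdm$P, bone = pdm$bone)
  scale <- diff(range(contour$points[, 2])) / pdm$train_mean_zext
  depth <- pdm$mean_depth * scale
  pts <- if (pdm$view == "AP") cbind(q[, 1], depth, q[, 2])
         else cbind(depth, q[, 1], q[, 2])
  pcloud3(pts)
}

#' Fit a statistical shape model to sparse reference points
#'
#' Alternates (a) a similarity transform (rigid + uniform scale) of the
#' current model instance onto the reference points by closest-point least
#' squares and (b) a linear solve for the shape-mode coefficients, each
#' clamped to `clamp` standard deviations of its mode. The matched
#' objective is non-increasing; a warning flag is set if `max_iter` is
#' reached before the change drops below `tol`.
#'
#' @param refs a `pcloud3` of reference points (both views pooled).
#' @param ssm a `knee_ssm` from [build_ssm()].
#' @param max_iter maximum outer iterations.
#' @param clamp coefficient clamp in units of sqrt(eigenvalue) (default 3).
#' @param tol stop when the objective change (mm) falls below this.
#' @return A `mesh3` of the morphed model in the reference frame, with
#'   attributes `coefficients`, `similarity` (list s, R, t), `trace`,
#'   `converged`.
#' @export
fit_ssm <- function(refs, ssm, max_iter = 60L, clamp = 3, tol = 1e-4) {
  stopifnot(inherits(refs, "pcloud3"), inherits(ssm, "knee_ssm"))
  Y <- refs$points
  M0 <- ssm$mean_shape
  U <- ssm$modes
  nm <- ncol(U)
  lim <- clamp * sqrt(pmax(ssm$eigenvalues, 0))
  b <- numeric(nm)

  csize <- function(P) sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))
  s <- csize(Y) / csize(M0)
  R <- diag(3)
  t <- colMeans(Y) - s * as.numeric(R %*% colMeans(M0))

  model_of <- function(b) M0 + matrix(U %*% b, ncol = 3, byrow = TRUE)
  posed <- function(X) sweep(s * X %*% t(R), 2, -t)

  nn_index <- function(A, B) {
    # nearest row of B for each row of A
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    max.col(-d2, ties.method = "first")
  }
  obj <- function(X, idx) sqrt(mean(rowSums((Y - posed(X)[idx, ])^2)))

  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    X <- model_of(b)
    idx <- nn_index(Y, posed(X))
    # similarity update (Umeyama) for matched pairs
    Xm <- X[idx, , drop = FALSE]
    cx <- colMeans(Xm); cy <- colMeans(Y)
    Xc <- sweep(Xm, 2, cx); Yc <- sweep(Y, 2, cy)
    sv <- svd(crossprod(Xc, Yc))
    dsgn <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, dsgn)) %*% t(sv$u)
    s <- sum(diag(diag(c(1, 1, dsgn)) %*% diag(sv$d))) / sum(Xc^2)
    t <- cy - s * as.numeric(R %*% cx)
    # coefficient update: LS in the model frame, clamped
    Z <- sweep(Y, 2, t) %*% R / s
    rows <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
    A <- U[rows, , drop = FALSE]
    r <- as.numeric(t(Z - M0[idx, , drop = FALSE]))
    b_new <- tryCatch(solve(crossprod(A), crossprod(A, r))[, 1],
                      error = function(e) b)
    b <- pmin(lim, pmax(-lim, b_new))
    o <- obj(model_of(b), idx)
    trace <- c(trace, o)
    if (is.finite(prev) && abs(prev - o) < tol) { converged <- TRUE; break }
    prev <- o
  }
  if (!converged) warning("shape-model fit did not converge in ", max_iter,
                          " iterations")
  X <- model_of(b)
  out <- mesh3(posed(X), ssm$faces)
  attr(out, "coefficients") <- b
  attr(out, "similarity") <- list(s = s, R = R, t = t)
  attr(out, "trace") <- trace
  attr(out, "converged") <- converged
  out
}

#' Reconstruct a bone from its two silhouette masks
#'
#' Convenience wrapper for the full per-bone pipeline: masks to contours,
#' bi-planar alignment, depth estimation for both views, pooling, and
#' shape-model fitting.
#'
#' @param ap_mask,lat_mask `mask_image`s of the bone.
#' @param models a `bone_models` bundle from [train_bone_models()] for the
#'   right bone.
#' @param ... passed to [fit_ssm()].
#' @return A `mesh3` (see [fit_ssm()] for attributes).
#' @export
reconstruct_bone <- function(ap_mask, lat_mask, models, ...) {
  bone <- models$bone
  al <- align_contours_3d(mask_to_contour(ap_mask), mask_to_contour(lat_mask),
                          bone = bone)
  refs <- rbind(apply_pdm(al$ap, models$pdm_ap)$points,
                apply_pdm(al$lat, models$pdm_lat)$points)
  fit_ssm(pcloud3(refs), models$ssm, ...)
}
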