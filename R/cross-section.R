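#' Planar cross-section of a mesh
#'
#' Intersects a triangulated surface with a plane and returns the largest
#' closed intersection loop expressed in 2D in-plane coordinates. The
#' in-plane basis is anatomical: the first axis is the projection of the
#' global X (medial-lateral) axis onto the plane, the second completes a
#' right-handed frame with the plane normal, so for a near-horizontal
#' resection plane the section coordinates read (ML, AP).
#'
#' @param mesh a `mesh3`.
#' @param plane a `plane3`.
#' @return A counter-clockwise closed `contour2` in plane coordinates (mm).
#' @export
cross_section <- function(mesh, plane) {
  stopifnot(inherits(mesh, "mesh3"), inherits(plane, "plane3"))
  V <- mesh$vertices
  F <- mesh$faces
  s <- as.numeric((V - matrix(plane$origin, nrow(V), 3, byrow = TRUE)) %*%
                    plane$normal)
  # nudge exact-zero vertices off the plane so every crossing is transversal
  s[abs(s) < 1e-9] <- 1e-9
  sf <- matrix(s[F], ncol = 3)
  crossed <- (apply(sf, 1, max) > 0) & (apply(sf, 1, min) < 0)
  if (!any(crossed)) stop("plane misses mesh")
  Fc <- F[crossed, , drop = FALSE]
  sfc <- sf[crossed, , drop = FALSE]

  # per crossed face: the two crossed edges, keyed by sorted vertex pair
  edge_pts <- new.env(hash = TRUE)
  seg_keys <- vector("list", nrow(Fc))
  pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  for (i in seq_len(nrow(Fc))) {
    keys <- character(0)
    for (pr in pairs) {
      sa <- sfc[i, pr[1]]; sb <- sfc[i, pr[2]]
      if (sa * sb < 0) {
        va <- Fc[i, pr[1]]; vb <- Fc[i, pr[2]]
        key <- paste(min(va, vb), max(va, vb), sep = "-")
        if (is.null(edge_pts[[key]])) {
          t <- sa / (sa - sb)
          edge_pts[[key]] <- V[va, ] + t * (V[vb, ] - V[va, ])
        }
        keys <- c(keys, key)
      }
    }
    seg_keys[[i]] <- keys
  }
  seg_keys <- seg_keys[vapply(seg_keys, length, 1L) == 2L]
  if (!length(seg_keys)) stop("plane misses mesh")

  # adjacency on intersection points (edge keys); walk loops, resolving
  # junction nodes (from near-tangential cuts) by direction continuity
  adj <- new.env(hash = TRUE)
  for (sk in seg_keys) {
    adj[[sk[1]]] <- c(adj[[sk[1]]], sk[2])
    adj[[sk[2]]] <- c(adj[[sk[2]]], sk[1])
  }
  keys_all <- ls(adj)
  visited <- new.env(hash = TRUE)
  loops <- list()
  open_chains <- 0L
  pt <- function(k) edge_pts[[k]]
  for (k0 in keys_all) {
    if (!is.null(visited[[k0]])) next
    loop <- character(0)
    k <- k0
    prev <- ""
    heading <- NULL
    closed <- FALSE
    repeat {
      visited[[k]] <- TRUE
      loop <- c(loop, k)
      nbrs <- setdiff(unique(adj[[k]]), prev)
      nbrs <- nbrs[is.na(match(nbrs, loop)) | nbrs == k0]
      if (!length(nbrs)) break
      if (length(nbrs) > 1L && !is.null(heading)) {
        # continue in the direction closest to the current heading
        sc <- vapply(nbrs, function(nk) {
          v <- pt(nk) - pt(k)
          L <- sqrt(sum(v^2))
          if (L < 1e-12) return(-Inf)
          sum(v * heading) / L
        }, 0)
        nbrs <- nbrs[order(-sc)]
      }
      nxt <- nbrs[1]
      if (nxt == k0 && length(loop) > 2L) { closed <- TRUE; break }
      v <- pt(nxt) - pt(k)
      L <- sqrt(sum(v^2))
      if (L > 1e-9) heading <- v / L
      prev <- k
      k <- nxt
    }
    if (closed) loops[[length(loops) + 1L]] <- loop else open_chains <- open_chains + 1L
  }
  if (!length(loops)) {
    stop(sprintf("cross-section loop is open (%d chain(s) cross the mesh boundary)",
                 open_chains))
  }

  # in-plane basis: ex = projected global X (fallback Y when normal ~ X)
  n <- plane$normal
  seed <- c(1, 0, 0)
  ex <- seed - sum(seed * n) * n
  if (sqrt(sum(ex^2)) < 1e-6) {
    seed <- c(0, 1, 0)
    ex <- seed - sum(seed * n) * n
  }
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(n[2] * ex[3] - n[3] * ex[2],
          n[3] * ex[1] - n[1] * ex[3],
          n[1] * ex[2] - n[2] * ex[1])

  to2d <- function(loop) {
    pts3 <- t(vapply(loop, function(k) edge_pts[[k]], numeric(3)))
    pts3 <- sweep(pts3, 2, plane$origin)
    cbind(pts3 %*% ex, pts3 %*% ey)
  }
  areas <- vapply(loops, function(l) abs(polygon_signed_area(to2d(l))), 0)
  contour2(to2d(loops[[which.max(areas)]]), closed = TRUE)
}
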