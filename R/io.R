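# Mesh, contour and mask I/O. STL (ASCII + binary) and PLY (ASCII) are
# read/written directly; masks are 8-bit PNG with spacing in a sidecar JSON.
# All writes are atomic (temp file + rename).

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a surface mesh from STL or PLY
#'
#' Format is chosen by file extension; both binary and ASCII STL are
#' handled. Duplicate vertices in STL soups are merged.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @return A `mesh3`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: ", ext))
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a `mesh3`.
#' @param path output path ending in `.stl` or `.ply`.
#' @param binary for STL, write the binary variant (default `FALSE`: ASCII).
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: ", ext))
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.info(path)$size
  if (length(ntri) == 1L && !is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) {
    tri <- matrix(0, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2L)
    }
    return(soup_to_mesh(tri))
  }
  close(con)
  on.exit()
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  if (!length(vl)) stop("not a valid STL file: ", path)
  tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  soup_to_mesh(tri)
}

soup_to_mesh <- function(tri) {
  key <- apply(round(tri, 6), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  V <- tri[uk, , drop = FALSE]
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  mesh3(V, F)
}

write_stl <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len < 1e-30] <- 1
  n <- n / len
  if (binary) {
    atomic_write(path, function(tmp) {
      con <- file(tmp, "wb")
      on.exit(close(con))
      writeBin(as.raw(rep(0L, 80L)), con)
      writeBin(as.integer(nrow(F)), con, size = 4L, endian = "little")
      for (i in seq_len(nrow(F))) {
        writeBin(as.numeric(c(n[i, ], t(V[F[i, ], ]))), con, size = 4L,
                 endian = "little")
        writeBin(as.raw(c(0L, 0L)), con)
      }
    })
  } else {
    atomic_write(path, function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      cat("solid tkrsize\n", file = con)
      for (i in seq_len(nrow(F))) {
        cat(sprintf(" facet normal %.9g %.9g %.9g\n", n[i, 1], n[i, 2], n[i, 3]),
            "  outer loop\n", file = con, sep = "")
        for (k in 1:3)
          cat(sprintf("   vertex %.9g %.9g %.9g\n",
                      V[F[i, k], 1], V[F[i, k], 2], V[F[i, k], 3]), file = con)
        cat("  endloop\n endfacet\n", file = con)
      }
      cat("endsolid tkrsize\n", file = con)
    })
  }
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  end_hdr <- match("end_header", trimws(txt))
  if (is.na(end_hdr)) stop("not a valid ASCII PLY file: ", path)
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", txt, value = TRUE)[1]))
  body <- txt[(end_hdr + 1L):length(txt)]
  V <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  Fl <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
               function(x) as.integer(x))
  if (any(vapply(Fl, `[`, 1L, 1L) != 3L)) stop("only triangular PLY faces supported")
  F <- do.call(rbind, lapply(Fl, function(x) x[2:4] + 1L))
  mesh3(V, F)
}

write_ply <- function(mesh, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    cat("ply\nformat ascii 1.0\n", file = con)
    cat(sprintf("element vertex %d\n", nrow(mesh$vertices)), file = con)
    cat("property float x\nproperty float y\nproperty float z\n", file = con)
    cat(sprintf("element face %d\n", nrow(mesh$faces)), file = con)
    cat("property list uchar int vertex_indices\nend_header\n", file = con)
    utils::write.table(format(mesh$vertices, digits = 9, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  })
}

#' Read or write a contour as CSV
#'
#' CSV with columns `x,y` (one point per row, mm, in order).
#'
#' @param path CSV path.
#' @param closed whether the stored contour is closed.
#' @return `read_contour_csv` returns a `contour2`.
#' @export
read_contour_csv <- function(path, closed = TRUE) {
  df <- utils::read.csv(path)
  contour2(as.matrix(df[, c("x", "y")]), closed = closed)
}

#' @rdname read_contour_csv
#' @param contour a `contour2` to write.
#' @export
write_contour_csv <- function(contour, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(data.frame(x = contour$points[, 1],
                                y = contour$points[, 2]),
                     tmp, row.names = FALSE)
  })
}

#' Read a silhouette mask from PNG
#'
#' 8-bit PNG; pixels above 127/255 are foreground. The physical pixel
#' spacing comes from a `<name>.json` sidecar (key `spacing_mm`) unless
#' given explicitly. Left-side masks are mirrored downstream, not here.
#'
#' @param path PNG path.
#' @param spacing pixel spacing in mm/px; `NULL` reads the sidecar JSON.
#' @param view `"AP"` or `"lateral"`.
#' @param bone `"femur"` or `"tibia"`.
#' @param side `"left"` or `"right"`.
#' @return A `mask_image`: list with `pixels` (logical matrix, rows = image
#'   rows top to bottom), `spacing`, `view`, `bone`, `side`.
#' @export
read_mask_png <- function(path, spacing = NULL, view = "AP", bone = "femur",
                          side = "right") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (is.null(spacing)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    if (!file.exists(sidecar))
      stop("no spacing given and no sidecar JSON found: ", sidecar)
    spacing <- jsonlite::read_json(sidecar)$spacing_mm
  }
  mask_image(img > (127 / 255), spacing = spacing, view = view, bone = bone,
             side = side)
}

#' Construct a silhouette mask object
#'
#' @param pixels logical/numeric matrix; `TRUE`/`1` is bone foreground.
#' @inheritParams read_mask_png
#' @return A `mask_image`.
#' @export
mask_image <- function(pixels, spacing, view = c("AP", "lateral"),
                       bone = c("femur", "tibia"), side = c("right", "left")) {
  view <- match.arg(view)
  bone <- match.arg(bone)
  side <- match.arg(side)
  stopifnot(is.matrix(pixels), spacing > 0)
  structure(list(pixels = pixels > 0, spacing = as.numeric(spacing),
                 view = view, bone = bone, side = side),
            class = "mask_image")
}

#' Write a mask as PNG with a spacing sidecar
#' @param mask a `mask_image`.
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  atomic_write(path, function(tmp) {
    png::writePNG(ifelse(mask$pixels, 1, 0), tmp)
  })
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  atomic_write(sidecar, function(tmp) {
    jsonlite::write_json(list(spacing_mm = mask$spacing, view = mask$view,
                              bone = mask$bone, side = mask$side),
                         tmp, auto_unbox = TRUE)
  })
  invisible(path)
}
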