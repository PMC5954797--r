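#' Read an STL file
#'
#' Reads binary or ASCII STL. STL stores every facet independently, so
#' duplicate vertices are merged (snap tolerance `tol`, default 1e-6 mm) and
#' the watertight flag is recomputed from the merged topology.
#'
#' @param path file path.
#' @param tol vertex merge tolerance in mm.
#' @return A [tri_mesh()] with attribute `watertight`.
#' @export
read_stl <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  if (length(head80) < 80) stop("STL parse error at byte 0: truncated header")
  sz <- file.size(path)
  nfac <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- (length(nfac) == 1 && sz == 84 + 50 * as.numeric(nfac))
  if (!is_binary &&
      identical(rawToChar(head80[1:5]), "solid")) {
    return(read_stl_ascii(path, tol))
  }
  if (!is_binary)
    stop("STL parse error at byte 80: declared facet count ", nfac,
         " implies size ", 84 + 50 * as.numeric(nfac),
         " bytes but file has ", sz)
  raw <- readBin(con, "raw", 50 * nfac)
  if (length(raw) != 50 * nfac)
    stop("STL parse error at byte ", 84 + length(raw),
         ": expected ", nfac, " facets")
  m <- matrix(raw, nrow = 50)
  tri <- readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12 * nfac,
                 endian = "little")
  tri <- matrix(tri, ncol = 12, byrow = TRUE)   # normal + 3 vertices
  v <- matrix(t(tri[, 4:12]), ncol = 3, byrow = TRUE)
  f <- matrix(seq_len(3 * nfac), ncol = 3, byrow = TRUE)
  mesh <- merge_vertices(tri_mesh(v, f), tol)
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}

read_stl_ascii <- function(path, tol = 1e-6) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  nfacet_open <- length(grep("^\\s*facet\\s+normal", txt))
  nfacet_close <- length(grep("^\\s*endfacet", txt))
  if (nfacet_open != nfacet_close || length(vl) != 3L * nfacet_open)
    stop("STL parse error: ", nfacet_open, " facets opened, ",
         nfacet_close, " closed, ", length(vl), " vertex lines")
  if (nfacet_open == 0L) stop("STL parse error: no facets")
  nums <- lapply(strsplit(trimws(vl), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, nums)
  if (any(!is.finite(v))) stop("STL parse error: non-numeric vertex")
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  mesh <- merge_vertices(tri_mesh(v, f), tol)
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}

#' Write an STL file
#'
#' @param mesh a non-empty [tri_mesh()]. Part structure is not representable
#'   in STL and is flattened.
#' @param path output path.
#' @param dialect `"binary"` (default; little-endian, 84 + 50 n bytes) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  u <- b - a; w <- c - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  n <- n / ifelse(len > 0, len, 1)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "printqa binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    dat <- t(cbind(n, a, b, c))            # 12 floats per facet
    block <- writeBin(as.vector(dat), raw(), size = 4, endian = "little")
    block <- matrix(block, nrow = 48)
    block <- rbind(block, matrix(as.raw(0), 2, ncol(block)))
    writeBin(as.vector(block), con)
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    nm <- if (is.null(mesh$name)) "printqa" else mesh$name
    writeLines(paste("solid", nm), con)
    fmt <- paste0(
      "facet normal %.9g %.9g %.9g\n outer loop\n",
      "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
      "  vertex %.9g %.9g %.9g\n endloop\nendfacet")
    writeLines(sprintf(fmt, n[, 1], n[, 2], n[, 3],
                       a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                       c[, 1], c[, 2], c[, 3]), con)
    writeLines(paste("endsolid", nm), con)
  }
  invisible(path)
}

# diverging blue-white-red colormap over [0, 1]
distance_colormap <- function(t) {
  t <- pmax(0, pmin(1, t))
  lo <- c(59, 76, 192); mid <- c(245, 245, 245); hi <- c(180, 4, 38)
  out <- matrix(0, length(t), 3)
  below <- t <= 0.5
  for (k in 1:3) {
    out[below, k]  <- lo[k] + (mid[k] - lo[k]) * (t[below] / 0.5)
    out[!below, k] <- mid[k] + (hi[k] - mid[k]) * ((t[!below] - 0.5) / 0.5)
  }
  round(out)
}

#' Write a color-annotated PLY file
#'
#' Writes a binary little-endian PLY with per-vertex properties
#' `x y z red green blue scalar`: the scalar channel (for example a signed
#' surface distance in mm) is preserved verbatim, and the color is the
#' diverging blue-white-red map of the scalar over `colormap_range`.
#'
#' @param mesh a [tri_mesh()].
#' @param scalars numeric vector, one value per vertex (mm).
#' @param path output path.
#' @param colormap_range length-2 numeric; scalars at or beyond the ends map
#'   to the endpoint colors. Defaults to `range(scalars)`.
#' @return `path`, invisibly.
#' @export
write_annotated_ply <- function(mesh, scalars, path, colormap_range = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (length(scalars) != nrow(mesh$vertices))
    stop("need one scalar per vertex (", nrow(mesh$vertices), "), got ",
         length(scalars))
  if (is.null(colormap_range)) colormap_range <- range(scalars)
  span <- diff(colormap_range)
  t <- if (span > 0) (scalars - colormap_range[1]) / span
       else rep(0.5, length(scalars))
  col <- distance_colormap(t)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment printqa annotated surface",
           paste("element vertex", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "property float scalar",
           paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  nv <- nrow(mesh$vertices)
  xyz <- writeBin(as.vector(t(mesh$vertices)), raw(), size = 4,
                  endian = "little")
  xyz <- matrix(xyz, nrow = 12)                 # 12 bytes per vertex
  sc <- matrix(writeBin(as.numeric(scalars), raw(), size = 4,
                        endian = "little"), nrow = 4)
  rgbraw <- matrix(as.raw(t(col)), nrow = 3)
  writeBin(as.vector(rbind(xyz, rgbraw, sc)), con)
  nf <- nrow(mesh$faces)
  fidx <- matrix(writeBin(as.vector(t(mesh$faces - 1L)), raw(), size = 4,
                          endian = "little"), nrow = 12)
  writeBin(as.vector(rbind(matrix(as.raw(3L), 1, nf), fidx)), con)
  invisible(path)
}

#' Read a PLY file written by [write_annotated_ply()]
#'
#' @param path file path.
#' @return A [tri_mesh()] with the `scalars` channel populated and an
#'   attribute `colors` (n x 3 integer matrix).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- character(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0) stop("PLY parse error: header not terminated")
      if (ch == charToRaw("\n")) break
      ln <- c(ln, rawToChar(ch))
    }
    ln <- paste(ln, collapse = "")
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  vraw <- matrix(readBin(con, "raw", 19 * nv), nrow = 19)
  V <- matrix(readBin(as.vector(vraw[1:12, ]), "numeric", size = 4,
                      n = 3 * nv, endian = "little"),
              ncol = 3, byrow = TRUE)
  C <- matrix(as.integer(vraw[13:15, ]), ncol = 3, byrow = TRUE)
  S <- readBin(as.vector(vraw[16:19, ]), "numeric", size = 4, n = nv,
               endian = "little")
  fraw <- matrix(readBin(con, "raw", 13 * nf), nrow = 13)
  if (any(as.integer(fraw[1, ]) != 3L))
    stop("PLY parse error: non-triangular face")
  F <- matrix(readBin(as.vector(fraw[2:13, ]), "integer", size = 4,
                      n = 3 * nf, endian = "little"),
              ncol = 3, byrow = TRUE) + 1L
  m <- tri_mesh(V, F, scalars = S)
  attr(m, "colors") <- C
  m
}
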