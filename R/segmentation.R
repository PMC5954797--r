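# Threshold segmentation and surface extraction. A printed model scanned in
# air has such high contrast that a single global threshold separates it;
# the iso-surface is extracted with sub-voxel interpolation (marching
# tetrahedra on the conforming 6-tet cube decomposition), which is what
# gives dimension errors well below the voxel size. Wrapping is defined
# operationally as morphological closing plus hole filling, and smoothing is
# volume-compensated so it cannot silently shrink the model.

#' Threshold segmentation
#'
#' Foreground is every voxel at or above the threshold; with `keep_largest`
#' only the largest 26-connected component is retained (a region-growing
#' surrogate that discards disconnected specks).
#'
#' @param vol a [voxel_volume()].
#' @param threshold HU threshold; must lie within the volume's value range.
#' @param keep_largest keep only the largest connected component.
#' @return An object of class `seg_mask`: logical array plus grid geometry,
#'   the threshold used, and the source protocol.
#' @export
threshold_segment <- function(vol, threshold, keep_largest = FALSE) {
  stopifnot(inherits(vol, "voxel_volume"))
  rng <- range(vol$data)
  if (threshold < rng[1] || threshold > rng[2])
    stop(sprintf(
      "threshold %g HU outside volume range [%g, %g] HU", threshold,
      rng[1], rng[2]))
  mask <- vol$data >= threshold
  if (!any(mask))
    stop(sprintf(
      "empty segmentation at threshold %g HU (volume range [%g, %g] HU)",
      threshold, rng[1], rng[2]))
  d <- dim(vol$data)
  if (keep_largest) {
    lab <- cpp_label_components(as.logical(mask), d)
    tab <- tabulate(lab[lab > 0])
    mask <- array(lab == which.max(tab), d)
  }
  structure(list(mask = array(mask, d), spacing = vol$spacing,
                 origin = vol$origin, threshold = threshold,
                 protocol = vol$protocol),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("seg_mask: %d x %d x %d voxels, %d foreground (threshold %g HU)\n",
              d[1], d[2], d[3], sum(x$mask), x$threshold))
  invisible(x)
}

#' Extract an iso-surface mesh
#'
#' Marching-tetrahedra iso-surface in world coordinates. For a binary
#' [threshold_segment()] mask the iso-level is 0.5 (surface midway between
#' foreground and background voxels); for a grayscale [voxel_volume()] pass
#' the HU iso-level explicitly (typically midway between object and
#' background HU), which recovers the surface with sub-voxel accuracy.
#'
#' @param x a `seg_mask` or [voxel_volume()].
#' @param iso_level iso value; default 0.5 for masks, required for volumes.
#' @return Watertight [tri_mesh()] with outward normals.
#' @export
extract_surface <- function(x, iso_level = NULL) {
  if (inherits(x, "seg_mask")) {
    field <- x$mask * 1.0
    if (is.null(iso_level)) iso_level <- 0.5
    fg <- x$mask
  } else if (inherits(x, "voxel_volume")) {
    if (is.null(iso_level))
      stop("iso_level is required when extracting from a grayscale volume")
    field <- x$data
    fg <- x$data >= iso_level
  } else stop("x must be a seg_mask or voxel_volume")
  if (!any(fg)) stop("no foreground at this iso level")
  d <- dim(field)
  if (any(fg[c(1, d[1]), , ]) || any(fg[, c(1, d[2]), ]) ||
      any(fg[, , c(1, d[3])]))
    stop("foreground touches the grid boundary; the surface would be open")
  # field samples live at voxel centers
  orig <- x$origin + x$spacing / 2
  res <- cpp_marching_tetra(as.numeric(field), d, orig, x$spacing,
                            iso_level)
  m <- tri_mesh(res$vertices, res$faces, name = "iso_surface")
  if (sum(face_volumes(m)) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Wrap a segmentation (morphological closing + hole fill)
#'
#' Closes the mask with a spherical structuring element of the given radius
#' (exact Euclidean distance transform, so anisotropic voxels are handled in
#' mm), then fills fully enclosed cavities. Wrapping is extensive: it can
#' bridge gaps narrower than twice the radius and swallow thin features, but
#' never removes foreground.
#'
#' @param mask a `seg_mask`.
#' @param radius structuring-element radius (mm); 0 performs hole filling
#'   only.
#' @return The wrapped `seg_mask`.
#' @export
wrap <- function(mask, radius) {
  stopifnot(inherits(mask, "seg_mask"), radius >= 0)
  d <- dim(mask$mask)
  extent <- d * mask$spacing
  if (radius > min(extent) / 4)
    stop("wrap radius ", radius, " mm exceeds a quarter of the grid extent")
  m <- mask$mask
  if (radius > 0) {
    r2 <- radius^2 + 1e-9
    dil <- array(cpp_edt_sq(as.logical(m), d, mask$spacing) <= r2, d)
    ero <- array(cpp_edt_sq(as.logical(!dil), d, mask$spacing) > r2, d)
    m <- ero
  }
  m <- array(cpp_fill_holes(as.logical(m), d), d)
  out <- mask
  out$mask <- m | mask$mask    # guard: closing is extensive by construction
  out
}

#' Volume-compensated mesh smoothing
#'
#' Taubin lambda/mu smoothing with the uniform graph Laplacian: the shrink
#' step (lambda) is followed by an inflate step (mu) each iteration, which
#' removes high-frequency surface noise while keeping the enclosed volume
#' nearly unchanged — the failure mode it avoids is the silent shrinkage of
#' naive Laplacian smoothing.
#'
#' @param mesh a [tri_mesh()].
#' @param iterations number of lambda/mu passes; 0 returns the mesh
#'   unchanged.
#' @param strength scales the lambda/mu step sizes (0 to 1].
#' @return The smoothed [tri_mesh()]; topology is preserved.
#' @export
smooth_mesh <- function(mesh, iterations = 10, strength = 1) {
  stopifnot(inherits(mesh, "tri_mesh"), iterations >= 0,
            strength > 0, strength <= 1)
  if (iterations == 0 || nrow(mesh$faces) == 0) return(mesh)
  lambda <- 0.33 * strength
  mu <- -0.34 * strength
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = rep(nrow(mesh$vertices), 2))
  A <- (A > 0) * 1
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- A / deg
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(W %*% V) - V)
    V <- V + mu * (as.matrix(W %*% V) - V)
  }
  out <- mesh
  out$vertices <- V
  out
}

#' Mask boundary contours on one slice
#'
#' Marching-squares contours of the mask on an axial, coronal or sagittal
#' slice, in world mm coordinates, for overlay on the source image. Corner
#' values are averaged from the adjacent voxels, which anti-aliases the
#' binary mask and places contours with sub-voxel accuracy.
#'
#' @param mask a `seg_mask`.
#' @param plane `"axial"` (z index), `"coronal"` (y) or `"sagittal"` (x).
#' @param index 1-based slice index.
#' @return List of closed contours; each is an n x 2 matrix of the two
#'   in-plane world coordinates (mm). Attribute `plane_axes` names the
#'   columns.
#' @export
overlay_contours <- function(mask, plane = c("axial", "coronal", "sagittal"),
                             index) {
  stopifnot(inherits(mask, "seg_mask"))
  plane <- match.arg(plane)
  ax <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  d <- dim(mask$mask)
  if (index < 1 || index > d[ax])
    stop("slice index ", index, " out of range 1..", d[ax])
  sl <- switch(plane,
               axial = mask$mask[, , index],
               coronal = mask$mask[, index, ],
               sagittal = mask$mask[index, , ])
  keep <- setdiff(1:3, ax)
  sp <- mask$spacing[keep]
  or <- mask$origin[keep]
  contours <- marching_squares(sl * 1.0, 0.5)
  out <- lapply(contours, function(cc)
    cbind(or[1] + cc[, 1] * sp[1], or[2] + cc[, 2] * sp[2]))
  attr(out, "plane_axes") <- c("x", "y", "z")[keep]
  out
}

# marching squares at `iso` on corner-sampled field (zero-padded outside);
# returns contours in voxel units (voxel centers at 0.5, 1.5, ...)
marching_squares <- function(img, iso) {
  nx <- nrow(img); ny <- ncol(img)
  pad <- matrix(0, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- img
  # corner lattice: value at corner (i, j) averages the 4 adjacent voxels
  cor <- (pad[1:(nx + 1), 1:(ny + 1)] + pad[2:(nx + 2), 1:(ny + 1)] +
          pad[1:(nx + 1), 2:(ny + 2)] + pad[2:(nx + 2), 2:(ny + 2)]) / 4
  nxc <- nx + 1; nyc <- ny + 1
  segs <- list()
  interp <- function(p1, v1, p2, v2) p1 + (iso - v1) / (v2 - v1) * (p2 - p1)
  for (j in seq_len(nyc - 1)) {
    for (i in seq_len(nxc - 1)) {
      v <- c(cor[i, j], cor[i + 1, j], cor[i + 1, j + 1], cor[i, j + 1])
      inside <- v > iso
      if (all(inside) || !any(inside)) next
      # corner positions in voxel-center units
      p <- rbind(c(i - 1.5, j - 1.5), c(i - 0.5, j - 1.5),
                 c(i - 0.5, j - 0.5), c(i - 1.5, j - 0.5))
      eg <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
      cut <- which(vapply(eg, function(e) xor(inside[e[1]], inside[e[2]]),
                          TRUE))
      pts <- lapply(cut, function(k) {
        e <- eg[[k]]
        interp(p[e[1], ], v[e[1]], p[e[2], ], v[e[2]])
      })
      if (length(cut) == 2) {
        segs[[length(segs) + 1]] <- rbind(pts[[1]], pts[[2]])
      } else if (length(cut) == 4) {
        # saddle: split by the cell-center value
        ctr <- mean(v)
        if ((ctr > iso) == inside[1]) {
          segs[[length(segs) + 1]] <- rbind(pts[[1]], pts[[2]])
          segs[[length(segs) + 1]] <- rbind(pts[[3]], pts[[4]])
        } else {
          segs[[length(segs) + 1]] <- rbind(pts[[1]], pts[[4]])
          segs[[length(segs) + 1]] <- rbind(pts[[2]], pts[[3]])
        }
      }
    }
  }
  segs <- Filter(function(s) sum((s[1, ] - s[2, ])^2) > 1e-12, segs)
  loops <- chain_segments(segs)
  Filter(function(l) nrow(l) >= 3, loops)
}

# join segments into closed polylines; segment endpoint order is arbitrary,
# so both endpoints are indexed and segments are reversed as needed
chain_segments <- function(segs, tol = 1e-6) {
  if (!length(segs)) return(list())
  key <- function(p) paste(round(p[1] / tol), round(p[2] / tol))
  index <- new.env(hash = TRUE)
  push <- function(p, k) assign(key(p), c(get0(key(p), envir = index), k),
                                envir = index)
  for (k in seq_along(segs)) {
    push(segs[[k]][1, ], k)
    push(segs[[k]][2, ], k)
  }
  used <- logical(length(segs))
  loops <- list()
  for (k in seq_along(segs)) {
    if (used[k]) next
    used[k] <- TRUE
    loop <- segs[[k]]
    repeat {
      endp <- loop[nrow(loop), ]
      cand <- get0(key(endp), envir = index)
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      nk <- cand[1]
      used[nk] <- TRUE
      s <- segs[[nk]]
      nxt <- if (sum((s[1, ] - endp)^2) <= sum((s[2, ] - endp)^2))
        s[2, , drop = FALSE] else s[1, , drop = FALSE]
      if (sum((nxt - loop[1, ])^2) < (10 * tol)^2) break   # closed
      loop <- rbind(loop, nxt)
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}
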