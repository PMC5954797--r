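#' Triangle mesh objects
#'
#' A `tri_mesh` stores vertices (mm, world coordinates) and triangular faces.
#' A mesh may consist of several closed *parts*; each part carries a sign:
#' `+1` for solid material and `-1` for a cavity subtracted from the solids.
#' This lightweight constructive representation lets phantom components such
#' as a base plate with recessed test shapes stay exactly parametric: every
#' inside/outside query and the voxelizer resolve the union of positive parts
#' minus the union of negative parts.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices,
#'   consistently wound so that face normals point out of the enclosed solid.
#' @param part optional integer vector, one entry per face, assigning faces to
#'   parts (default: a single part).
#' @param part_sign optional integer vector, one entry per part, `+1` or `-1`.
#' @param part_names optional character vector naming each part.
#' @param scalars optional numeric per-vertex scalar channel (mm), e.g. a
#'   signed distance map.
#' @param name optional name tag.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, part = NULL, part_sign = NULL,
                     part_names = NULL, scalars = NULL, name = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(vertices) > 0 && !all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (is.null(part)) part <- rep.int(1L, nrow(faces))
  part <- as.integer(part)
  if (length(part) != nrow(faces)) stop("one part id per face required")
  np <- if (length(part)) max(part) else 1L
  if (is.null(part_sign)) part_sign <- rep.int(1L, np)
  part_sign <- as.integer(part_sign)
  if (length(part_sign) != np) stop("one sign per part required")
  if (!all(part_sign %in% c(-1L, 1L))) stop("part signs must be +1 or -1")
  if (!is.null(scalars) && length(scalars) != nrow(vertices))
    stop("one scalar per vertex required")
  structure(
    list(vertices = vertices, faces = faces, part = part,
         part_sign = part_sign, part_names = part_names,
         scalars = scalars, name = name),
    class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat(sprintf("  %d vertices, %d faces, %d part(s)\n",
              nrow(x$vertices), nrow(x$faces), length(x$part_sign)))
  m <- measure(x)
  cat(sprintf("  bbox [%s] to [%s] mm\n",
              paste(sprintf("%.3f", m$bbox[1, ]), collapse = ", "),
              paste(sprintf("%.3f", m$bbox[2, ]), collapse = ", ")))
  cat(sprintf("  area %.3f mm^2, volume %s, watertight: %s\n",
              m$area,
              if (is.na(m$volume)) "undefined (not watertight)"
              else sprintf("%.3f mm^3", m$volume),
              m$watertight))
  invisible(x)
}

faces0 <- function(mesh) {
  f <- mesh$faces - 1L
  storage.mode(f) <- "integer"
  f
}

#' Extract one named part of a mesh as a standalone mesh
#'
#' @param mesh a [tri_mesh()].
#' @param name part name (see `part_names`).
#' @return A `tri_mesh` holding only that part, with unreferenced vertices
#'   dropped.
#' @export
mesh_part <- function(mesh, name) {
  if (is.null(mesh$part_names)) stop("mesh has no named parts")
  ids <- which(mesh$part_names == name)
  if (!length(ids)) stop("no part named '", name, "'")
  keep <- mesh$part %in% ids
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[f], ncol = 3),
           part = match(mesh$part[keep], ids),
           part_sign = mesh$part_sign[ids],
           part_names = rep(name, length(ids)),
           name = name)
}

#' Concatenate meshes into one multi-part mesh
#'
#' @param ... `tri_mesh` objects (or a single list of them).
#' @param signs optional integer vector of part signs, one per input mesh
#'   (inputs with several parts keep their own signs and are re-signed only
#'   if a sign is given).
#' @param names optional character vector of part names, one per input.
#' @param name name tag of the combined mesh.
#' @return A `tri_mesh` whose parts are the inputs.
#' @export
mesh_concat <- function(..., signs = NULL, names = NULL, name = NULL) {
  ms <- list(...)
  if (length(ms) == 1L && !inherits(ms[[1]], "tri_mesh")) ms <- ms[[1]]
  V <- NULL; F <- NULL; part <- integer(0)
  psign <- integer(0); pnames <- character(0)
  voff <- 0L; poff <- 0L
  for (i in seq_along(ms)) {
    m <- ms[[i]]
    V <- rbind(V, m$vertices)
    F <- rbind(F, m$faces + voff)
    part <- c(part, m$part + poff)
    s <- m$part_sign
    if (!is.null(signs)) s <- rep.int(as.integer(signs[i]), length(s))
    psign <- c(psign, s)
    nm <- if (!is.null(names)) rep.int(names[i], length(s))
          else if (!is.null(m$part_names)) m$part_names
          else rep.int(if (is.null(m$name)) paste0("part", i) else m$name,
                       length(s))
    pnames <- c(pnames, nm)
    voff <- voff + nrow(m$vertices)
    poff <- poff + length(s)
  }
  tri_mesh(V, F, part, psign, part_names = pnames, name = name)
}

# per-face contributions to the divergence-theorem volume
face_volumes <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
   a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

face_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Watertightness check
#'
#' A mesh is watertight when, within every part, each undirected edge is
#' shared by exactly two faces and each directed edge occurs once (consistent
#' winding).
#'
#' @param mesh a [tri_mesh()].
#' @return logical flag.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  for (p in seq_along(mesh$part_sign)) {
    F <- mesh$faces[mesh$part == p, , drop = FALSE]
    if (nrow(F) == 0L) next
    e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (any(table(undirected) != 2L)) return(FALSE)
    directed <- paste(e[, 1], e[, 2])
    if (anyDuplicated(directed)) return(FALSE)
  }
  TRUE
}

#' Caliper-style mesh measurements
#'
#' Reports the axis-aligned bounding box, surface area, enclosed volume (by
#' the divergence theorem, summed over parts with their signs) and the
#' watertight flag. The volume of a non-watertight mesh is undefined and
#' returned as `NA` with a warning.
#'
#' @param mesh a non-empty [tri_mesh()].
#' @return A list with elements `bbox` (2 x 3 matrix, min and max corner),
#'   `area` (mm^2), `volume` (mm^3 or `NA`), and `watertight`.
#' @export
measure <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$vertices) == 0L) stop("mesh is empty")
  bbox <- rbind(min = apply(mesh$vertices, 2, min),
                max = apply(mesh$vertices, 2, max))
  colnames(bbox) <- c("x", "y", "z")
  wt <- is_watertight(mesh)
  vol <- NA_real_
  if (wt) {
    fv <- face_volumes(mesh)
    vol <- sum(fv * mesh$part_sign[mesh$part])
  } else {
    warning("mesh is not watertight; enclosed volume is undefined")
  }
  list(bbox = bbox, area = sum(face_areas(mesh)), volume = vol,
       watertight = wt)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1 within
#'   1e-6).
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang * 180 / pi, x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.vector(t(tf$rotation) %*% tf$translation))
}

#' Compose rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @return The composed transform.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex to `R v + t`; topology, parts and scalars are unchanged.
#'
#' @param mesh a [tri_mesh()].
#' @param tf a [rigid_transform()].
#' @return The transformed mesh.
#' @export
apply_transform <- function(mesh, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  v <- mesh$vertices %*% t(tf$rotation)
  v <- sweep(v, 2, tf$translation, "+")
  out <- mesh
  out$vertices <- v
  out
}

#' Translate a mesh
#' @param mesh a [tri_mesh()].
#' @param offset length-3 numeric (mm).
#' @return The translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  apply_transform(mesh, rigid_transform(diag(3), offset))
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 direction (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# merge vertices closer than tol (snap-to-grid); returns a remapped mesh
merge_vertices <- function(mesh, tol = 1e-6) {
  if (nrow(mesh$vertices) == 0L) return(mesh)
  key <- round(mesh$vertices / tol)
  o <- do.call(order, as.data.frame(key))
  k <- key[o, , drop = FALSE]
  newgrp <- c(TRUE, rowSums(abs(k[-1, , drop = FALSE] -
                                k[-nrow(k), , drop = FALSE])) > 0)
  grp <- cumsum(newgrp)
  remap <- integer(nrow(mesh$vertices))
  remap[o] <- grp
  first <- o[newgrp]
  v <- mesh$vertices[first, , drop = FALSE]
  f <- matrix(remap[mesh$faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  sc <- if (!is.null(mesh$scalars)) mesh$scalars[first] else NULL
  tri_mesh(v, f[keep, , drop = FALSE], mesh$part[keep],
           mesh$part_sign, mesh$part_names, scalars = sc, name = mesh$name)
}

# inside-solid test honoring part signs
points_inside <- function(mesh, points) {
  cpp_inside(mesh$vertices, faces0(mesh), mesh$part, mesh$part_sign,
             as.matrix(points))
}
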