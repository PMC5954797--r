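# Parametric watertight primitives. Conventions: solids sit with their base
# on z = 0 unless noted; circular cross-sections place vertices at angle 0,
# so bounding boxes hit the nominal diameters exactly; segment counts are
# chosen from the chord-error budget (default 0.01 mm) and rounded up to a
# multiple of 4 so the +-x / +-y extremes are sampled exactly.

segments_for_radius <- function(r, chord = 0.01) {
  if (r <= 0) return(8L)
  n <- ceiling(pi / acos(max(-1, min(1, 1 - chord / r))))
  max(16L, as.integer(4L * ceiling(n / 4)))
}

circle_ring <- function(r, n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

# triangulate a closed ring fan around a center vertex; ring and center are
# vertex indices; flip controls winding
fan_faces <- function(center, ring, flip = FALSE) {
  n <- length(ring)
  nxt <- c(ring[-1], ring[1])
  if (flip) cbind(center, nxt, ring) else cbind(center, ring, nxt)
}

# quad strip between two rings of equal length (side wall), outward when
# ring2 is above ring1 and both are counterclockwise seen from +z
strip_faces <- function(ring1, ring2) {
  n <- length(ring1)
  a <- ring1; b <- c(ring1[-1], ring1[1])
  c2 <- ring2; d <- c(ring2[-1], ring2[1])
  rbind(cbind(a, b, d), cbind(a, d, c2))
}

#' Axis-aligned box primitive
#' @param lo,hi opposite corners (mm).
#' @param name optional name.
#' @return Watertight [tri_mesh()].
#' @export
prim_box <- function(lo, hi, name = NULL) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  tri_mesh(v, f, name = name)
}

# generic solid of revolution-by-rings: rings is a list of list(r=, z=);
# r == 0 collapses to an apex vertex. Closed with caps at both ends.
lathe_solid <- function(rings, n, name = NULL) {
  V <- NULL; ids <- list()
  for (k in seq_along(rings)) {
    rk <- rings[[k]]
    if (rk$r <= 0) {
      V <- rbind(V, c(0, 0, rk$z))
      ids[[k]] <- nrow(V)
    } else {
      ring <- cbind(circle_ring(rk$r, n), rk$z)
      V <- rbind(V, ring)
      ids[[k]] <- (nrow(V) - n + 1):nrow(V)
    }
  }
  F <- NULL
  # bottom cap
  if (length(ids[[1]]) > 1) {
    V <- rbind(V, c(0, 0, rings[[1]]$z))
    F <- rbind(F, fan_faces(nrow(V), ids[[1]], flip = TRUE))
  }
  for (k in seq_len(length(rings) - 1)) {
    a <- ids[[k]]; b <- ids[[k + 1]]
    if (length(a) > 1 && length(b) > 1) F <- rbind(F, strip_faces(a, b))
    else if (length(a) > 1) F <- rbind(F, fan_faces(b, a))
    else F <- rbind(F, fan_faces(a, b, flip = TRUE))
  }
  nlast <- length(rings)
  if (length(ids[[nlast]]) > 1) {
    V <- rbind(V, c(0, 0, rings[[nlast]]$z))
    F <- rbind(F, fan_faces(nrow(V), ids[[nlast]]))
  }
  m <- tri_mesh(V, F, name = name)
  if (sum(face_volumes(m)) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Cylinder primitive (axis z, base at z = 0)
#' @param diameter,height dimensions in mm.
#' @param chord tessellation chord error (mm).
#' @param name optional name.
#' @return Watertight [tri_mesh()].
#' @export
prim_cylinder <- function(diameter, height, chord = 0.01, name = NULL) {
  r <- diameter / 2
  n <- segments_for_radius(r, chord)
  lathe_solid(list(list(r = r, z = 0), list(r = r, z = height)), n, name)
}

#' Conical frustum primitive (axis z, base at z = 0)
#' @param d_bottom,d_top,height dimensions in mm; either diameter may be 0
#'   (true cone apex).
#' @param chord tessellation chord error (mm).
#' @param name optional name.
#' @return Watertight [tri_mesh()].
#' @export
prim_frustum <- function(d_bottom, d_top, height, chord = 0.01, name = NULL) {
  n <- segments_for_radius(max(d_bottom, d_top) / 2, chord)
  lathe_solid(list(list(r = d_bottom / 2, z = 0),
                   list(r = d_top / 2, z = height)), n, name)
}

#' Sphere primitive (centered at the origin)
#' @param diameter mm.
#' @param chord tessellation chord error (mm).
#' @param name optional name.
#' @return Watertight [tri_mesh()].
#' @export
prim_sphere <- function(diameter, chord = 0.01, name = NULL) {
  r <- diameter / 2
  n <- segments_for_radius(r, chord)
  nth <- as.integer(max(8, 2 * ceiling(n / 4)))   # even: equator included
  th <- seq(0, pi, length.out = nth + 1)
  rings <- lapply(th, function(t) list(r = r * sin(t), z = r * cos(t)))
  rings[[1]]$r <- 0; rings[[nth + 1]]$r <- 0
  lathe_solid(rings, n, name)
}

#' Semi-sphere (dome) primitive: flat face on z = 0, dome up
#' @param diameter mm.
#' @param chord tessellation chord error (mm).
#' @param name optional name.
#' @param down if `TRUE`, the dome points down (flat face on top at z = 0).
#' @return Watertight [tri_mesh()].
#' @export
prim_dome <- function(diameter, chord = 0.01, name = NULL, down = FALSE) {
  r <- diameter / 2
  n <- segments_for_radius(r, chord)
  nth <- max(4L, as.integer(ceiling(n / 4)))
  th <- seq(0, pi / 2, length.out = nth + 1)     # equator up to pole
  rings <- lapply(th, function(t) list(r = r * cos(t), z = r * sin(t)))
  rings[[nth + 1]]$r <- 0
  m <- lathe_solid(rings, n, name)
  if (down) {
    m$vertices[, 3] <- -m$vertices[, 3]
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}

#' Hexagonal prism primitive (axis z, base at z = 0)
#'
#' `width` is the across-flats width; two flats are normal to the x axis so
#' the x-extent of the bounding box equals `width` exactly.
#' @param width,height mm.
#' @param name optional name.
#' @return Watertight [tri_mesh()].
#' @export
prim_hexprism <- function(width, height, name = NULL) {
  rc <- width / sqrt(3)                           # circumradius
  th <- pi / 6 + (0:5) * pi / 3                   # flats normal to x
  ring <- cbind(rc * cos(th), rc * sin(th))
  V <- rbind(cbind(ring, 0), cbind(ring, height), c(0, 0, 0), c(0, 0, height))
  bot <- 1:6; top <- 7:12
  F <- rbind(fan_faces(13, bot, flip = TRUE), strip_faces(bot, top),
             fan_faces(14, top))
  tri_mesh(V, F, name = name)
}

# parallel-transport frames along a polyline path (n x 3)
path_frames <- function(path) {
  np <- nrow(path)
  tang <- matrix(0, np, 3)
  tang[1, ] <- path[2, ] - path[1, ]
  tang[np, ] <- path[np, ] - path[np - 1, ]
  if (np > 2)
    tang[2:(np - 1), ] <- path[3:np, , drop = FALSE] -
      path[1:(np - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  u <- matrix(0, np, 3); w <- matrix(0, np, 3)
  ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u[1, ] <- ref - sum(ref * tang[1, ]) * tang[1, ]
  u[1, ] <- u[1, ] / sqrt(sum(u[1, ]^2))
  w[1, ] <- crossv(tang[1, ], u[1, ])
  for (i in 2:np) {
    # rotate previous frame onto the new tangent (double-reflection method)
    v1 <- path[i, ] - path[i - 1, ]
    c1 <- sum(v1 * v1)
    rl <- u[i - 1, ] - (2 / c1) * sum(v1 * u[i - 1, ]) * v1
    tl <- tang[i - 1, ] - (2 / c1) * sum(v1 * tang[i - 1, ]) * v1
    v2 <- tang[i, ] - tl
    c2 <- sum(v2 * v2)
    u[i, ] <- if (c2 > 1e-12) rl - (2 / c2) * sum(v2 * rl) * v2 else rl
    u[i, ] <- u[i, ] - sum(u[i, ] * tang[i, ]) * tang[i, ]
    u[i, ] <- u[i, ] / sqrt(sum(u[i, ]^2))
    w[i, ] <- crossv(tang[i, ], u[i, ])
  }
  list(t = tang, u = u, w = w)
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Tube swept along a polyline
#'
#' Sweeps a circular (optionally annular) cross-section along an open path
#' using parallel-transport frames; ends are capped (with annular caps when
#' `d_inner > 0`), producing a closed solid: the wall of a hollow duct.
#'
#' @param path n x 3 matrix of centerline points (mm).
#' @param d_outer outer diameter (mm).
#' @param d_inner inner diameter (mm); 0 for a solid rod.
#' @param chord tessellation chord error (mm).
#' @param name optional name.
#' @return Watertight [tri_mesh()].
#' @export
prim_tube <- function(path, d_outer, d_inner = 0, chord = 0.01, name = NULL) {
  path <- as.matrix(path)
  ro <- d_outer / 2; ri <- d_inner / 2
  n <- segments_for_radius(ro, chord)
  fr <- path_frames(path)
  np <- nrow(path)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ringat <- function(i, r) {
    ctr <- path[i, ]
    t(ctr + t(outer(cos(th), fr$u[i, ]) + outer(sin(th), fr$w[i, ])) * r)
  }
  V <- NULL; outer_ids <- list(); inner_ids <- list()
  for (i in seq_len(np)) {
    V <- rbind(V, ringat(i, ro))
    outer_ids[[i]] <- (nrow(V) - n + 1):nrow(V)
  }
  if (ri > 0) {
    for (i in seq_len(np)) {
      V <- rbind(V, ringat(i, ri))
      inner_ids[[i]] <- (nrow(V) - n + 1):nrow(V)
    }
  }
  F <- NULL
  for (i in seq_len(np - 1))
    F <- rbind(F, strip_faces(outer_ids[[i]], outer_ids[[i + 1]]))
  if (ri > 0) {
    for (i in seq_len(np - 1))                   # inner wall, inward normal
      F <- rbind(F, strip_faces(inner_ids[[i + 1]], inner_ids[[i]]))
    # annular end caps, oriented along -t (start) and +t (end)
    cap_or <- function(ids_in, ids_out, want_dir) {
      cf <- strip_faces(ids_in, ids_out)
      a <- V[cf[1, 1], ]; b <- V[cf[1, 2], ]; c2 <- V[cf[1, 3], ]
      nvec <- crossv(b - a, c2 - a)
      if (sum(nvec * want_dir) < 0) cf <- cf[, c(1, 3, 2)]
      cf
    }
    F <- rbind(F, cap_or(inner_ids[[1]], outer_ids[[1]], -fr$t[1, ]),
               cap_or(inner_ids[[np]], outer_ids[[np]], fr$t[np, ]))
  } else {
    V <- rbind(V, path[1, ], path[np, ])
    F <- rbind(F, fan_faces(nrow(V) - 1L, outer_ids[[1]], flip = TRUE),
               fan_faces(nrow(V), outer_ids[[np]]))
  }
  m <- tri_mesh(V, F, name = name)
  # enforce outward global winding
  fv <- sum(face_volumes(m))
  if (fv < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Block with one sinusoidal period as its top surface
#'
#' A rectangular block (footprint `length` x `width`, y along `length`) whose
#' top surface is one full sine period along y: z from
#' `depth - height` ... `depth`. Used for the concave/convex curvature test
#' surface.
#'
#' @param length,width footprint (mm).
#' @param height peak-to-valley amplitude of the surface (mm).
#' @param depth total envelope height of the block (mm).
#' @param ny,nx surface sampling density.
#' @param name optional name.
#' @return Watertight [tri_mesh()].
#' @export
prim_sine_block <- function(length, width, height, depth,
                            ny = 201, nx = 13, name = NULL) {
  xs <- seq(-width / 2, width / 2, length.out = nx)
  ys <- seq(0, length, length.out = ny)
  # peak at L/4, valley at 3L/4; exact peak/valley sampled when (ny-1) %% 4 == 0
  ztop <- function(y) depth - height / 2 + (height / 2) * sin(2 * pi * y / length)
  nvtop <- nx * ny
  Vt <- cbind(rep(xs, times = ny), rep(ys, each = nx),
              ztop(rep(ys, each = nx)))
  Vb <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  V <- rbind(Vt, Vb)
  idx <- function(i, j) (j - 1L) * nx + i         # top sheet
  F <- NULL
  quads <- NULL
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- idx(i, j); b <- idx(i + 1, j); c2 <- idx(i + 1, j + 1); d <- idx(i, j + 1)
  F <- rbind(cbind(a, b, c2), cbind(a, c2, d))                 # top (up)
  F <- rbind(F, cbind(a, c2, b) + nvtop, cbind(a, d, c2) + nvtop)  # bottom
  # side walls
  e1 <- idx(seq_len(nx - 1), 1); e1n <- idx(seq_len(nx - 1) + 1, 1)
  e2 <- idx(seq_len(nx - 1), ny); e2n <- idx(seq_len(nx - 1) + 1, ny)
  F <- rbind(F,
             cbind(e1, e1 + nvtop, e1n), cbind(e1n, e1 + nvtop, e1n + nvtop),
             cbind(e2, e2n, e2 + nvtop), cbind(e2n, e2n + nvtop, e2 + nvtop))
  s1 <- idx(1, seq_len(ny - 1)); s1n <- idx(1, seq_len(ny - 1) + 1)
  s2 <- idx(nx, seq_len(ny - 1)); s2n <- idx(nx, seq_len(ny - 1) + 1)
  F <- rbind(F,
             cbind(s1, s1n, s1 + nvtop), cbind(s1n, s1n + nvtop, s1 + nvtop),
             cbind(s2, s2 + nvtop, s2n), cbind(s2n, s2 + nvtop, s2n + nvtop))
  m <- tri_mesh(V, F, name = name)
  if (sum(face_volumes(m)) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}
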