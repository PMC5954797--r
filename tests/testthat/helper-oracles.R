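# Independent brute-force oracles used to cross-check the accelerated
# geometry paths. These stay deliberately naive: every triangle is tested
# for every query, and morphology enumerates the structuring element.

# exact distance from one point to every triangle (vectorized Ericson
# region test), returning the minimum
brute_point_mesh_distance <- function(p, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  P <- matrix(p, nrow(A), 3, byrow = TRUE)
  ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  best <- rep(Inf, nrow(A))
  upd <- function(best, Q) pmin(best, sqrt(rowSums((Q - P)^2)))
  # vertex regions
  best <- ifelse(d1 <= 0 & d2 <= 0, sqrt(rowSums((A - P)^2)), best)
  best <- ifelse(d3 >= 0 & d4 <= d3, pmin(best, sqrt(rowSums((B - P)^2))),
                 best)
  best <- ifelse(d6 >= 0 & d5 <= d6, pmin(best, sqrt(rowSums((C - P)^2))),
                 best)
  # edge AB
  sel <- vc <= 0 & d1 >= 0 & d3 <= 0
  v <- ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0)
  best <- ifelse(sel, pmin(best, sqrt(rowSums((A + ab * v - P)^2))), best)
  # edge AC
  sel <- vb <= 0 & d2 >= 0 & d6 <= 0
  w <- ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0)
  best <- ifelse(sel, pmin(best, sqrt(rowSums((A + ac * w - P)^2))), best)
  # edge BC
  sel <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  w <- ifelse((d4 - d3) + (d5 - d6) != 0,
              (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)
  best <- ifelse(sel, pmin(best, sqrt(rowSums((B + (C - B) * w - P)^2))),
                 best)
  # face interior
  denom <- va + vb + vc
  sel <- va > 0 & vb > 0 & vc > 0
  v <- vb / denom; w <- vc / denom
  Q <- A + ab * v + ac * w
  best <- ifelse(sel, pmin(best, sqrt(rowSums((Q - P)^2))), best)
  min(best)
}

# spherical-structuring-element dilation/erosion by explicit offset
# enumeration (small grids only)
ball_offsets <- function(radius, spacing) {
  rr <- ceiling(radius / spacing)
  g <- expand.grid(dx = -rr[1]:rr[1], dy = -rr[2]:rr[2], dz = -rr[3]:rr[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= radius^2 + 1e-9, ])
}

brute_dilate <- function(mask, radius, spacing = c(1, 1, 1)) {
  off <- ball_offsets(radius, spacing)
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    p <- idx
    p[, 1] <- p[, 1] + off[k, 1]
    p[, 2] <- p[, 2] + off[k, 2]
    p[, 3] <- p[, 3] + off[k, 3]
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    out[p[ok, , drop = FALSE]] <- TRUE
  }
  out
}

brute_erode <- function(mask, radius, spacing = c(1, 1, 1)) {
  !brute_dilate(!mask, radius, spacing)
}

brute_close <- function(mask, radius, spacing = c(1, 1, 1)) {
  brute_erode(brute_dilate(mask, radius, spacing), radius, spacing)
}

# random closed test meshes (spheres, boxes, frustums under random rigid
# transforms and scalings), face count kept small for brute-force oracles
random_test_mesh <- function(seed) {
  set.seed(seed)
  kind <- sample(3, 1)
  m <- switch(kind,
              prim_sphere(runif(1, 4, 12), chord = 0.5),
              prim_box(c(0, 0, 0), runif(3, 3, 12)),
              prim_frustum(runif(1, 5, 10), runif(1, 1, 4),
                           runif(1, 3, 10), chord = 0.5))
  ax <- rnorm(3)
  tf <- rigid_transform(rotation_about_axis(ax, runif(1, 0, pi)),
                        rnorm(3, 0, 5))
  apply_transform(m, tf)
}

# smooth, asymmetric, bone-like reference object: a warped sphere
organic_reference <- function(diameter = 24, seed = 42, chord = 0.01) {
  warp_mesh(prim_sphere(diameter, chord = chord),
            print_error_model(warp_amplitude = diameter / 16,
                              warp_wavelength = diameter,
                              seed = seed))$mesh
}

random_rigid <- function(seed, max_angle_deg = 20, max_translation = 20) {
  set.seed(seed)
  ax <- rnorm(3)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  rigid_transform(
    rotation_about_axis(ax, runif(1, 0.2, max_angle_deg) * pi / 180),
    dir * runif(1, 0.2, max_translation))
}

expect_watertight <- function(mesh) {
  expect_true(is_watertight(mesh))
  expect_gt(measure(mesh)$volume, 0)
}
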