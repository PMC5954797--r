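# Synthetic print-error generator: stands in for the physical printer so
# the whole validation chain can be exercised closed-loop against known
# ground truth. Errors modeled: uniform surface offset (over/under
# deposition), smooth sinusoidal warp (deformation), rigid misplacement,
# and loss of thin features (morphological opening), each seeded and
# recorded.

#' Print-error model
#'
#' @param offset uniform signed surface offset (mm); positive grows the
#'   part.
#' @param warp_amplitude peak displacement of the sinusoidal warp field
#'   (mm).
#' @param warp_wavelength wavelength of the warp field (mm); the amplitude
#'   must stay below a tenth of it (no-fold regime).
#' @param misplace_angle rigid misplacement rotation bound (degrees).
#' @param misplace_translation rigid misplacement translation bound (mm).
#' @param min_feature minimum printable feature diameter (mm); thinner
#'   protrusions are lost.
#' @param voxel voxel pitch of the morphological operations (mm).
#' @param seed random seed (phases and misplacement).
#' @return Object of class `print_error_model`.
#' @export
print_error_model <- function(offset = 0, warp_amplitude = 0,
                              warp_wavelength = 20, misplace_angle = 0,
                              misplace_translation = 0, min_feature = 0,
                              voxel = 0.05, seed = 1L) {
  stopifnot(warp_wavelength > 0, min_feature >= 0, voxel > 0)
  if (warp_amplitude < 0) stop("warp amplitude must be non-negative")
  structure(list(offset = offset, warp_amplitude = warp_amplitude,
                 warp_wavelength = warp_wavelength,
                 misplace_angle = misplace_angle,
                 misplace_translation = misplace_translation,
                 min_feature = min_feature, voxel = voxel,
                 seed = as.integer(seed)),
            class = "print_error_model")
}

# signed-distance field of a mesh on a voxel grid: coarse EDT everywhere,
# exact point-to-surface distances in a narrow band around the `iso` level
signed_field <- function(mesh, voxel, band_center = 0, band_halfwidth = NULL) {
  pad <- abs(band_center) + 10 * voxel
  lo <- apply(mesh$vertices, 2, min) - pad
  hi <- apply(mesh$vertices, 2, max) + pad
  sp <- rep(voxel, 3)
  dims <- as.integer(ceiling((hi - lo) / sp))
  occ <- cpp_voxelize(mesh$vertices, faces0(mesh), mesh$part,
                      mesh$part_sign, lo, sp, dims, 1L)
  maskv <- occ >= 0.5
  d_in <- sqrt(cpp_edt_sq(maskv, dims, sp))       # distance to foreground
  d_out <- sqrt(cpp_edt_sq(!maskv, dims, sp))     # distance to background
  sdf <- d_in - d_out                             # negative inside
  if (is.null(band_halfwidth)) band_halfwidth <- 6 * voxel
  band <- which(abs(sdf - band_center) <= band_halfwidth)
  if (length(band)) {
    centers <- arrayInd(band, dims)
    pts <- sweep(sweep(centers - 0.5, 2, sp, "*"), 2, lo, "+")
    dd <- cpp_closest_point(mesh$vertices, faces0(mesh), pts)$distance
    inside <- points_inside(mesh, pts)
    sdf[band] <- ifelse(inside, -dd, dd)
  }
  list(sdf = sdf, dims = dims, origin = lo, spacing = sp, occ = occ)
}

#' Uniformly offset a mesh surface
#'
#' Surface offset by voxel morphology: a signed-distance field is sampled
#' on a fine grid (exact point-to-surface distances in a band around the
#' offset level) and the `d` level set is re-extracted. Positive `d` grows
#' the part, negative shrinks it.
#'
#' @param mesh watertight [tri_mesh()].
#' @param d signed offset (mm).
#' @param voxel grid pitch (mm); keep an order of magnitude below the
#'   errors of interest.
#' @return The offset [tri_mesh()].
#' @export
offset_mesh <- function(mesh, d, voxel = 0.05) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is_watertight(mesh)) stop("offset requires a watertight mesh")
  sf <- signed_field(mesh, voxel, band_center = d)
  if (!any(sf$sdf < d))
    stop("offset ", d, " mm annihilates the mesh")
  # marching expects inside = value > iso; inside solid has sdf < d
  res <- cpp_marching_tetra(-sf$sdf, sf$dims,
                            sf$origin + sf$spacing / 2, sf$spacing, -d)
  if (nrow(res$faces) == 0) stop("offset ", d, " mm annihilates the mesh")
  m <- tri_mesh(res$vertices, res$faces, name = mesh$name)
  if (sum(face_volumes(m)) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Warp a mesh with a smooth sinusoidal displacement field
#'
#' Displaces vertices by a sum of three axis-aligned sinusoids with seeded
#' random phases, rescaled so the peak displacement equals the model
#' amplitude; the exact per-vertex ground-truth displacement is returned
#' for recovery tests. Fields violating the no-fold regime (amplitude
#' >= wavelength / 10) are refused.
#'
#' @param mesh a [tri_mesh()].
#' @param model a [print_error_model()] (uses `warp_amplitude`,
#'   `warp_wavelength`, `seed`).
#' @return List: `mesh` (warped), `displacement` (n x 3 matrix, mm).
#' @export
warp_mesh <- function(mesh, model) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(model, "print_error_model"))
  A <- model$warp_amplitude
  lam <- model$warp_wavelength
  if (A == 0)
    return(list(mesh = mesh, displacement = matrix(0, nrow(mesh$vertices), 3)))
  if (A >= lam / 10)
    stop("warp amplitude ", A, " mm >= wavelength/10: self-intersection risk")
  state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, .GlobalEnv))
  set.seed(model$seed)
  phase <- stats::runif(3, 0, 2 * pi)
  V <- mesh$vertices
  raw <- cbind(sin(2 * pi * V[, 2] / lam + phase[1]),
               sin(2 * pi * V[, 3] / lam + phase[2]),
               sin(2 * pi * V[, 1] / lam + phase[3]))
  mag <- sqrt(rowSums(raw^2))
  scale <- A / max(mag)
  disp <- raw * scale
  out <- mesh
  out$vertices <- V + disp
  list(mesh = out, displacement = disp)
}

#' Remove features thinner than a minimum printable diameter
#'
#' Morphological opening in the voxel domain at radius `min_diameter / 2`:
#' protrusions thinner than the minimum printable feature disappear, which
#' emulates both printer resolution limits and the loss of distal thin
#' branches during mesh processing. Anti-extensive and idempotent.
#'
#' @param mesh watertight [tri_mesh()].
#' @param min_diameter minimum surviving feature diameter (mm); 0 is the
#'   identity.
#' @param voxel grid pitch (mm).
#' @return The opened [tri_mesh()].
#' @export
drop_thin_features <- function(mesh, min_diameter, voxel = 0.05) {
  stopifnot(inherits(mesh, "tri_mesh"), min_diameter >= 0)
  if (!is_watertight(mesh)) stop("opening requires a watertight mesh")
  if (min_diameter == 0) return(mesh)
  r <- min_diameter / 2
  pad <- r + 5 * voxel
  lo <- apply(mesh$vertices, 2, min) - pad
  hi <- apply(mesh$vertices, 2, max) + pad
  sp <- rep(voxel, 3)
  dims <- as.integer(ceiling((hi - lo) / sp))
  occ <- cpp_voxelize(mesh$vertices, faces0(mesh), mesh$part,
                      mesh$part_sign, lo, sp, dims, 2L)
  maskv <- occ >= 0.5
  r2 <- r^2 + 1e-9
  ero <- cpp_edt_sq(!maskv, dims, sp) > r2
  opened <- cpp_edt_sq(ero, dims, sp) <= r2
  if (!any(opened)) stop("opening at ", min_diameter, " mm removes the mesh")
  # keep the partial-volume field everywhere except where the opening
  # removed material, so unchanged surfaces re-extract with sub-voxel
  # accuracy while removed features (and their partial-volume halo, which
  # never reaches the 0.5 level) disappear
  field <- occ
  field[maskv & !opened] <- 0
  res <- cpp_marching_tetra(field, dims, lo + sp / 2, sp, 0.5)
  m <- tri_mesh(res$vertices, res$faces, name = mesh$name)
  if (sum(face_volumes(m)) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Simulate a complete print with known errors
#'
#' Composition: [drop_thin_features()], [offset_mesh()], [warp_mesh()],
#' then a seeded random rigid misplacement within the model bounds. The
#' full ground truth (offset, displacement field, misplacement transform)
#' is returned for closed-loop recovery tests.
#'
#' @param mesh watertight [tri_mesh()].
#' @param model a [print_error_model()].
#' @return List: `mesh` (the "printed" model), `truth` (list with `offset`,
#'   `displacement`, `transform`, `min_feature`).
#' @export
simulate_print <- function(mesh, model = print_error_model()) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(model, "print_error_model"))
  m <- mesh
  if (model$min_feature > 0)
    m <- drop_thin_features(m, model$min_feature, model$voxel)
  if (model$offset != 0)
    m <- offset_mesh(m, model$offset, model$voxel)
  disp <- NULL
  if (model$warp_amplitude > 0) {
    wr <- warp_mesh(m, model)
    m <- wr$mesh
    disp <- wr$displacement
  }
  tf <- rigid_transform()
  if (model$misplace_angle > 0 || model$misplace_translation > 0) {
    state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(state)) assign(".Random.seed", state, .GlobalEnv))
    set.seed(model$seed + 104729L)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, model$misplace_angle) * pi / 180
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    tr <- dir * stats::runif(1, 0, model$misplace_translation)
    tf <- rigid_transform(rotation_about_axis(ax, ang), tr)
    m <- apply_transform(m, tf)
  }
  list(mesh = m,
       truth = list(offset = model$offset, displacement = disp,
                    transform = tf, min_feature = model$min_feature,
                    seed = model$seed))
}
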