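# CT acquisition simulator. The forward model reproduces the acquisition
# effects that matter for anatomic modeling QA: partial volume (exact
# integration of mesh occupancy along the slice direction, supersampled
# in-plane), reconstruction-kernel blur (in-plane Gaussian; sharp/smooth),
# through-plane slice averaging (boxcar, the stair-step generator on
# inclined surfaces), and additive white Gaussian image noise. It is not a
# projection/reconstruction simulator: beam hardening, metal artifacts and
# dose modeling are out of scope.

#' CT scan protocol
#'
#' @param in_plane in-plane voxel spacing (mm).
#' @param slice_thickness slice thickness = through-plane spacing (mm).
#' @param kernel reconstruction kernel, `"sharp"` or `"smooth"`.
#' @param psf_sigma in-plane Gaussian point-spread sigma (mm). Defaults to
#'   0.15 for the sharp and 0.60 for the smooth kernel.
#' @param noise_sigma image noise standard deviation (HU); 0 disables noise.
#' @param object_hu,background_hu HU of the printed material and of the
#'   surrounding air. A printed polymer scanned in air is about 120 vs
#'   -1000 HU.
#' @param supersampling in-plane rays per voxel axis for the partial-volume
#'   integration (the slice direction is integrated exactly).
#' @param padding grid padding beyond the mesh bounds (mm).
#' @param seed random seed used by [add_noise()].
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(in_plane = 0.2, slice_thickness = 0.4,
                          kernel = c("sharp", "smooth"), psf_sigma = NULL,
                          noise_sigma = 0, object_hu = 120,
                          background_hu = -1000, supersampling = 3L,
                          padding = 5, seed = 1L) {
  kernel <- match.arg(kernel)
  if (is.null(psf_sigma))
    psf_sigma <- if (kernel == "sharp") 0.15 else 0.60
  stopifnot(in_plane > 0, slice_thickness > 0, psf_sigma >= 0,
            noise_sigma >= 0, supersampling >= 1, padding >= 0)
  structure(list(in_plane = in_plane, slice_thickness = slice_thickness,
                 kernel = kernel, psf_sigma = psf_sigma,
                 noise_sigma = noise_sigma, object_hu = object_hu,
                 background_hu = background_hu,
                 supersampling = as.integer(supersampling),
                 padding = padding, seed = as.integer(seed)),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "scan_protocol: %.3g mm in-plane, %.3g mm slices, %s kernel (sigma %.3g mm), noise %.3g HU\n",
    x$in_plane, x$slice_thickness, x$kernel, x$psf_sigma, x$noise_sigma))
  invisible(x)
}

#' Scalar CT-like volume
#'
#' @param data 3-D numeric array, axis order (x, y, z); z is the slice
#'   direction.
#' @param spacing per-axis voxel spacing (mm).
#' @param origin world coordinate (mm) of the corner of voxel (1,1,1)
#'   (voxel centers sit at `origin + (index - 0.5) * spacing`).
#' @param protocol optional [scan_protocol()] provenance.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0),
                         protocol = NULL) {
  stopifnot(length(dim(data)) == 3, all(spacing > 0), length(origin) == 3)
  if (!all(is.finite(data))) stop("volume values must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), protocol = protocol),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, range [%.1f, %.1f] HU\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

# voxel center coordinates along one axis
voxel_centers <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 0.5) * vol$spacing[axis]
}

#' Voxelize a mesh into an HU volume with partial volume
#'
#' Each voxel receives `background + (object - background) * f` where `f` is
#' the fraction of the voxel inside the mesh: occupancy is integrated
#' exactly along z (the slice direction) and supersampled in-plane. The grid
#' is padded beyond the mesh bounds; the through-plane spacing equals the
#' protocol slice thickness.
#'
#' @param mesh watertight [tri_mesh()].
#' @param protocol a [scan_protocol()].
#' @return A [voxel_volume()].
#' @export
voxelize <- function(mesh, protocol = scan_protocol()) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(protocol, "scan_protocol"))
  if (!is_watertight(mesh))
    stop("refusing to voxelize a non-watertight mesh (inside test undefined)")
  sp <- c(protocol$in_plane, protocol$in_plane, protocol$slice_thickness)
  lo <- apply(mesh$vertices, 2, min) - protocol$padding
  hi <- apply(mesh$vertices, 2, max) + protocol$padding
  dims <- as.integer(ceiling((hi - lo) / sp))
  occ <- cpp_voxelize(mesh$vertices, faces0(mesh), mesh$part,
                      mesh$part_sign, lo, sp, dims, protocol$supersampling)
  hu <- protocol$background_hu +
    (protocol$object_hu - protocol$background_hu) * occ
  voxel_volume(array(hu, dims), sp, lo, protocol)
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-half:half) / sigma_vox)^2)
  k / sum(k)
}

boxcar_kernel <- function(width_vox) {
  if (width_vox <= 1) return(1)
  half <- ceiling((width_vox - 1) / 2)
  k <- pmin(1, pmax(0, (width_vox / 2) - (abs(-half:half) - 0.5)))
  k / sum(k)
}

#' Apply the reconstruction kernel and slice averaging
#'
#' In-plane Gaussian blur of the protocol PSF sigma and a through-plane
#' boxcar average of width equal to the slice thickness. Kernels are
#' normalized, so the mean HU of a padded volume is conserved. With sigma 0
#' and slice thickness equal to the through-plane spacing this is the
#' identity.
#'
#' @param vol a [voxel_volume()].
#' @param protocol a [scan_protocol()]; defaults to the volume's own.
#' @return The filtered [voxel_volume()].
#' @export
apply_kernel <- function(vol, protocol = vol$protocol) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(protocol, "scan_protocol"))
  d <- dim(vol$data)
  out <- as.numeric(vol$data)
  kxy <- gaussian_kernel(protocol$psf_sigma / vol$spacing[1])
  if (length(kxy) > 1) {
    out <- cpp_convolve_axis(out, d, kxy, 0L)
    kxy2 <- gaussian_kernel(protocol$psf_sigma / vol$spacing[2])
    out <- cpp_convolve_axis(out, d, kxy2, 1L)
  }
  kz <- boxcar_kernel(protocol$slice_thickness / vol$spacing[3])
  if (length(kz) > 1) out <- cpp_convolve_axis(out, d, kz, 2L)
  voxel_volume(array(out, d), vol$spacing, vol$origin, protocol)
}

#' Add image noise
#'
#' Additive white Gaussian noise of the protocol sigma (HU), reproducible
#' under the protocol seed. The global RNG state is restored afterwards.
#'
#' @param vol a [voxel_volume()].
#' @param protocol a [scan_protocol()]; defaults to the volume's own.
#' @return The noisy [voxel_volume()].
#' @export
add_noise <- function(vol, protocol = vol$protocol) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(protocol, "scan_protocol"))
  if (protocol$noise_sigma <= 0) {
    vol$protocol <- protocol
    return(vol)
  }
  state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, .GlobalEnv))
  set.seed(protocol$seed)
  vol$data <- vol$data + array(rnorm(length(vol$data), 0,
                                     protocol$noise_sigma), dim(vol$data))
  vol$protocol <- protocol
  vol
}

#' Simulate a CT scan of a mesh
#'
#' Composition [voxelize()] then [apply_kernel()] then [add_noise()]; the
#' protocol is recorded with the returned volume.
#'
#' @param mesh watertight [tri_mesh()].
#' @param protocol a [scan_protocol()].
#' @return A [voxel_volume()].
#' @export
simulate_scan <- function(mesh, protocol = scan_protocol()) {
  add_noise(apply_kernel(voxelize(mesh, protocol), protocol), protocol)
}

#' Write a volume as NIfTI
#'
#' Voxel spacing goes to the NIfTI pixdim and the origin to an axis-aligned
#' sform; axis order is (x, y, z) with z the slice direction.
#'
#' @param vol a [voxel_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin + vol$spacing / 2
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return A [voxel_volume()] (axis-aligned geometry only; oblique sforms
#'   are rejected).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  if (is.matrix(m) && all(dim(m) == c(4, 4)) && any(m[1:3, 1:3] != 0)) {
    sp <- diag(m[1:3, 1:3])
    if (max(abs(m[1:3, 1:3] - diag(sp))) > 1e-4 * max(abs(sp)) ||
        any(sp <= 0))
      stop("only axis-aligned volumes are supported")
    origin <- m[1:3, 4] - sp / 2
  } else {
    sp <- RNifti::pixdim(img)[1:3]
    origin <- c(0, 0, 0)
  }
  voxel_volume(array(as.numeric(img), dim(img)[1:3]), sp, origin)
}
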