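test_that("voxelization applies the partial-volume model to a cube", {
  cube <- prim_box(c(0, 0, 0), c(10, 10, 10))
  pr <- scan_protocol(in_plane = 0.5, slice_thickness = 0.5, psf_sigma = 0,
                      object_hu = 1000, background_hu = -1000, padding = 2)
  vol <- voxelize(cube, pr)
  ctr <- vapply(1:3, function(k) which.min(abs(voxel_centers(vol, k) - 5)),
                1L)
  expect_equal(vol$data[ctr[1], ctr[2], ctr[3]], 1000, tolerance = 1e-6)
  expect_equal(vol$data[1, 1, 1], -1000)
  # occupancy integrates to the mesh volume (volume conservation)
  occ <- (vol$data + 1000) / 2000
  expect_equal(sum(occ) * prod(vol$spacing), 1000, tolerance = 0.01 * 1000)
})

test_that("voxelization conserves volume within 1% for curved solids", {
  s <- prim_sphere(12)
  pr <- scan_protocol(in_plane = 0.4, slice_thickness = 0.4,
                      supersampling = 3)
  vol <- voxelize(s, pr)
  occ <- (vol$data - pr$background_hu) / (pr$object_hu - pr$background_hu)
  vox_vol <- sum(occ) * prod(vol$spacing)
  expect_equal(vox_vol, measure(s)$volume, tolerance = 0.01 * measure(s)$volume)
})

test_that("voxelize refuses non-watertight meshes and pads with background", {
  s <- prim_sphere(6)
  open_mesh <- tri_mesh(s$vertices, s$faces[-1, ])
  expect_error(voxelize(open_mesh, scan_protocol()), "watertight")
  vol <- voxelize(s, scan_protocol(in_plane = 0.5, slice_thickness = 0.5))
  expect_true(all(vol$data[1, , ] == vol$protocol$background_hu))
})

test_that("kernel with zero sigma and matching slice thickness is the identity", {
  s <- prim_sphere(8)
  pr <- scan_protocol(in_plane = 0.5, slice_thickness = 0.5, psf_sigma = 0)
  vol <- voxelize(s, pr)
  out <- apply_kernel(vol, pr)
  expect_identical(out$data, vol$data)
})

test_that("Gaussian blur spreads a step edge by the closed-form 25-75% width", {
  # 1-D step embedded in a volume; edge width between quartiles = 1.349 sigma
  n <- 401
  arr <- array(rep(ifelse(seq_len(n) > n / 2, 1000, -1000), times = 9),
               c(n, 3, 3))
  vol <- voxel_volume(arr, c(0.1, 0.1, 0.1))
  pr <- scan_protocol(in_plane = 0.1, slice_thickness = 0.1,
                      psf_sigma = 0.8)
  out <- apply_kernel(vol, pr)
  prof <- out$data[, 2, 2]
  xs <- voxel_centers(vol, 1)
  x25 <- stats::approx(prof, xs, xout = -500, ties = "ordered")$y
  x75 <- stats::approx(prof, xs, xout = 500, ties = "ordered")$y
  expect_equal(x75 - x25, 1.349 * 0.8, tolerance = 0.02)
  # mean conservation
  expect_equal(mean(out$data), mean(vol$data), tolerance = 1e-6)
})

test_that("slice averaging of an inclined slab produces stair-steps at the slice period", {
  # thin slab tilted against the slice direction
  slab <- prim_box(c(0, 0, 0), c(40, 10, 2))
  tilted <- apply_transform(slab, rigid_transform(
    rotation_about_axis(c(0, 1, 0), 10 * pi / 180), c(0, 0, 10)))
  pr <- scan_protocol(in_plane = 0.4, slice_thickness = 3, psf_sigma = 0,
                      padding = 4)
  vol <- simulate_scan(tilted, pr)
  surf <- extract_surface(threshold_segment(vol, -440))
  # top surface heights vary in discrete jumps; neighboring-profile height
  # differences cluster at 0 and at the slice thickness
  expect_equal(vol$spacing[3], 3)
  zs <- surf$vertices[, 3]
  expect_gt(diff(range(zs)), 3)   # staircase spans at least one slice jump
})

test_that("noise is seeded, optional, and has the requested magnitude", {
  arr <- array(0, c(60, 60, 30))
  vol <- voxel_volume(arr, c(1, 1, 1))
  pr0 <- scan_protocol(noise_sigma = 0)
  expect_identical(add_noise(vol, pr0)$data, arr)
  pr <- scan_protocol(noise_sigma = 20, seed = 11)
  n1 <- add_noise(vol, pr)
  n2 <- add_noise(vol, pr)
  expect_identical(n1$data, n2$data)
  expect_equal(sd(n1$data), 20, tolerance = 0.02 * 20)
  pr2 <- scan_protocol(noise_sigma = 20, seed = 12)
  expect_false(identical(n1$data, add_noise(vol, pr2)$data))
})

test_that("noise-free scans are deterministic end to end", {
  s <- prim_frustum(8, 4, 6)
  pr <- scan_protocol(in_plane = 0.4, slice_thickness = 0.8)
  v1 <- simulate_scan(s, pr)
  v2 <- simulate_scan(s, pr)
  expect_identical(v1$data, v2$data)
  expect_s3_class(v1$protocol, "scan_protocol")
})

test_that("volumes survive a NIfTI round trip", {
  s <- prim_sphere(6)
  vol <- simulate_scan(s, scan_protocol(in_plane = 0.5,
                                        slice_thickness = 1))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-4)
  expect_equal(back$data, vol$data, tolerance = 1e-6,
               ignore_attr = TRUE)
})
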