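test_that("threshold segmentation selects exactly the high-HU voxels", {
  arr <- array(-1000, c(20, 20, 20))
  arr[5:15, 5:15, 5:15] <- 120
  vol <- voxel_volume(arr, c(1, 1, 1))
  mk <- threshold_segment(vol, -440)
  expect_equal(sum(mk$mask), 11^3)
  expect_true(all(mk$mask[5:15, 5:15, 5:15]))
  expect_error(threshold_segment(vol, 500), "outside volume range")
})

test_that("keep_largest removes disconnected specks", {
  arr <- array(-1000, c(30, 30, 30))
  arr[5:20, 5:20, 5:20] <- 120
  arr[27, 27, 27] <- 120
  vol <- voxel_volume(arr, c(1, 1, 1))
  mk <- threshold_segment(vol, 0, keep_largest = TRUE)
  expect_false(mk$mask[27, 27, 27])
  expect_equal(sum(mk$mask), 16^3)
})

test_that("threshold duality: segmenting -volume at -t is the complement", {
  set.seed(5)
  arr <- array(stats::rnorm(8000), c(20, 20, 20))
  vol <- voxel_volume(arr, c(1, 1, 1))
  volneg <- voxel_volume(-arr, c(1, 1, 1))
  t <- 0.3
  a <- threshold_segment(vol, t)$mask
  b <- threshold_segment(volneg, -t)$mask   # -x >= -t  <=>  x <= t
  expect_true(all(a | b))                    # union covers everything
  expect_true(all(!(a & b) | abs(arr - t) < 1e-12))
})

test_that("extract_surface recovers a voxelized sphere within 1% volume", {
  s <- prim_sphere(10)
  vol <- voxelize(s, scan_protocol(in_plane = 0.2, slice_thickness = 0.2,
                                   psf_sigma = 0))
  surf <- extract_surface(vol, iso_level = -440)
  expect_watertight(surf)
  expect_equal(measure(surf)$volume, 4 / 3 * pi * 125,
               tolerance = 0.01 * 4 / 3 * pi * 125)
})

test_that("a single foreground voxel yields a closed unit surface", {
  arr <- array(FALSE, c(7, 7, 7)); arr[4, 4, 4] <- TRUE
  mk <- structure(list(mask = arr, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), threshold = 0.5,
                       protocol = NULL), class = "seg_mask")
  surf <- extract_surface(mk)
  expect_watertight(surf)
  expect_equal(measure(surf)$volume, 1, tolerance = 0.6)  # octahedral voxel
})

test_that("foreground touching the grid boundary is an open-surface error", {
  arr <- array(TRUE, c(5, 5, 5))
  mk <- structure(list(mask = arr, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), threshold = 0.5,
                       protocol = NULL), class = "seg_mask")
  expect_error(extract_surface(mk), "boundary")
})

test_that("wrap equals the brute-force closing oracle and has its properties", {
  set.seed(42)
  for (rep in 1:3) {
    arr <- array(FALSE, c(24, 24, 24))
    pts <- matrix(sample(5:20, 30, TRUE), ncol = 3)
    for (i in seq_len(nrow(pts)))
      arr[pts[i, 1] + (-1:1), pts[i, 2] + (-1:1), pts[i, 3] + (-1:1)] <- TRUE
    mk <- structure(list(mask = arr, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), threshold = 0.5,
                         protocol = NULL), class = "seg_mask")
    r <- 2.2
    w <- wrap(mk, r)
    oracle <- brute_close(arr, r)
    # hole filling only adds fully enclosed cavities on top of closing
    filled <- array(printqa:::cpp_fill_holes(as.logical(oracle),
                                             dim(oracle)), dim(oracle))
    expect_identical(w$mask, filled)
    expect_true(all(w$mask[arr]))                    # extensive
    w2 <- wrap(w, r)
    expect_identical(w2$mask, w$mask)                # idempotent
    # increasing: wrap of a superset is a superset
    arr2 <- arr; arr2[12, 12, 12] <- TRUE
    mk2 <- mk; mk2$mask <- arr2
    expect_true(all(w$mask[wrap(mk2, r)$mask == FALSE] == FALSE))
  }
})

test_that("closing bridges gaps narrower than twice the radius", {
  arr <- array(FALSE, c(40, 20, 20))
  arr[5:14, 5:14, 5:14] <- TRUE     # two 10-voxel cubes, 2-voxel gap
  arr[17:26, 5:14, 5:14] <- TRUE
  mk <- structure(list(mask = arr, spacing = c(0.5, 0.5, 0.5),
                       origin = c(0, 0, 0), threshold = 0.5,
                       protocol = NULL), class = "seg_mask")
  w <- wrap(mk, 1)                  # gap 1 mm < 2 r
  lab <- printqa:::cpp_label_components(as.logical(w$mask), dim(w$mask))
  expect_equal(max(lab), 1)
  expect_error(wrap(mk, 5), "quarter")
})

test_that("radius-0 wrap only fills enclosed cavities", {
  arr <- array(FALSE, c(12, 12, 12))
  arr[3:10, 3:10, 3:10] <- TRUE
  arr[6:7, 6:7, 6:7] <- FALSE
  mk <- structure(list(mask = arr, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), threshold = 0.5,
                       protocol = NULL), class = "seg_mask")
  w <- wrap(mk, 0)
  expect_true(all(w$mask[3:10, 3:10, 3:10]))
  expect_equal(sum(w$mask), 8^3)
})

test_that("smoothing reduces surface noise while conserving volume", {
  s <- prim_sphere(10, chord = 0.05)
  set.seed(9)
  noisy <- s
  nrm <- noisy$vertices / sqrt(rowSums(noisy$vertices^2))
  noisy$vertices <- noisy$vertices + nrm * stats::runif(nrow(nrm), -0.1, 0.1)
  sm <- smooth_mesh(noisy, iterations = 20)
  rms_dev <- function(m) {
    r <- sqrt(rowSums(m$vertices^2))
    sqrt(mean((r - mean(r))^2))
  }
  expect_lt(rms_dev(sm), rms_dev(noisy))
  v0 <- measure(s)$volume
  expect_equal(measure(sm)$volume, v0, tolerance = 0.01 * v0)
  expect_identical(smooth_mesh(noisy, iterations = 0), noisy)
  expect_equal(nrow(sm$faces), nrow(noisy$faces))
})

test_that("overlay contours trace a sphere's equator within 2%", {
  s <- prim_sphere(10)
  vol <- voxelize(s, scan_protocol(in_plane = 0.2, slice_thickness = 0.2))
  mk <- threshold_segment(vol, -440)
  k <- which.min(abs(voxel_centers(vol, 3)))   # equatorial slice
  cc <- overlay_contours(mk, "axial", k)
  expect_length(cc, 1)
  per <- sum(sqrt(rowSums(diff(rbind(cc[[1]], cc[[1]][1, ]))^2)))
  expect_equal(per, 2 * pi * 5, tolerance = 0.02 * 2 * pi * 5)
  # empty slice
  expect_length(overlay_contours(mk, "axial", 1), 0)
  expect_error(overlay_contours(mk, "axial", 10000), "out of range")
})

test_that("a full-foreground slice contours at the slice bounds", {
  arr <- array(FALSE, c(10, 12, 5)); arr[, , 3] <- TRUE
  mk <- structure(list(mask = arr, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), threshold = 0.5,
                       protocol = NULL), class = "seg_mask")
  cc <- overlay_contours(mk, "axial", 3)
  expect_length(cc, 1)
  rng <- apply(cc[[1]], 2, range)
  expect_equal(unname(rng[, 1]), c(0, 10), tolerance = 0.5)
  expect_equal(unname(rng[, 2]), c(0, 12), tolerance = 0.5)
})
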