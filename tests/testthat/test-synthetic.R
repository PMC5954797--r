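test_that("offsetting a sphere reproduces the analytic offset volume", {
  s <- prim_sphere(20)                       # r = 10
  grown <- offset_mesh(s, 0.5, voxel = 0.1)
  expect_watertight(grown)
  v_target <- 4 / 3 * pi * 10.5^3
  expect_equal(measure(grown)$volume, v_target, tolerance = 0.01 * v_target)
  d <- signed_distance(grown, s)
  expect_equal(mean(d), 0.5, tolerance = 0.02)
  shrunk <- offset_mesh(s, -0.5, voxel = 0.1)
  v_target2 <- 4 / 3 * pi * 9.5^3
  expect_equal(measure(shrunk)$volume, v_target2,
               tolerance = 0.01 * v_target2)
})

test_that("zero offset re-extracts with negligible volume change", {
  s <- prim_sphere(14)
  s0 <- offset_mesh(s, 0, voxel = 0.1)
  expect_equal(measure(s0)$volume, measure(s)$volume,
               tolerance = 0.005 * measure(s)$volume)
})

test_that("an annihilating offset is an error", {
  s <- prim_sphere(3)
  expect_error(offset_mesh(s, -2, voxel = 0.1), "annihilates")
})

test_that("warp fields are seeded, bounded and refuse the fold regime", {
  s <- prim_sphere(20)
  m <- print_error_model(warp_amplitude = 0.3, warp_wavelength = 30,
                         seed = 2)
  w1 <- warp_mesh(s, m)
  w2 <- warp_mesh(s, m)
  expect_identical(w1$mesh$vertices, w2$mesh$vertices)   # same seed
  expect_equal(max(sqrt(rowSums(w1$displacement^2))), 0.3,
               tolerance = 1e-9)
  d <- signed_distance(w1$mesh, s)
  expect_gte(max(abs(d)), 0.25)
  expect_lte(max(abs(d)), 0.35)
  m0 <- print_error_model(warp_amplitude = 0, seed = 2)
  w0 <- warp_mesh(s, m0)
  expect_identical(w0$mesh, s)
  expect_true(all(w0$displacement == 0))
  expect_error(warp_mesh(s, print_error_model(warp_amplitude = 3,
                                              warp_wavelength = 20)),
               "self-intersection")
})

test_that("drop_thin_features removes sub-threshold branches and keeps the trunk", {
  spec <- gen2_phantom_spec()
  vt <- printqa:::vascular_tree(spec, c(0, 0), 0, 0.01)
  tree <- mesh_concat(vt$parts, names = vt$names, name = "tree")
  dropped <- drop_thin_features(tree, 1.0, voxel = 0.1)
  expect_watertight(dropped)
  # segments 1-3 (5, 2.5, 1.25 mm) span z 0-30; thinner segments and the
  # 0.75 mm branch must be gone
  zmax <- max(dropped$vertices[, 3])
  expect_lt(zmax, 31)
  expect_gt(zmax, 29)
  # 2.5 mm branch at 45 degrees survives (it points toward -x, reaching
  # beyond the trunk radius)
  expect_lt(min(dropped$vertices[, 1]), -4)
  # anti-extensive: nothing outside the original solid (within voxel error)
  d <- signed_distance(dropped, tree)
  expect_lt(max(d), 0.1)
  # idempotent
  again <- drop_thin_features(dropped, 1.0, voxel = 0.1)
  expect_equal(measure(again)$volume, measure(dropped)$volume,
               tolerance = 0.01 * measure(dropped)$volume)
})

test_that("opening keeps a solid cube essentially unchanged", {
  cb <- prim_box(c(0, 0, 0), c(10, 10, 10))
  cb2 <- drop_thin_features(cb, 1.0)
  expect_equal(measure(cb2)$volume, 1000, tolerance = 10)
  expect_identical(drop_thin_features(cb, 0), cb)
})

test_that("simulate_print composes the error chain with recorded ground truth", {
  s <- prim_sphere(14)
  null_print <- simulate_print(s, print_error_model())
  expect_identical(null_print$mesh, s)
  expect_equal(null_print$truth$offset, 0)

  pm <- print_error_model(misplace_angle = 15, misplace_translation = 10,
                          seed = 5)
  ref <- organic_reference(15, seed = 21, chord = 0.05)
  pr <- simulate_print(ref, pm)
  tf_true <- pr$truth$transform
  expect_gt(rotation_angle(tf_true$rotation), 0)
  tf <- register_icp(pr$mesh, ref)
  err <- compose_transform(tf, tf_true)
  expect_lt(rotation_angle(err$rotation) * 180 / pi, 0.1)
  expect_lt(max(abs(apply_transform(pr$mesh, tf)$vertices - ref$vertices)),
            0.05)
  # same seed reproduces the same misplacement
  pr2 <- simulate_print(ref, pm)
  expect_identical(pr$mesh$vertices, pr2$mesh$vertices)
})

test_that("offset-only prints validate back to the injected offset", {
  s <- prim_sphere(14)
  pm <- print_error_model(offset = -0.1, voxel = 0.1)
  printed <- simulate_print(s, pm)
  vol <- simulate_scan(printed$mesh, scan_protocol(in_plane = 0.2,
                                                   slice_thickness = 0.4))
  rep <- validate_model(s, vol)
  expect_equal(rep$mean, -0.1, tolerance = 0.05)
})
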