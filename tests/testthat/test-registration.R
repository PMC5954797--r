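test_that("signed distance matches the brute-force all-triangle oracle", {
  set.seed(2)
  for (s in 1:6) {
    ref <- random_test_mesh(s)
    probe <- random_test_mesh(s + 50)
    expect_lte(nrow(ref$faces), 500)
    d <- abs(signed_distance(probe, ref))
    idx <- unique(round(seq(1, nrow(probe$vertices), length.out = 25)))
    for (i in idx) {
      expect_equal(d[i],
                   brute_point_mesh_distance(probe$vertices[i, ], ref),
                   tolerance = 1e-9)
    }
  }
})

test_that("signed distance uses the outside-positive / inside-negative convention", {
  ref <- prim_sphere(20)            # r = 10
  probe_out <- prim_sphere(24)      # r = 12, fully outside
  probe_in <- prim_sphere(16)       # r = 8, fully inside
  expect_true(all(signed_distance(probe_out, ref) > 0))
  expect_true(all(signed_distance(probe_in, ref) < 0))
  # concentric spheres closed form
  d <- signed_distance(prim_sphere(20), prim_sphere(20.2))
  expect_equal(mean(d), -0.1, tolerance = 0.005)
  # identical meshes give zero
  expect_lt(max(abs(signed_distance(ref, ref))), 1e-9)
})

test_that("a shifted cube's vertices land within the expected distance band", {
  cube <- prim_box(c(0, 0, 0), c(1, 1, 1))
  shifted <- translate_mesh(cube, c(0.2, 0, 0))
  d <- signed_distance(shifted, cube)
  expect_true(all(d >= -1e-12 & d <= 0.2 + 1e-12))
  expect_true(any(abs(d - 0.2) < 1e-9))
  for (i in seq_len(nrow(shifted$vertices)))
    expect_equal(abs(d[i]),
                 brute_point_mesh_distance(shifted$vertices[i, ], cube),
                 tolerance = 1e-9)
})

test_that("non-watertight references fall back to unsigned distances", {
  ref <- prim_sphere(10)
  open_ref <- tri_mesh(ref$vertices, ref$faces[-1, ])
  expect_warning(d <- signed_distance(prim_sphere(8), open_ref),
                 "unsigned")
  expect_false(attr(d, "signed"))
  expect_true(all(d >= 0))
})

test_that("ICP is exact on identical meshes and recovers known transforms", {
  m <- organic_reference(16, seed = 9, chord = 0.05)
  tf0 <- register_icp(m, m)
  expect_lt(rotation_angle(tf0$rotation), 1e-4)
  expect_lt(sqrt(sum(tf0$translation^2)), 1e-4)

  tf_true <- rigid_transform(rotation_about_axis(c(1, 2, 3), 10 * pi / 180),
                             c(5, -1, 2))
  moved <- apply_transform(m, tf_true)
  tf <- register_icp(moved, m)
  back <- apply_transform(moved, tf)
  expect_lt(max(abs(back$vertices - m$vertices)), 0.05)
  err <- compose_transform(tf, tf_true)
  expect_lt(rotation_angle(err$rotation) * 180 / pi, 0.1)
})

test_that("ICP cost is monotone non-increasing and collinear input fails", {
  m <- organic_reference(14, seed = 3, chord = 0.05)
  tf_true <- random_rigid(3, 15, 10)
  tf <- register_icp(apply_transform(m, tf_true), m)
  tr <- attr(tf, "trace")
  expect_true(all(diff(tr) <= 1e-9))
  line <- tri_mesh(cbind(seq_len(10), 0, 0),
                   cbind(1:8, 2:9, 3:10))
  expect_error(register_icp(line, m), "collinear|degenerate")
})

test_that("distance_stats summarizes with population SD and 0.05 mm bins", {
  r0 <- distance_stats(c(0, 0, 0))
  expect_equal(c(r0$min, r0$max, r0$mean, r0$sd), c(0, 0, 0, 0))
  r <- distance_stats(c(-0.57, -0.12, 0.34))
  expect_equal(r$min, -0.57)
  expect_equal(r$max, 0.34)
  r2 <- distance_stats(c(1, 2, 3, 4))
  expect_equal(r2$mean, 2.5)
  expect_equal(r2$sd, sqrt(1.25))
  expect_equal(diff(r2$histogram$edges)[1], 0.05)
  expect_equal(sum(r2$histogram$counts), 4)
  expect_error(distance_stats(numeric(0)), "empty")
})

test_that("validate_model on a noise-free self-scan is nearly unbiased", {
  s <- prim_sphere(12)
  vol <- simulate_scan(s, scan_protocol(in_plane = 0.2,
                                        slice_thickness = 0.4))
  rep <- validate_model(s, vol)
  expect_lt(abs(rep$mean), 0.05)
  expect_lt(rep$sd, 0.1)
  expect_s3_class(rep$transform, "rigid_transform")
})

test_that("validate_model recovers a known dilation and writes reports", {
  s <- prim_sphere(12)
  grown <- offset_mesh(s, 0.3, voxel = 0.1)
  vol <- simulate_scan(grown, scan_protocol(in_plane = 0.2,
                                            slice_thickness = 0.4))
  ply <- tempfile(fileext = ".ply")
  js <- tempfile(fileext = ".json")
  rep <- validate_model(s, vol, annotated_ply = ply, json = js)
  expect_equal(rep$mean, 0.3, tolerance = 0.05)
  parsed <- jsonlite::read_json(js)
  expect_true(all(c("min", "max", "mean", "sd", "registration",
                    "protocol") %in% names(parsed)))
  annotated <- read_ply(ply)
  expect_equal(nrow(annotated$vertices), rep$n)
  expect_equal(mean(annotated$scalars), rep$mean, tolerance = 1e-4)
})
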