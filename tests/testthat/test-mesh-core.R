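test_that("measure reports exact box geometry and divergence-theorem volume", {
  cube <- prim_box(c(0, 0, 0), c(1, 1, 1))
  m <- measure(cube)
  expect_equal(m$volume, 1)
  expect_equal(m$area, 6)
  expect_true(m$watertight)
  plate <- prim_box(c(0, 0, 0), c(50, 100, 5))
  expect_equal(measure(plate)$volume, 25000)
  expect_equal(unname(measure(plate)$bbox[2, ] - measure(plate)$bbox[1, ]),
               c(50, 100, 5))
})

test_that("volume of a non-watertight mesh is flagged undefined", {
  cube <- prim_box(c(0, 0, 0), c(1, 1, 1))
  open_mesh <- tri_mesh(cube$vertices, cube$faces[-1, ])
  expect_warning(m <- measure(open_mesh), "not watertight")
  expect_true(is.na(m$volume))
  expect_false(m$watertight)
})

test_that("tri_mesh validates its invariants", {
  expect_error(tri_mesh(matrix(c(0, 0, Inf), 1, 3), matrix(1, 1, 3)),
               "finite")
  expect_error(tri_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  expect_error(tri_mesh(diag(3), rbind(c(1, 2, 3)), part_sign = 2L),
               "\\+1 or -1")
})

test_that("rigid transforms preserve area, volume and watertightness", {
  set.seed(7)
  for (s in 1:5) {
    m <- random_test_mesh(s)
    tf <- random_rigid(s + 100)
    m2 <- apply_transform(m, tf)
    expect_equal(measure(m2)$area, measure(m)$area, tolerance = 1e-9)
    expect_equal(measure(m2)$volume, measure(m)$volume, tolerance = 1e-9)
    expect_true(is_watertight(m2))
    # group inverse round trip
    m3 <- apply_transform(m2, invert_transform(tf))
    expect_lt(max(abs(m3$vertices - m$vertices)), 1e-9)
  }
})

test_that("pure translation shifts the bounding box exactly", {
  m <- prim_box(c(0, 0, 0), c(2, 3, 4))
  m2 <- translate_mesh(m, c(1, 2, 3))
  expect_equal(measure(m2)$bbox, measure(m)$bbox + rep(c(1, 2, 3),
                                                       each = 2))
})

test_that("rigid_transform rejects non-rotations", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(2 * diag(3)), "orthonormal")
})

test_that("watertightness is invariant under vertex permutation", {
  m <- prim_frustum(6, 3, 5, chord = 0.2)
  set.seed(1)
  perm <- sample(nrow(m$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- tri_mesh(m$vertices[perm, ], matrix(inv[m$faces], ncol = 3))
  expect_true(is_watertight(m2))
  expect_equal(abs(measure(m2)$volume), measure(m)$volume, tolerance = 1e-9)
})
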