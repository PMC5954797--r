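test_that("ASCII STL of a tetrahedron parses to 4 merged vertices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  tet <- tri_mesh(v, f)
  path <- tempfile(fileext = ".stl")
  write_stl(tet, path, dialect = "ascii")
  m <- read_stl(path)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 4)
  expect_true(attr(m, "watertight"))
})

test_that("binary STL layout is 84 + 50 n bytes and round-trips", {
  cube <- prim_box(c(0, 0, 0), c(1, 1, 1))
  path <- tempfile(fileext = ".stl")
  write_stl(cube, path)
  expect_equal(file.size(path), 84 + 12 * 50)
  m <- read_stl(path)
  expect_equal(nrow(m$faces), 12)
  expect_equal(sort(as.vector(m$vertices)), sort(as.vector(cube$vertices)),
               tolerance = 1e-6)
})

test_that("STL round trip is idempotent after the first pass", {
  m1 <- random_test_mesh(3)
  p1 <- tempfile(fileext = ".stl"); p2 <- tempfile(fileext = ".stl")
  write_stl(m1, p1)
  r1 <- read_stl(p1)
  write_stl(r1, p2)
  r2 <- read_stl(p2)
  expect_equal(r1$vertices, r2$vertices, tolerance = 1e-6)
  expect_equal(r1$faces, r2$faces)
})

test_that("malformed STL files are rejected with a byte offset", {
  path <- tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(charToRaw(sprintf("%-80s", "broken")), con)
  writeBin(10L, con, size = 4, endian = "little")      # declares 10 facets
  writeBin(raw(50 * 9), con)                           # contains 9
  close(con)
  expect_error(read_stl(path), "byte")
  expect_error(write_stl(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                         tempfile()), "empty")
})

test_that("generated phantom components survive an STL round trip watertight", {
  ph <- build_gen2_phantom()
  path <- tempfile(fileext = ".stl")
  write_stl(ph$positive_base_assembly, path)
  m <- read_stl(path)
  expect_true(attr(m, "watertight"))
})

test_that("annotated PLY preserves scalars and maps extremes to the colormap ends", {
  m <- prim_box(c(0, 0, 0), c(1, 1, 1))
  sc <- seq(-0.57, 0.34, length.out = nrow(m$vertices))
  path <- tempfile(fileext = ".ply")
  write_annotated_ply(m, sc, path, colormap_range = c(-0.57, 0.34))
  r <- read_ply(path)
  expect_equal(r$scalars, sc, tolerance = 1e-6)
  cols <- attr(r, "colors")
  expect_equal(cols[which.min(sc), ], c(59, 76, 192))    # cold end
  expect_equal(cols[which.max(sc), ], c(180, 4, 38))     # hot end

  # all-zero scalars on a symmetric range sit at the midpoint color
  write_annotated_ply(m, rep(0, nrow(m$vertices)), path,
                      colormap_range = c(-1, 1))
  r0 <- read_ply(path)
  expect_true(all(abs(attr(r0, "colors") - 245) <= 1))
  expect_error(write_annotated_ply(m, 1:3, path), "per vertex")
})
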