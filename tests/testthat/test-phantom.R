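spec2 <- gen2_phantom_spec()
ph <- build_gen2_phantom(spec2)

test_that("every gen-2 component is watertight with outward winding", {
  for (nm in names(ph)) expect_watertight(ph[[nm]])
})

test_that("gen-2 components reproduce their defining dimensions exactly", {
  pos <- ph$positive_base_assembly
  ext <- function(m, k) unname(measure(m)$bbox[2, k] - measure(m)$bbox[1, k])
  base <- mesh_part(pos, "base")
  expect_equal(ext(base, 1), 50, tolerance = 1e-9)
  expect_equal(ext(base, 2), 100, tolerance = 1e-9)
  expect_equal(ext(base, 3), 5, tolerance = 1e-9)
  expect_equal(measure(base)$volume, 25000, tolerance = 1e-6)

  # largest semi-sphere caliper width (on the insert and in the recess)
  dome <- mesh_part(ph$insert_spheres, "sphere3")
  expect_equal(ext(dome, 1), 7.5, tolerance = 1e-3)
  expect_equal(ext(mesh_part(ph$negative_base, "recess_sphere1"), 1), 2.5,
               tolerance = 1e-3)

  hexm <- mesh_part(ph$insert_hexagons, "hexagon")
  expect_equal(ext(hexm, 1), 10, tolerance = 1e-3)     # across flats
  expect_equal(ext(hexm, 3), 20, tolerance = 1e-3)     # height

  cone <- mesh_part(pos, "cone_positive")
  expect_equal(ext(cone, 1), 20, tolerance = 1e-3)
  expect_equal(ext(cone, 3), 20, tolerance = 1e-3)
  zb <- measure(base)$bbox[2, 3]
  expect_equal(unname(measure(cone)$bbox[1, 3]), unname(zb))  # sits on base

  vseg <- mesh_part(pos, "vascular_seg5")
  expect_equal(ext(vseg, 1), 0.5, tolerance = 1e-3)

  surfm <- mesh_part(pos, "surface")
  expect_equal(ext(surfm, 1), 12.5, tolerance = 1e-3)
  expect_equal(ext(surfm, 2), 50, tolerance = 1e-3)
  expect_equal(ext(surfm, 3), 10, tolerance = 1e-3)

  neg <- mesh_part(ph$negative_base, "slab")
  expect_equal(ext(neg, 3), 12.5, tolerance = 1e-9)

  ends <- attr(pos, "spiral_endpoints")
  expect_equal(sqrt(sum((ends[1, ] - ends[2, ])^2)), 10, tolerance = 0.05)
})

test_that("nominal feature table echoes the specification", {
  tab <- nominal_feature_table(spec2)
  val <- function(f) tab$nominal_mm[tab$feature == f]
  expect_equal(val("ruler spacing"), 10)
  expect_equal(val("spiral inner diameter"), 1.8)
  expect_equal(val("cone bottom diameter"), 20)
  expect_equal(val("negative cone top diameter"), 16.5)
  expect_equal(val("sphere2 diameter"), 5.0)
  expect_equal(val("vascular segment5 diameter"), 0.5)
})

test_that("gen-2 spec invariants are enforced", {
  expect_error(gen2_phantom_spec(cone_positive = list(d_bottom = 5,
                                                      d_top = 10,
                                                      height = 20)),
               "wider at the bottom")
  expect_error(gen2_phantom_spec(vascular = list(diameters = c(5, 5, 1))),
               "strictly decreasing")
  expect_error(gen2_phantom_spec(hexagon = list(width = -1)), "positive")
})

test_that("overlapping layout placements are a layout error", {
  expect_error(build_gen2_phantom(
    gen2_phantom_spec(layout = list(cone_positive = c(14, 20)))),
    "layout error")
})

test_that("gen-1 phantom has the specified groups and openings", {
  spec <- gen1_phantom_spec()
  g1 <- build_gen1_phantom(spec)
  expect_watertight(g1)
  lay <- attr(g1, "layout")
  expect_equal(max(lay$openings$group), 11)
  expect_true(all(table(lay$openings$group) == 5))
  # nominal width table echoes the spec
  tab <- nominal_feature_table(spec)
  expect_equal(tab$nominal_mm[1:11], spec$widths)
  sp2 <- gen1_phantom_spec(groups = 2, widths = c(2, 1))
  tab2 <- nominal_feature_table(sp2)
  expect_equal(tab2$nominal_mm[1:2], c(2, 1))
  expect_error(build_gen1_phantom(
    gen1_phantom_spec(groups = 2, widths = c(2, 0.1))), "0.2 mm")
})

test_that("exact complements fit and an offset sphere penetrates its recess", {
  # hemispherical recess in a slab and the matching dome
  slab <- prim_box(c(-10, -10, -10), c(10, 10, 0))
  recess <- translate_mesh(prim_dome(5, down = TRUE), c(0, 0, 0))
  cavity <- mesh_concat(slab, recess, signs = c(1, -1),
                        names = c("slab", "recess"))
  dome <- translate_mesh(prim_dome(5, down = TRUE), c(0, 0, 0))
  ft <- fit_test(dome, cavity, clearance = 0)
  expect_true(ft$fits)
  expect_lt(ft$penetration_mm, 1e-9)

  big <- translate_mesh(prim_dome(5.4, down = TRUE), c(0, 0, 0))
  ft2 <- fit_test(big, cavity, clearance = 0.1)
  expect_false(ft2$fits)
  expect_lt(abs(ft2$penetration_mm - 0.2), 0.03)

  open_mesh <- tri_mesh(dome$vertices, dome$faces[-1, ])
  expect_error(fit_test(open_mesh, cavity), "watertight")
})

test_that("as-designed gen-2 inserts fit their recesses at 0.05 mm clearance", {
  for (nm in c("insert_spheres", "insert_hexagons", "insert_cone")) {
    ft <- fit_test(ph[[nm]], ph$negative_base, clearance = 0.05)
    expect_true(ft$fits)
    expect_lt(ft$penetration_mm, 1e-6)
  }
})
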