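# QA phantom generators.
#
# The second-generation phantom is a pair of 50 x 100 mm plates: the positive
# base carries raised test objects (line pairs, a sinusoidal curvature
# surface, a cone, a cochlea-like spiral, a branching vascular tree); the
# negative base carries recessed copies of three shapes (semi-spheres,
# hexagonal cylinder, cone frustum) plus edge ruler markers, and three insert
# plates carry the positives of those recessed shapes for the qualitative
# fit test. The first-generation phantom is a block of line-pair groups with
# air openings used to benchmark geometric accuracy and resolution.

#' Specification of the second-generation QA phantom
#'
#' Returns the parametric description of every test object with the default
#' dimensions of the reference design, which users may override before
#' building. Dimensions in mm; line-pair frequencies in lp/mm.
#'
#' @param ... named overrides of top-level entries (partial lists are merged).
#' @return An object of class `gen2_spec`.
#' @export
gen2_phantom_spec <- function(...) {
  spec <- list(
    linepair = list(frequencies = c(0.5, 1.0, 2.0), pairs = 3L,
                    bar_length = 8, bar_height = 5),
    surface = list(height = 7.5, length = 50, width = 12.5, depth = 10),
    spheres = list(diameters = c(2.5, 5.0, 7.5)),
    cone_positive = list(d_bottom = 20, d_top = 10, height = 20),
    cone_negative = list(d_top = 16.5, d_bottom = 10, height = 7.5),
    hexagon = list(width = 10, height = 20, recess_depth = 10),
    base_positive = list(width = 50, length = 100, height = 5),
    base_negative = list(width = 50, length = 100, height = 12.5),
    ruler = list(markers = 5L, spacing = 10, notch = c(1, 1, 0.5)),
    spiral = list(d_inner = 1.8, d_outer = 2.5, separation = 10,
                  coil_diameter = 10, turns = 2),
    vascular = list(seg_length = 10, diameters = c(5, 2.5, 1.25, 0.75, 0.5),
                    branch_diameters = c(2.5, 0.75),
                    branch_angles = c(45, 25)),
    layout = list(linepair = c(5, 5), surface = c(31.25, 4),
                  cone_positive = c(14, 44), spiral = c(12.5, 70),
                  vascular = c(35, 80),
                  recess_x = 15, recess_y = c(15, 30, 45),
                  hex_center = c(15, 65), cone_center = c(15, 85),
                  min_separation = 5),
    insert_plate = list(thickness = 3, margin = 3),
    chord = 0.01)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(spec[[nm]]))
      spec[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else spec[[nm]] <- ov[[nm]]
  }
  validate_gen2_spec(structure(spec, class = "gen2_spec"))
}

validate_gen2_spec <- function(spec) {
  dims <- c(unlist(spec$surface), spec$spheres$diameters,
            unlist(spec$cone_positive), unlist(spec$cone_negative),
            spec$hexagon$width, spec$hexagon$height,
            unlist(spec$base_positive), unlist(spec$base_negative),
            spec$ruler$spacing, spec$spiral$d_inner, spec$spiral$d_outer,
            spec$vascular$seg_length, spec$vascular$diameters)
  if (any(dims <= 0)) stop("all phantom dimensions must be positive")
  if (spec$cone_positive$d_bottom <= spec$cone_positive$d_top)
    stop("positive cone must be wider at the bottom than at the top")
  if (any(diff(spec$vascular$diameters) >= 0))
    stop("vascular diameters must be strictly decreasing")
  if (spec$spiral$d_outer <= spec$spiral$d_inner)
    stop("spiral outer diameter must exceed the inner diameter")
  spec
}

#' Specification of the first-generation line-pair QA phantom
#'
#' Eleven groups of line-pair patterns; each group has `openings` air
#' openings whose width equals the adjacent bar width. Default widths follow
#' a geometric ladder from 3.0 mm down to 0.3 mm.
#'
#' @param groups number of line-pair groups.
#' @param openings air openings per group.
#' @param widths bar/opening width per group (mm), strictly decreasing.
#' @param bar_height,bar_depth bar dimensions (mm).
#' @param base_height supporting slab thickness (mm).
#' @param group_gap solid separation between groups (mm).
#' @param margin solid margin around the pattern (mm).
#' @return An object of class `gen1_spec`.
#' @export
gen1_phantom_spec <- function(groups = 11L, openings = 5L,
                              widths = 3.0 * 10^(-(seq_len(groups) - 1) / 10),
                              bar_height = 10, bar_depth = 5,
                              base_height = 5, group_gap = 5, margin = 5) {
  if (length(widths) != groups) stop("need one width per group")
  if (any(diff(widths) >= 0)) stop("widths must be strictly decreasing")
  structure(list(groups = as.integer(groups), openings = as.integer(openings),
                 widths = widths, bar_height = bar_height,
                 bar_depth = bar_depth, base_height = base_height,
                 group_gap = group_gap, margin = margin),
            class = "gen1_spec")
}

# opening/bar x-layout; one row per opening, plus probe-line coordinates
gen1_layout <- function(spec) {
  x <- spec$margin
  rows <- NULL
  for (g in seq_len(spec$groups)) {
    w <- spec$widths[g]
    # group = (openings + 1) bars alternating with `openings` openings
    for (o in seq_len(spec$openings)) {
      left <- x + (2 * o - 1) * w
      rows <- rbind(rows, data.frame(group = g, opening = o,
                                     left = left, right = left + w,
                                     width = w))
    }
    x <- x + (2 * spec$openings + 1) * w + spec$group_gap
  }
  total_x <- x - spec$group_gap + spec$margin
  list(openings = rows, total_x = total_x,
       probe_y = spec$margin + spec$bar_depth / 2,
       probe_z = spec$base_height + spec$bar_height / 2,
       bar_top = spec$base_height + spec$bar_height)
}

#' Build the first-generation line-pair phantom
#'
#' A solid slab carrying, for each group, alternating bars and air openings
#' of equal width. Group widths are queryable with
#' [nominal_feature_table()].
#'
#' @param spec a [gen1_phantom_spec()].
#' @return A watertight multi-part [tri_mesh()]; attribute `layout` holds the
#'   opening positions and the caliper probe line.
#' @export
build_gen1_phantom <- function(spec = gen1_phantom_spec()) {
  stopifnot(inherits(spec, "gen1_spec"))
  if (any(spec$widths < 0.2))
    stop("bar/opening widths below 0.2 mm cannot be voxelized reliably")
  lay <- gen1_layout(spec)
  depth_y <- spec$bar_depth + 2 * spec$margin
  parts <- list(prim_box(c(0, 0, 0), c(lay$total_x, depth_y,
                                       spec$base_height), name = "base"))
  y0 <- spec$margin; y1 <- spec$margin + spec$bar_depth
  z0 <- spec$base_height; z1 <- lay$bar_top
  x <- spec$margin
  for (g in seq_len(spec$groups)) {
    w <- spec$widths[g]
    for (b in seq_len(spec$openings + 1L)) {
      xb <- x + (2 * b - 2) * w
      parts <- c(parts, list(prim_box(c(xb, y0, z0), c(xb + w, y1, z1),
                                      name = sprintf("bar_g%d", g))))
    }
    x <- x + (2 * spec$openings + 1) * w + spec$group_gap
  }
  m <- mesh_concat(parts, name = "gen1_phantom")
  attr(m, "layout") <- lay
  attr(m, "spec") <- spec
  m
}

# line-pair bar ladder along one axis: bars long in `long_axis`, stacked
# along `across_axis`, standing on z0
linepair_block <- function(spec, origin, z0) {
  lp <- spec$linepair
  parts <- list()
  x <- origin[1]
  for (f in lp$frequencies) {
    w <- 1 / (2 * f)
    for (b in seq_len(lp$pairs + 1L)) {
      parts <- c(parts, list(prim_box(
        c(x, origin[2], z0), c(x + w, origin[2] + lp$bar_length,
                               z0 + lp$bar_height),
        name = "linepair")))
      x <- x + 2 * w
    }
    x <- x + 1.5                       # inter-frequency spacing
  }
  # the same ladder rotated to run along y
  y <- origin[2] + lp$bar_length + 2
  for (f in lp$frequencies) {
    w <- 1 / (2 * f)
    for (b in seq_len(lp$pairs + 1L)) {
      parts <- c(parts, list(prim_box(
        c(origin[1], y, z0), c(origin[1] + lp$bar_length, y + w,
                               z0 + lp$bar_height),
        name = "linepair")))
      y <- y + 2 * w
    }
    y <- y + 1.5
  }
  parts
}

vascular_tree <- function(spec, center, z0, chord) {
  vs <- spec$vascular
  parts <- list(); names <- character(0)
  z <- z0
  mids <- numeric(length(vs$diameters))
  for (k in seq_along(vs$diameters)) {
    cyl <- prim_cylinder(vs$diameters[k], vs$seg_length, chord)
    parts <- c(parts, list(translate_mesh(cyl, c(center[1], center[2], z))))
    names <- c(names, sprintf("vascular_seg%d", k))
    mids[k] <- z + vs$seg_length / 2
    z <- z + vs$seg_length
  }
  for (j in seq_along(vs$branch_diameters)) {
    d <- vs$branch_diameters[j]
    k <- which(abs(vs$diameters - d) < 1e-9)[1]
    if (is.na(k)) k <- which.min(abs(vs$diameters - d))
    ang <- vs$branch_angles[j] * pi / 180
    R <- rotation_about_axis(c(0, 1, 0), (-1)^j * ang)
    br <- prim_cylinder(d, vs$seg_length, chord)
    br <- apply_transform(br, rigid_transform(R, c(center[1], center[2],
                                                   mids[k])))
    parts <- c(parts, list(br))
    names <- c(names, sprintf("vascular_branch%d", j))
  }
  list(parts = parts, names = names)
}

spiral_tube <- function(spec, center, z0, chord) {
  sp <- spec$spiral
  turns <- sp$turns
  rc <- sp$coil_diameter / 2
  tt <- seq(0, 2 * pi * turns, length.out = max(100, 60 * turns))
  pitch_total <- sp$separation              # axial end-to-end distance
  path <- cbind(center[1] + rc * cos(tt), center[2] + rc * sin(tt),
                z0 + sp$d_outer / 2 + pitch_total * tt / (2 * pi * turns))
  m <- prim_tube(path, sp$d_outer, sp$d_inner, chord, name = "spiral")
  attr(m, "axis_endpoints") <- rbind(path[1, ], path[nrow(path), ])
  m
}

#' Build the second-generation QA phantom
#'
#' Constructs the full component set: the positive base assembly (line
#' pairs, curvature surface, positive cone, spiral, vascular tree on the
#' 50 x 100 x 5 mm plate), the negative base (50 x 100 x 12.5 mm plate with
#' recessed semi-spheres, hexagonal cylinder, cone frustum and edge ruler
#' markers) and the three insert plates carrying positives of the recessed
#' shapes. Inserts are returned already seated in negative-base coordinates,
#' so [fit_test()] can be applied directly.
#'
#' @param spec a [gen2_phantom_spec()].
#' @return Named list of [tri_mesh()] components: `positive_base_assembly`,
#'   `negative_base`, `insert_spheres`, `insert_hexagons`, `insert_cone`.
#' @export
build_gen2_phantom <- function(spec = gen2_phantom_spec()) {
  stopifnot(inherits(spec, "gen2_spec"))
  ch <- spec$chord
  lay <- spec$layout
  bp <- spec$base_positive
  zb <- bp$height

  check_gen2_layout(spec)

  ## ---- positive base assembly ----
  parts <- list(prim_box(c(0, 0, 0), c(bp$width, bp$length, zb),
                         name = "base"))
  names <- "base"
  lpp <- linepair_block(spec, lay$linepair, zb)
  parts <- c(parts, lpp); names <- c(names, rep("linepair", length(lpp)))
  surf <- prim_sine_block(spec$surface$length, spec$surface$width,
                          spec$surface$height, spec$surface$depth,
                          name = "surface")
  surf <- translate_mesh(surf, c(lay$surface[1], lay$surface[2], zb))
  parts <- c(parts, list(surf)); names <- c(names, "surface")
  cone <- prim_frustum(spec$cone_positive$d_bottom, spec$cone_positive$d_top,
                       spec$cone_positive$height, ch)
  cone <- translate_mesh(cone, c(lay$cone_positive, zb))
  parts <- c(parts, list(cone)); names <- c(names, "cone_positive")
  spir <- spiral_tube(spec, lay$spiral, zb, ch)
  spiral_ends <- attr(spir, "axis_endpoints")
  parts <- c(parts, list(spir)); names <- c(names, "spiral")
  vt <- vascular_tree(spec, lay$vascular, zb, ch)
  parts <- c(parts, vt$parts); names <- c(names, vt$names)
  positive <- mesh_concat(parts, names = names,
                          name = "gen2_positive_base_assembly")
  attr(positive, "spiral_endpoints") <- spiral_ends

  ## ---- negative base with recessed shapes ----
  bn <- spec$base_negative
  zt <- bn$height
  nparts <- list(prim_box(c(0, 0, 0), c(bn$width, bn$length, zt),
                          name = "slab"))
  nnames <- "slab"; nsigns <- 1L
  for (i in seq_along(spec$spheres$diameters)) {
    d <- spec$spheres$diameters[i]
    cav <- translate_mesh(prim_dome(d, ch, down = TRUE),
                          c(lay$recess_x, lay$recess_y[i], zt))
    nparts <- c(nparts, list(cav))
    nnames <- c(nnames, sprintf("recess_sphere%d", i))
    nsigns <- c(nsigns, -1L)
  }
  hx <- spec$hexagon
  cav <- translate_mesh(prim_hexprism(hx$width, hx$recess_depth),
                        c(lay$hex_center, zt - hx$recess_depth))
  nparts <- c(nparts, list(cav)); nnames <- c(nnames, "recess_hexagon")
  nsigns <- c(nsigns, -1L)
  cn <- spec$cone_negative
  cav <- translate_mesh(prim_frustum(cn$d_bottom, cn$d_top, cn$height, ch),
                        c(lay$cone_center, zt - cn$height))
  nparts <- c(nparts, list(cav)); nnames <- c(nnames, "recess_cone")
  nsigns <- c(nsigns, -1L)
  rl <- spec$ruler
  marker_x <- rl$spacing / 2 + rl$spacing * (seq_len(rl$markers) - 1)
  for (i in seq_len(rl$markers)) {
    nx <- rl$notch
    cav <- prim_box(c(marker_x[i] - nx[1] / 2, 2 - nx[2] / 2, zt - nx[3]),
                    c(marker_x[i] + nx[1] / 2, 2 + nx[2] / 2, zt))
    nparts <- c(nparts, list(cav))
    nnames <- c(nnames, sprintf("ruler_x%d", i)); nsigns <- c(nsigns, -1L)
    cav <- prim_box(c(2 - nx[1] / 2, marker_x[i] - nx[2] / 2, zt - nx[3]),
                    c(2 + nx[1] / 2, marker_x[i] + nx[2] / 2, zt))
    nparts <- c(nparts, list(cav))
    nnames <- c(nnames, sprintf("ruler_y%d", i)); nsigns <- c(nsigns, -1L)
  }
  negative <- mesh_concat(nparts, signs = nsigns, names = nnames,
                          name = "gen2_negative_base")

  ## ---- insert plates (seated pose, negative-base coordinates) ----
  pl <- spec$insert_plate
  mg <- pl$margin
  dmax <- max(spec$spheres$diameters) / 2
  p_lo <- c(lay$recess_x - dmax - mg, lay$recess_y[1] - dmax - mg)
  p_hi <- c(lay$recess_x + dmax + mg,
            lay$recess_y[length(lay$recess_y)] + dmax + mg)
  iparts <- list(prim_box(c(p_lo[1], p_lo[2], zt),
                          c(p_hi[1], p_hi[2], zt + pl$thickness),
                          name = "plate"))
  inames <- "plate"
  for (i in seq_along(spec$spheres$diameters)) {
    d <- spec$spheres$diameters[i]
    dome <- translate_mesh(prim_dome(d, ch, down = TRUE),
                           c(lay$recess_x, lay$recess_y[i], zt))
    iparts <- c(iparts, list(dome))
    inames <- c(inames, sprintf("sphere%d", i))
  }
  insert_spheres <- mesh_concat(iparts, names = inames,
                                name = "gen2_insert_spheres")

  hw <- hx$width / sqrt(3) + mg              # hex circumradius + margin
  zhex0 <- zt - hx$recess_depth              # seated: bottom on recess floor
  hex_top <- zhex0 + hx$height
  iparts <- list(prim_box(c(lay$hex_center[1] - hw, lay$hex_center[2] - hw,
                            hex_top),
                          c(lay$hex_center[1] + hw, lay$hex_center[2] + hw,
                            hex_top + pl$thickness), name = "plate"),
                 translate_mesh(prim_hexprism(hx$width, hx$height),
                                c(lay$hex_center, zhex0)))
  insert_hexagons <- mesh_concat(iparts, names = c("plate", "hexagon"),
                                 name = "gen2_insert_hexagons")

  cw <- cn$d_top / 2 + mg
  iparts <- list(prim_box(c(lay$cone_center[1] - cw, lay$cone_center[2] - cw,
                            zt),
                          c(lay$cone_center[1] + cw, lay$cone_center[2] + cw,
                            zt + pl$thickness), name = "plate"),
                 translate_mesh(prim_frustum(cn$d_bottom, cn$d_top,
                                             cn$height, ch),
                                c(lay$cone_center, zt - cn$height)))
  insert_cone <- mesh_concat(iparts, names = c("plate", "cone"),
                             name = "gen2_insert_cone")

  list(positive_base_assembly = positive, negative_base = negative,
       insert_spheres = insert_spheres, insert_hexagons = insert_hexagons,
       insert_cone = insert_cone)
}

# 2-D footprint rectangles of the positive-base objects; overlap or
# out-of-base placement is a layout error
check_gen2_layout <- function(spec) {
  lay <- spec$layout
  lp <- spec$linepair
  lp_w <- sum(sapply(lp$frequencies,
                     function(f) (lp$pairs + 1) / f)) + 1.5 *
    (length(lp$frequencies) - 1)
  boxes <- list(
    linepair = c(lay$linepair, lay$linepair + c(lp_w, lp$bar_length + 2 +
                                                  lp_w)),
    surface = c(lay$surface, lay$surface + c(spec$surface$width,
                                             spec$surface$length)),
    cone_positive = c(lay$cone_positive - spec$cone_positive$d_bottom / 2,
                      lay$cone_positive + spec$cone_positive$d_bottom / 2),
    spiral = c(lay$spiral - (spec$spiral$coil_diameter +
                               spec$spiral$d_outer) / 2,
               lay$spiral + (spec$spiral$coil_diameter +
                               spec$spiral$d_outer) / 2),
    vascular = c(lay$vascular - spec$vascular$seg_length,
                 lay$vascular + spec$vascular$seg_length))
  bp <- spec$base_positive
  nm <- names(boxes)
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    if (b[1] < 0 || b[2] < 0 || b[3] > bp$width || b[4] > bp$length)
      stop("layout error: ", nm[i], " extends beyond the positive base")
    if (i < length(boxes)) for (j in (i + 1):length(boxes)) {
      o <- boxes[[j]]
      if (b[1] < o[3] && o[1] < b[3] && b[2] < o[4] && o[2] < b[4])
        stop("layout error: ", nm[i], " overlaps ", nm[j])
    }
  }
  invisible(spec)
}

#' Nominal feature dimensions (the gold-standard record)
#'
#' One row per dimensioned feature of a phantom specification; measured QA
#' values are compared against this table.
#'
#' @param spec a [gen2_phantom_spec()] or [gen1_phantom_spec()].
#' @return A data frame with columns `feature` and `nominal_mm` (line-pair
#'   frequencies are reported in lp/mm).
#' @export
nominal_feature_table <- function(spec) {
  if (inherits(spec, "gen1_spec")) {
    return(data.frame(
      feature = c(sprintf("group%02d width", seq_len(spec$groups)),
                  "bar height", "bar depth"),
      nominal_mm = c(spec$widths, spec$bar_height, spec$bar_depth)))
  }
  stopifnot(inherits(spec, "gen2_spec"))
  rows <- rbind(
    data.frame(feature = sprintf("line pair frequency %g lp/mm",
                                 spec$linepair$frequencies),
               nominal_mm = spec$linepair$frequencies),
    data.frame(feature = c("surface height", "surface length",
                           "surface width", "surface depth"),
               nominal_mm = unlist(spec$surface, use.names = FALSE)),
    data.frame(feature = sprintf("sphere%d diameter",
                                 seq_along(spec$spheres$diameters)),
               nominal_mm = spec$spheres$diameters),
    data.frame(feature = c("cone bottom diameter", "cone top diameter",
                           "cone height"),
               nominal_mm = c(spec$cone_positive$d_bottom,
                              spec$cone_positive$d_top,
                              spec$cone_positive$height)),
    data.frame(feature = c("negative cone top diameter",
                           "negative cone bottom diameter",
                           "negative cone height"),
               nominal_mm = c(spec$cone_negative$d_top,
                              spec$cone_negative$d_bottom,
                              spec$cone_negative$height)),
    data.frame(feature = c("hexagon width", "hexagon height"),
               nominal_mm = c(spec$hexagon$width, spec$hexagon$height)),
    data.frame(feature = c("positive base width", "positive base length",
                           "positive base height"),
               nominal_mm = unlist(spec$base_positive, use.names = FALSE)),
    data.frame(feature = c("negative base width", "negative base length",
                           "negative base height"),
               nominal_mm = unlist(spec$base_negative, use.names = FALSE)),
    data.frame(feature = c("ruler marker count", "ruler spacing"),
               nominal_mm = c(spec$ruler$markers, spec$ruler$spacing)),
    data.frame(feature = c("spiral inner diameter", "spiral outer diameter",
                           "spiral start-end separation"),
               nominal_mm = c(spec$spiral$d_inner, spec$spiral$d_outer,
                              spec$spiral$separation)),
    data.frame(feature = c(sprintf("vascular segment%d diameter",
                                   seq_along(spec$vascular$diameters)),
                           sprintf("vascular branch%d diameter",
                                   seq_along(spec$vascular$branch_diameters)),
                           sprintf("vascular branch%d angle (deg)",
                                   seq_along(spec$vascular$branch_angles))),
               nominal_mm = c(spec$vascular$diameters,
                              spec$vascular$branch_diameters,
                              spec$vascular$branch_angles)))
  rows
}

#' Positive-into-negative fit test
#'
#' Places a positive insert (at its nominal seated pose) against the
#' negative cavity component and measures the deepest penetration of the
#' positive surface into cavity material. The print passes when the
#' penetration does not exceed the allowed clearance.
#'
#' @param positive insert [tri_mesh()] in the negative component's frame.
#' @param negative_cavity the negative base (cavities as negative parts).
#' @param clearance allowed penetration (mm).
#' @return An object of class `fit_result`: `fits`, `penetration_mm`
#'   (maximum), `clearance_mm` (minimum gap of non-penetrating surface).
#' @export
fit_test <- function(positive, negative_cavity, clearance = 0.05) {
  if (!is_watertight(positive)) stop("positive mesh is not watertight")
  if (!is_watertight(negative_cavity)) stop("negative mesh is not watertight")
  V <- positive$vertices; F <- positive$faces
  cent <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
             V[F[, 3], , drop = FALSE]) / 3
  probe <- rbind(V, cent)
  inside <- points_inside(negative_cavity, probe)
  d <- cpp_closest_point(negative_cavity$vertices, faces0(negative_cavity),
                         probe)$distance
  pen <- if (any(inside)) max(d[inside]) else 0
  clr <- if (any(!inside)) min(d[!inside]) else 0
  # 1 nm floor so exactly-complementary surfaces pass at zero clearance
  structure(list(fits = pen <= clearance + 1e-6, penetration_mm = pen,
                 min_clearance_mm = clr, allowed_mm = clearance),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit test: %s (max penetration %.4f mm, allowed %.4f mm)\n",
              if (x$fits) "FITS" else "DOES NOT FIT",
              x$penetration_mm, x$allowed_mm))
  invisible(x)
}
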