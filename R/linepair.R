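# Line-pair phantom analysis: computational caliper readings of the air
# openings, resolvable-frequency analysis of scanned volumes, and the
# longitudinal QA log with operational limits.

#' Measure air-gap widths of a line-pair phantom
#'
#' A computational caliper: for each opening a probe ray is cast across the
#' bars at mid-height and the gap width is the distance between the opposing
#' bar walls. On a mesh the walls are exact ray-surface crossings; on a
#' volume or mask they are the 0.5-occupancy crossings of the interpolated
#' profile (the half-maximum convention of caliper jaws on a step edge).
#' Openings with no detectable air gap are recorded as width 0 and flagged
#' fused.
#'
#' @param x a [tri_mesh()] (aligned to the layout frame), a `seg_mask`, or a
#'   [voxel_volume()].
#' @param spec the [gen1_phantom_spec()] describing the nominal layout.
#' @return An object of class `gap_measurements`: data frame with columns
#'   `group`, `opening`, `nominal_mm`, `measured_mm`, `diff_mm`, `fused`;
#'   per-group means in attribute `by_group`.
#' @export
measure_gaps <- function(x, spec = gen1_phantom_spec()) {
  stopifnot(inherits(spec, "gen1_spec"))
  lay <- gen1_layout(spec)
  op <- lay$openings
  if (inherits(x, "tri_mesh")) {
    cr <- cpp_ray_crossings(x$vertices, faces0(x),
                            c(0, lay$probe_y, lay$probe_z), c(1, 0, 0))
    walls <- sort(cr)
    edge_at <- function(target, rising) {
      if (!length(walls)) return(NA_real_)
      walls[which.min(abs(walls - target))]
    }
  } else {
    prof <- occupancy_profile(x, lay)
    edge_at <- function(target, rising) profile_crossing(prof, target, rising)
    walls <- NULL
  }
  measured <- numeric(nrow(op)); fused <- logical(nrow(op))
  for (k in seq_len(nrow(op))) {
    w <- op$width[k]
    left <- find_wall(walls, edge_at, op$left[k], w, rising = FALSE)
    right <- find_wall(walls, edge_at, op$right[k], w, rising = TRUE)
    if (is.na(left) || is.na(right) || right <= left) {
      measured[k] <- 0; fused[k] <- TRUE
    } else measured[k] <- right - left
  }
  df <- data.frame(group = op$group, opening = op$opening,
                   nominal_mm = op$width, measured_mm = measured,
                   diff_mm = measured - op$width, fused = fused)
  by_group <- stats::aggregate(df[c("nominal_mm", "measured_mm", "diff_mm")],
                               by = list(group = df$group), FUN = mean)
  structure(df, by_group = by_group, class = c("gap_measurements",
                                               "data.frame"))
}

# nearest wall crossing within +-width/2 of the expected position
find_wall <- function(walls, edge_at, target, width, rising) {
  if (!is.null(walls)) {
    cand <- walls[abs(walls - target) <= width / 2 + 1e-9]
    if (!length(cand)) return(NA_real_)
    return(cand[which.min(abs(cand - target))])
  }
  edge_at(target, rising)
}

# occupancy profile along the caliper probe line of a volume/mask
occupancy_profile <- function(x, lay) {
  if (inherits(x, "seg_mask")) {
    data <- x$mask * 1.0; sp <- x$spacing; orig <- x$origin
    lohi <- c(0, 1)
  } else if (inherits(x, "voxel_volume")) {
    data <- x$data; sp <- x$spacing; orig <- x$origin
    p <- x$protocol
    lohi <- if (!is.null(p)) c(p$background_hu, p$object_hu)
            else range(data)
  } else stop("unsupported input")
  nx <- dim(data)[1]
  xs <- orig[1] + (seq_len(nx) - 0.5) * sp[1]
  vals <- sample_volume_line(data, sp, orig, lay$probe_y, lay$probe_z)
  occ <- (vals - lohi[1]) / (lohi[2] - lohi[1])
  list(x = xs, occ = occ)
}

# bilinear interpolation of the (y, z) position on every x column
sample_volume_line <- function(data, sp, orig, y, z) {
  d <- dim(data)
  fy <- (y - orig[2]) / sp[2] - 0.5
  fz <- (z - orig[3]) / sp[3] - 0.5
  j0 <- max(1, min(d[2] - 1, floor(fy) + 1)); ty <- fy - (j0 - 1)
  k0 <- max(1, min(d[3] - 1, floor(fz) + 1)); tz <- fz - (k0 - 1)
  ty <- max(0, min(1, ty)); tz <- max(0, min(1, tz))
  (1 - ty) * (1 - tz) * data[, j0, k0] +
    ty * (1 - tz) * data[, j0 + 1, k0] +
    (1 - ty) * tz * data[, j0, k0 + 1] +
    ty * tz * data[, j0 + 1, k0 + 1]
}

# sub-voxel 0.5-crossing of the occupancy profile nearest `target`;
# rising = occupancy increases with x (right wall of an opening)
profile_crossing <- function(prof, target, rising) {
  occ <- prof$occ; xs <- prof$x
  lo <- occ[-length(occ)]; hi <- occ[-1]
  if (rising) idx <- which(lo < 0.5 & hi >= 0.5)
  else idx <- which(lo >= 0.5 & hi < 0.5)
  if (!length(idx)) return(NA_real_)
  xc <- xs[idx] + (0.5 - lo[idx]) / (hi[idx] - lo[idx]) *
    (xs[idx + 1] - xs[idx])
  xc[which.min(abs(xc - target))]
}

#' @export
print.gap_measurements <- function(x, ...) {
  bg <- attr(x, "by_group")
  cat("line-pair gap measurements (per-group means):\n")
  print.data.frame(format(bg, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.gap_measurements <- function(x, ...) {
  bg <- attr(x, "by_group")
  plot(bg$group, bg$diff_mm, type = "b", pch = 19,
       xlab = "line-pair group", ylab = "measured - nominal gap (mm)",
       main = "air-gap differences by group", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Resolvable line-pair frequency of a scanned phantom
#'
#' Samples the HU profile across each group at bar centers and opening
#' centers and computes the modulation relative to the coarsest group
#' (group 1). A group is resolved when its relative modulation reaches the
#' threshold; the finest resolved group is the last group of the contiguous
#' resolved run starting at group 1.
#'
#' @param volume a [voxel_volume()] containing the phantom, aligned to the
#'   layout frame.
#' @param spec the [gen1_phantom_spec()].
#' @param threshold modulation threshold for "resolved" (conventional
#'   detectability cutoff 0.2).
#' @return List: `finest_resolved_group`, `modulation` (data frame with
#'   group, modulation, resolved).
#' @export
resolvable_frequency <- function(volume, spec = gen1_phantom_spec(),
                                 threshold = 0.2) {
  stopifnot(inherits(volume, "voxel_volume"))
  lay <- gen1_layout(spec)
  op <- lay$openings
  xs <- voxel_centers(volume, 1)
  if (min(op$left) < min(xs) || max(op$right) > max(xs))
    stop("profile extends outside the volume grid")
  prof <- sample_volume_line(volume$data, volume$spacing, volume$origin,
                             lay$probe_y, lay$probe_z)
  sample_at <- function(x0) {
    f <- (x0 - volume$origin[1]) / volume$spacing[1] - 0.5
    i0 <- max(1, min(length(prof) - 1, floor(f) + 1))
    t <- max(0, min(1, f - (i0 - 1)))
    (1 - t) * prof[i0] + t * prof[i0 + 1]
  }
  mods <- numeric(spec$groups)
  for (g in seq_len(spec$groups)) {
    rows <- op[op$group == g, ]
    gaps <- (rows$left + rows$right) / 2
    bars <- c(rows$left - rows$width / 2, rows$right[nrow(rows)] +
                rows$width[1] / 2)
    imax <- mean(vapply(bars, sample_at, 0))
    imin <- mean(vapply(gaps, sample_at, 0))
    mods[g] <- imax - imin
  }
  if (mods[1] <= 0) stop("no modulation in group 1; is the phantom present?")
  rel <- mods / mods[1]
  resolved <- rel >= threshold
  finest <- if (resolved[1]) max(which(cumsum(!resolved) == 0)) else 0L
  list(finest_resolved_group = as.integer(finest),
       modulation = data.frame(group = seq_len(spec$groups),
                               modulation = rel, resolved = resolved))
}

#' Build a QA record
#'
#' @param measurements data frame with columns `feature` and `value_mm`
#'   (e.g. per-group gap differences, feature dimension errors).
#' @param phantom_generation 1 or 2.
#' @param protocol_id free-text identifier of the imaging/printing protocol.
#' @param timestamp POSIXct; defaults to now.
#' @return An object of class `qa_record`.
#' @export
qa_record <- function(measurements, phantom_generation, protocol_id,
                      timestamp = Sys.time()) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0 ||
      !all(c("feature", "value_mm") %in% names(measurements)))
    stop("measurements must be a non-empty data frame with columns ",
         "'feature' and 'value_mm'")
  structure(list(timestamp = timestamp,
                 phantom_generation = as.integer(phantom_generation),
                 protocol_id = as.character(protocol_id),
                 measurements = measurements),
            class = "qa_record")
}

#' Check a QA record against operational limits
#'
#' @param record a [qa_record()].
#' @param limits data frame with columns `feature`, `lower_mm`, `upper_mm`.
#'   Features without a matching limit row use `default_limits`.
#' @param default_limits length-2 numeric fallback interval (mm). The
#'   default of +-0.5 mm is a starting operational limit until a site has
#'   accumulated its own longitudinal benchmark.
#' @return List: `pass` (overall), `detail` data frame with per-feature
#'   pass/fail.
#' @export
check_limits <- function(record, limits = NULL,
                         default_limits = c(-0.5, 0.5)) {
  stopifnot(inherits(record, "qa_record"))
  meas <- record$measurements
  lo <- rep(default_limits[1], nrow(meas))
  hi <- rep(default_limits[2], nrow(meas))
  if (!is.null(limits)) {
    m <- match(meas$feature, limits$feature)
    lo[!is.na(m)] <- limits$lower_mm[m[!is.na(m)]]
    hi[!is.na(m)] <- limits$upper_mm[m[!is.na(m)]]
  }
  ok <- meas$value_mm >= lo & meas$value_mm <= hi
  list(pass = all(ok),
       detail = data.frame(feature = meas$feature,
                           value_mm = meas$value_mm, lower_mm = lo,
                           upper_mm = hi, pass = ok))
}

#' Append a QA record to a longitudinal log
#'
#' The log is an append-only CSV (one row per measurement, ISO-8601
#' timestamps) supporting trend analysis across the recommended periodic
#' phantom prints. Appending to a log with a different column layout is
#' refused.
#'
#' @param record a [qa_record()].
#' @param log_path CSV path; created if missing.
#' @param limits,default_limits forwarded to [check_limits()].
#' @return The check result from [check_limits()], invisibly.
#' @export
qa_log_append <- function(record, log_path, limits = NULL,
                          default_limits = c(-0.5, 0.5)) {
  chk <- check_limits(record, limits, default_limits)
  rows <- data.frame(
    timestamp = format(record$timestamp, "%Y-%m-%dT%H:%M:%S%z"),
    phantom_generation = record$phantom_generation,
    protocol_id = record$protocol_id,
    feature = record$measurements$feature,
    value_mm = record$measurements$value_mm,
    pass = chk$detail$pass)
  if (file.exists(log_path)) {
    hdr <- names(read.csv(log_path, nrows = 1))
    if (!identical(hdr, names(rows)))
      stop("existing log has a different schema: ",
           paste(hdr, collapse = ", "))
    write.table(rows, log_path, sep = ",", append = TRUE,
                col.names = FALSE, row.names = FALSE)
  } else {
    write.table(rows, log_path, sep = ",", col.names = TRUE,
                row.names = FALSE)
  }
  invisible(chk)
}

#' Read a QA log
#' @param log_path CSV path written by [qa_log_append()].
#' @return Data frame of all logged measurements.
#' @export
qa_log_read <- function(log_path) {
  read.csv(log_path, stringsAsFactors = FALSE)
}
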