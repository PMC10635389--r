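#' Feret axis of a cell polygon
#'
#' The feret length is the longest chord across the cell: the maximum
#' pairwise distance between polygon vertices. The feret angle is the axial
#' orientation of that chord in degrees, measured from the +x axis in image
#' coordinates (y downward) and reduced modulo 180 into [0, 180). Ties in
#' chord length are broken by the smaller angle, then by vertex order.
#'
#' @param poly n x 2 vertex matrix (micrometres), n >= 3.
#' @return list with `length` (um) and `angle` (degrees in [0, 180)).
#' @export
feret_axis <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  d2 <- outer(poly[, 1], poly[, 1], "-")^2 + outer(poly[, 2], poly[, 2], "-")^2
  best <- max(d2)
  idx <- which(d2 == best, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  angles <- axial_angle(poly[idx[, 1], 1], poly[idx[, 1], 2],
                        poly[idx[, 2], 1], poly[idx[, 2], 2])
  ord <- order(angles, idx[, 1], idx[, 2])
  list(length = sqrt(best), angle = angles[ord[1]])
}

#' Circularity shape descriptor
#'
#' C = 4 pi A / P^2: equals 1 for a circle, approaches 0 for a needle.
#'
#' @inheritParams feret_axis
#' @return Circularity in (0, 1] (up to vertex-resolution error).
#' @export
circularity <- function(poly) {
  p <- polygon_perimeter(poly)
  if (p <= 0) stop("zero perimeter")
  4 * pi * polygon_area(poly) / p^2
}

#' Angular offset of a cell axis to its nearest fiber tract
#'
#' Finds the tract segment nearest to the cell centroid (point-to-segment
#' distance; ties broken by lowest tract id) and returns the most acute
#' angle between the cell's feret axis and the tract direction. Both are
#' axial, so the offset lies in [0, 90].
#'
#' @param theta_cell axial feret angle of the cell, degrees.
#' @param centroid length-2 numeric (x, y).
#' @param tracts data.frame with columns tract_id, x1, y1, x2, y2 (already
#'   filtered to the cell's region).
#' @return list with `offset` (deg, [0, 90]), `tract_id`, `distance` (um).
#' @export
tract_angle_offset <- function(theta_cell, centroid, tracts) {
  if (is.null(tracts) || nrow(tracts) == 0) stop("no reference tract")
  d <- point_segment_distance(centroid[1], centroid[2],
                              tracts$x1, tracts$y1, tracts$x2, tracts$y2)
  ord <- order(d, tracts$tract_id)
  i <- ord[1]
  theta_tract <- axial_angle(tracts$x1[i], tracts$y1[i], tracts$x2[i], tracts$y2[i])
  list(offset = axial_difference(theta_cell, theta_tract),
       tract_id = tracts$tract_id[i],
       distance = d[i])
}

#' Total corrected cellular fluorescence
#'
#' TCCF = integrated density - mean local background x cell area. Negative
#' values are retained (not clipped) and flagged via the `negative`
#' attribute so downstream distributions are not silently censored.
#'
#' @param integrated_density integrated density per cell (a.u.).
#' @param background mean local background (a.u. per um^2).
#' @param area cell area (um^2), > 0.
#' @return Numeric vector of TCCF values with logical attribute `negative`.
#' @export
corrected_fluorescence <- function(integrated_density, background, area) {
  if (any(area <= 0)) stop("area must be positive")
  tccf <- integrated_density - background * area
  attr(tccf, "negative") <- tccf < 0
  tccf
}

#' Cell density per square millimetre
#'
#' @param n_cells number of cells inside the region.
#' @param region_poly region polygon in micrometres.
#' @return Cells per mm^2.
#' @export
cell_density <- function(n_cells, region_poly) {
  a <- polygon_area(region_poly) / 1e6   # um^2 -> mm^2
  if (a <= 0) stop("region polygon has zero area")
  n_cells / a
}

#' Normalize fluorescence to a control group and scale per channel
#'
#' Implements "normalized to controls, scaled per channel": values are
#' divided by the mean of the reference (young control) group, then min-max
#' scaled to [0, 1] across the whole experiment. Both factors are returned
#' so calls are reproducible on new data.
#'
#' @param values raw per-cell intensities for one channel.
#' @param groups group label per cell.
#' @param reference reference group label (default "YNG").
#' @return list with `scaled`, `ref_mean`, `range` (pre-scaling min/max).
#' @export
normalize_intensity <- function(values, groups, reference = "YNG") {
  if (!any(groups == reference)) stop("reference group absent: ", reference)
  ref_mean <- mean(values[groups == reference])
  if (ref_mean == 0) stop("reference group mean is zero")
  v <- values / ref_mean
  rng <- range(v)
  scaled <- if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  list(scaled = scaled, ref_mean = ref_mean, range = rng)
}

#' Threshold-based marker positivity calls
#'
#' A cell is positive when its (normalized) channel intensity strictly
#' exceeds the threshold; a value equal to the threshold is negative.
#'
#' @param values per-cell intensities (one channel).
#' @param threshold finite scalar threshold.
#' @return Logical vector of positivity calls.
#' @export
marker_calls <- function(values, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  values > threshold
}

#' Colocalization percentage of one marker within another
#'
#' 100 x |A and B| / |A|: e.g. the percentage of IBA1+ cells that are also
#' GAL3+.
#'
#' @param calls_a,calls_b logical vectors over the same cells.
#' @return Percentage in [0, 100].
#' @export
colocalization_fraction <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) stop("call vectors must match")
  na <- sum(calls_a)
  if (na == 0) stop("no positive cells in the denominator set")
  100 * sum(calls_a & calls_b) / na
}

#' Per-cell morphometric and intensity feature table
#'
#' Runs the full per-cell feature extraction over a segmentation-level cell
#' table: feret axis, area/perimeter/circularity, nearest-tract alignment,
#' TCCF per channel and normalized scaled intensity per channel.
#'
#' @param cells cell table as produced by [simulate_section()] /
#'   [read_cells()]: columns cell_id, mouse, group, region, x, y, area_um2,
#'   polygon, and per channel `intden_<ch>` / `bg_<ch>`.
#' @param tracts tract table with columns tract_id, region, x1, y1, x2, y2.
#' @param channels channel names to process.
#' @param reference_group group used for intensity normalization.
#' @return data.frame, one row per cell (MorphometricRecord).
#' @export
compute_morphometrics <- function(cells, tracts,
                                  channels = c("IBA1", "GAL3", "APOE"),
                                  reference_group = "YNG") {
  n <- nrow(cells)
  feret_len <- feret_ang <- perim <- circ <- numeric(n)
  t_off <- t_dist <- numeric(n)
  t_id <- integer(n)
  for (i in seq_len(n)) {
    poly <- parse_polygon(cells$polygon[i])
    fa <- feret_axis(poly)
    feret_len[i] <- fa$length
    feret_ang[i] <- fa$angle
    perim[i] <- polygon_perimeter(poly)
    circ[i] <- circularity(poly)
    tr <- tracts[tracts$region == cells$region[i], , drop = FALSE]
    to <- tract_angle_offset(fa$angle, c(cells$x[i], cells$y[i]), tr)
    t_off[i] <- to$offset
    t_id[i] <- to$tract_id
    t_dist[i] <- to$distance
  }
  out <- data.frame(cell_id = cells$cell_id, mouse = cells$mouse,
                    group = cells$group, region = cells$region,
                    feret_length = feret_len, feret_angle = feret_ang,
                    area = cells$area_um2, perimeter = perim,
                    circularity = circ, nearest_tract = t_id,
                    tract_distance = t_dist, angle_offset = t_off,
                    stringsAsFactors = FALSE)
  for (ch in channels) {
    idc <- cells[[paste0("intden_", ch)]]
    bgc <- cells[[paste0("bg_", ch)]]
    if (is.null(idc) || is.null(bgc)) stop("channel missing from cell table: ", ch)
    tccf <- corrected_fluorescence(idc, bgc, cells$area_um2)
    nrm <- normalize_intensity(as.numeric(tccf), cells$group, reference_group)
    out[[paste0("tccf_", ch)]] <- as.numeric(tccf)
    out[[paste0("tccf_neg_", ch)]] <- attr(tccf, "negative")
    out[[paste0("norm_", ch)]] <- nrm$scaled
  }
  out
}

#' Serialize / parse polygon vertex strings
#'
#' Cell polygons travel through CSV as a single string column:
#' `"x1 y1;x2 y2;..."` in micrometres.
#'
#' @param s polygon string.
#' @return `parse_polygon`: n x 2 numeric matrix.
#' @export
parse_polygon <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], " ", fixed = TRUE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' @rdname parse_polygon
#' @param poly n x 2 vertex matrix.
#' @return `format_polygon`: a single string.
#' @export
format_polygon <- function(poly) {
  paste(apply(poly, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " ")), collapse = ";")
}
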