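#' Polygon area by the shoelace formula
#'
#' Absolute area of a simple polygon given as an n x 2 vertex matrix.
#' Vertices may be in either winding order; the closing edge is implicit.
#'
#' @param poly numeric matrix with columns x, y (micrometres).
#' @return Area in squared input units.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter
#' @inheritParams polygon_area
#' @return Perimeter in input units.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon(poly)
  xn <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((xn - poly)^2)))
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3 || anyNA(poly))
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns")
  storage.mode(poly) <- "double"
  poly
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param x,y numeric vectors of point coordinates.
#' @param poly n x 2 vertex matrix.
#' @return Logical vector; points exactly on an edge follow the crossing
#'   parity and are not treated specially.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from points (px, py) to segments (x1,y1)-(x2,y2); vectorised over
# points (scalar segment) or over segments (scalar point) by recycling.
# Perpendicular foot when it falls on the segment, else the nearest endpoint.
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (any(len2 == 0)) stop("segment endpoints must be distinct")
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Minimum distance from points to a polyline
#'
#' Minimum over segments of the point-to-segment distance. Used for the
#' distance of marker-positive cells to the fimbria midline and to the
#' ventricle edge.
#'
#' @param points n x 2 matrix (or data.frame) of point coordinates.
#' @param polyline m x 2 vertex matrix, m >= 2; consecutive vertices form
#'   segments.
#' @return Numeric vector of distances (same units as input).
#' @export
distance_to_polyline <- function(points, polyline) {
  points <- as.matrix(points)
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stop("polyline needs at least 2 vertices")
  d <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(polyline) - 1)) {
    d <- pmin(d, point_segment_distance(points[, 1], points[, 2],
                                        polyline[i, 1], polyline[i, 2],
                                        polyline[i + 1, 1], polyline[i + 1, 2]))
  }
  d
}

#' Signed lateral offset from a midline
#'
#' Unsigned distance to the midline with a sign indicating the side facing a
#' reference polyline (typically the ventricle edge): positive on the
#' ventricle side. Coordinates follow the image convention (y increases
#' downward).
#'
#' @param points n x 2 matrix of cell centroids.
#' @param midline m x 2 polyline.
#' @param reference r x 2 polyline defining the positive side.
#' @return Numeric vector of signed offsets.
#' @export
signed_midline_offset <- function(points, midline, reference) {
  points <- as.matrix(points)
  midline <- as.matrix(midline)
  reference <- as.matrix(reference)
  d <- distance_to_polyline(points, midline)
  # side of the first midline segment, oriented so the reference centroid
  # is positive
  seg_side <- function(p) {
    (midline[2, 1] - midline[1, 1]) * (p[2] - midline[1, 2]) -
      (midline[2, 2] - midline[1, 2]) * (p[1] - midline[1, 1])
  }
  ref_sign <- sign(seg_side(colMeans(reference)))
  if (ref_sign == 0) ref_sign <- 1
  s <- apply(points, 1, seg_side)
  d * ifelse(sign(s) == 0, 1, sign(s)) * ref_sign
}

# Axial angle (degrees in [0, 180)) of the chord (x1,y1)->(x2,y2), measured
# from the +x axis in stored (image) coordinates.
axial_angle <- function(x1, y1, x2, y2) {
  a <- atan2(y2 - y1, x2 - x1) * 180 / pi
  a <- a %% 180
  ifelse(a >= 180, a - 180, a)
}

# Acute axial difference between two axial angles, in [0, 90].
axial_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
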