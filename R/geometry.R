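# Small planar geometry toolkit. All coordinates are projected metric (x
# east, y north); polygons are n x 2 matrices of vertices, not closed (the
# last vertex does not repeat the first).

#' Build a rotated rectangle polygon
#'
#' @param centre numeric length-2 `(x, y)`.
#' @param along rectangle extent along its main axis (metres).
#' @param across rectangle extent across the main axis (metres).
#' @param azimuth orientation of the main axis, degrees clockwise from north.
#' @return 4 x 2 matrix of corner coordinates (counter-clockwise).
#' @export
rect_polygon <- function(centre, along, across, azimuth = 0) {
  a <- azimuth * pi / 180
  u <- c(sin(a), cos(a))        # along-axis unit vector
  v <- c(cos(a), -sin(a))       # across-axis unit vector
  h <- along / 2; w <- across / 2
  corners <- rbind(-h * u - w * v, h * u - w * v, h * u + w * v, -h * u + w * v)
  sweep(corners, 2, centre, "+")
}

#' Test points for polygon membership (even-odd ray casting)
#'
#' Vectorised over points; boundary points may fall on either side and should
#' not be relied upon.
#'
#' @param px,py point coordinates.
#' @param poly n x 2 vertex matrix of a simple polygon.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Polygon area by the shoelace formula
#'
#' @param poly n x 2 vertex matrix.
#' @return area in squared coordinate units (always non-negative).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Sutherland-Hodgman clip of a convex polygon against an axis-aligned
# rectangle; returns the clipped vertex matrix (possibly 0 rows).
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_half <- function(p, keep, intersect) {
    if (nrow(p) == 0) return(p)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(p)
    for (i in seq_len(n)) {
      cur <- p[i, ]; prv <- p[if (i == 1) n else i - 1, ]
      cin <- keep(cur); pin <- keep(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(a, b, val, axis) {
    t <- (val - a[axis]) / (b[axis] - a[axis])
    a + t * (b - a)
  }
  p <- poly
  p <- clip_half(p, function(q) q[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip_half(p, function(q) q[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip_half(p, function(q) q[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip_half(p, function(q) q[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}

#' Distance from a point to a polygon ring
#'
#' Minimum euclidean distance from `(px, py)` to the boundary (edges) of a
#' polygon. Points inside the polygon get their distance to the nearest edge,
#' not zero.
#'
#' @param px,py point coordinates (vectorised).
#' @param poly n x 2 vertex matrix.
#' @return numeric vector of distances.
#' @export
dist_to_ring <- function(px, py, poly) {
  n <- nrow(poly)
  best <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
    d <- sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
    best <- pmin(best, d)
  }
  best
}
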