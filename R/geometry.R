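#' Polygon area by the shoelace formula
#'
#' Computes the unsigned planar area of a simple polygon given as an ordered
#' vertex matrix. The polygon is closed implicitly (last vertex connects back
#' to the first).
#'
#' @param poly numeric matrix with two columns (x, y), one row per vertex,
#'   at least 3 rows.
#' @return Area in squared coordinate units (micrometres squared throughout
#'   this package).
#' @examples
#' polygon_area(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))  # 100
#' @export
polygon_area <- function(poly) {
  poly <- check_polygon_matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon.
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  poly <- check_polygon_matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  cx <- sum((x + x[j]) * cross) / (6 * a)
  cy <- sum((y + y[j]) * cross) / (6 * a)
  c(cx, cy)
}

check_polygon_matrix <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) < 2 || nrow(poly) < 3)
    stop("polygon must be a matrix with >= 3 vertices and 2 columns (x, y)")
  if (!all(is.finite(poly[, 1:2])))
    stop("polygon vertices must be finite")
  poly[, 1:2, drop = FALSE]
}

#' Test points for polygon containment
#'
#' Vectorized crossing-number test, boundary inclusive: a point lying exactly
#' on a polygon edge (within `eps`) counts as inside. Boundary inclusion makes
#' spot-to-region assignment deterministic for spots that fall on a shared
#' apical/basal edge.
#'
#' @param x,y numeric vectors of point coordinates (recycled to equal length).
#' @param poly polygon vertex matrix, see [polygon_area()].
#' @param eps distance tolerance for the on-boundary test, in coordinate units.
#' @return Logical vector, one element per point.
#' @export
points_in_polygon <- function(x, y, poly, eps = 1e-9) {
  poly <- check_polygon_matrix(poly)
  n <- length(x)
  stopifnot(length(y) == n)
  px <- poly[, 1]; py <- poly[, 2]
  nv <- nrow(poly)
  j <- c(2:nv, 1)
  inside <- rep(FALSE, n)
  onedge <- rep(FALSE, n)
  for (k in seq_len(nv)) {
    x1 <- px[k]; y1 <- py[k]; x2 <- px[j[k]]; y2 <- py[j[k]]
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2))
      d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
      onedge <- onedge | d2 <= eps * eps
    } else {
      onedge <- onedge | ((x - x1)^2 + (y - y1)^2 <= eps * eps)
    }
    # crossing-number update (half-open rule avoids double counting vertices)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' @rdname points_in_polygon
#' @param pt numeric length-2 vector (x, y).
#' @export
point_in_polygon <- function(pt, poly, eps = 1e-9) {
  points_in_polygon(pt[1], pt[2], poly, eps = eps)
}

# Proper-crossing test between segments (p1,p2) and (p3,p4); touching at a
# shared endpoint does not count. Used for polygon simplicity validation.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Check that a polygon is simple (non-self-intersecting)
#'
#' @inheritParams polygon_area
#' @return `TRUE` if no two non-adjacent edges properly cross.
#' @export
polygon_is_simple <- function(poly) {
  poly <- check_polygon_matrix(poly)
  n <- nrow(poly)
  j <- c(2:n, 1)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # skip adjacent edges (share a vertex), incl. first/last pair
      if (b == a + 1 || (a == 1 && b == n)) next
      if (segments_cross(poly[a, ], poly[j[a], ], poly[b, ], poly[j[b], ]))
        return(FALSE)
    }
  }
  TRUE
}

# Minimum distance from points to a segment, plus the side sign
# (positive = left of the directed segment).
dist_points_segment <- function(x, y, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  len2 <- dx * dx + dy * dy
  if (len2 == 0) stop("degenerate (zero-length) segment")
  t <- pmin(1, pmax(0, ((x - a[1]) * dx + (y - a[2]) * dy) / len2))
  qx <- a[1] + t * dx; qy <- a[2] + t * dy
  dist <- sqrt((x - qx)^2 + (y - qy)^2)
  side <- sign(dx * (y - a[2]) - dy * (x - a[1]))
  list(dist = dist, side = side, t = t)
}

# Chord length of the intersection between an infinite line through `origin`
# with direction `dir` (unit vector) and the polygon boundary: the largest
# span between intersection parameters. Exact for convex regions, which is
# the geometry the drawn epithelial ROIs approximate.
line_polygon_chord <- function(origin, dir, poly) {
  poly <- check_polygon_matrix(poly)
  n <- nrow(poly)
  j <- c(2:n, 1)
  ts <- numeric(0)
  for (k in seq_len(n)) {
    p <- poly[k, ]; q <- poly[j[k], ]
    ex <- q[1] - p[1]; ey <- q[2] - p[2]
    denom <- dir[1] * ey - dir[2] * ex
    if (abs(denom) < 1e-12) next
    # origin + t*dir = p + s*e
    t <- ((p[1] - origin[1]) * ey - (p[2] - origin[2]) * ex) / denom
    s <- if (abs(ex) > abs(ey)) (origin[1] + t * dir[1] - p[1]) / ex
         else (origin[2] + t * dir[2] - p[2]) / ey
    if (s >= -1e-12 && s <= 1 + 1e-12) ts <- c(ts, t)
  }
  if (length(ts) < 2) return(0)
  max(ts) - min(ts)
}

# Uniform points inside a polygon by rejection from the bounding box.
runif_in_polygon <- function(n, poly) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  poly <- check_polygon_matrix(poly)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  guard <- 0
  while (length(out_x) < n && guard < 1000) {
    m <- max(2 * (n - length(out_x)), 16)
    cx <- stats::runif(m, xr[1], xr[2])
    cy <- stats::runif(m, yr[1], yr[2])
    keep <- points_in_polygon(cx, cy, poly)
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
    guard <- guard + 1
  }
  if (length(out_x) < n) stop("rejection sampling failed; degenerate polygon?")
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}
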