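# Planar polygon primitives: area, point-in-polygon, distance to boundary,
# rectangle clipping.  Coordinates are metric (metres); polygons are simple
# rings given as two-column matrices, open or closed (first vertex need not
# be repeated).

#' Close and validate a polygon ring
#' @noRd
as_ring <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (!is.numeric(boundary) || ncol(boundary) != 2L) {
    stop_ddd("polygon boundary must be a numeric matrix with two columns (x, y)")
  }
  if (anyNA(boundary) || any(!is.finite(boundary))) {
    stop_ddd("polygon boundary contains non-finite coordinates")
  }
  n <- nrow(boundary)
  if (n >= 2L && all(boundary[1L, ] == boundary[n, ])) {
    boundary <- boundary[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop_ddd("polygon boundary needs at least 3 distinct vertices")
  dimnames(boundary) <- list(NULL, c("x", "y"))
  boundary
}

#' Signed shoelace area of a ring (positive if counter-clockwise)
#' @noRd
ring_area_signed <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

polygon_area <- function(ring) abs(ring_area_signed(as_ring(ring)))

#' Point-in-polygon test (even-odd ray casting), boundary counts as inside
#'
#' Vectorised over points.  `tol` lets points within a small distance of the
#' boundary count as inside, absorbing floating-point jitter at window edges.
#' @noRd
points_in_ring <- function(x, y, ring, tol = 1e-6) {
  n <- nrow(ring)
  px <- ring[, 1L]; py <- ring[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    crosses <- ((py[k] > y) != (qy[k] > y))
    if (any(crosses)) {
      xin <- px[k] + (y[crosses] - py[k]) * (qx[k] - px[k]) / (qy[k] - py[k])
      inside[crosses] <- xor(inside[crosses], x[crosses] < xin)
    }
  }
  if (tol > 0) {
    out <- which(!inside)
    if (length(out)) {
      d <- dist_to_ring(x[out], y[out], ring)
      inside[out[d <= tol]] <- TRUE
    }
  }
  inside
}

#' Euclidean distance from points to the boundary of a ring
#'
#' Exact minimum distance over all boundary segments, vectorised over points.
#' @noRd
dist_to_ring <- function(x, y, ring) {
  n <- nrow(ring)
  ax <- ring[, 1L]; ay <- ring[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  best <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    if (len2[k] == 0) {
      d2 <- (x - ax[k])^2 + (y - ay[k])^2
    } else {
      t <- ((x - ax[k]) * dx[k] + (y - ay[k]) * dy[k]) / len2[k]
      t <- pmin(1, pmax(0, t))
      d2 <- (x - (ax[k] + t * dx[k]))^2 + (y - (ay[k] + t * dy[k]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Clip a ring by an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' Returns the clipped ring (possibly with 0 rows).  Used to measure the
#' fraction of a raster cell covered by a window.
#' @noRd
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2L)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1L) n else i - 1L, ]
      cur_in <- keep(cur); prev_in <- keep(prev)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    # intersection of segment p-q with the line coord == val
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- as_ring(ring)
  pts <- clip_edge(pts, function(p) p[1L] >= xmin, function(p, q) ix(p, q, xmin, 1L))
  pts <- clip_edge(pts, function(p) p[1L] <= xmax, function(p, q) ix(p, q, xmax, 1L))
  pts <- clip_edge(pts, function(p) p[2L] >= ymin, function(p, q) ix(p, q, ymin, 2L))
  pts <- clip_edge(pts, function(p) p[2L] <= ymax, function(p, q) ix(p, q, ymax, 2L))
  pts
}

#' Area of the intersection of a ring with a rectangle
#' @noRd
ring_rect_overlap_area <- function(ring, xmin, xmax, ymin, ymax) {
  clipped <- clip_ring_rect(ring, xmin, xmax, ymin, ymax)
  if (nrow(clipped) < 3L) return(0)
  abs(ring_area_signed(clipped))
}

#' Project geographic coordinates to planar UTM metres
#'
#' Standard transverse Mercator series on the WGS84 ellipsoid.  All package
#' statistics require planar metric coordinates; this helper converts
#' longitude/latitude inventories before a pattern is built.  The default
#' zone (19, southern hemisphere) covers Madre de Dios, Peru.
#'
#' @param lon,lat Numeric vectors of geographic coordinates in decimal
#'   degrees.
#' @param zone UTM zone number (1-60).
#' @param south Logical; use the southern-hemisphere false northing.
#' @return A two-column matrix of easting/northing in metres.
#' @examples
#' project_lonlat(-69.2, -12.6)
#' @export
project_lonlat <- function(lon, lat, zone = 19L, south = TRUE) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop_ddd("lon/lat outside valid geographic ranges")
  }
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lon0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180; lam <- lon * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lon0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
    (35 * e2^3 / 3072) * sin(6 * phi))
  easting <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
    (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  northing <- k0 * (M + N * tan(phi) * (A^2 / 2 +
    (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
    (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) northing <- northing + 1e7
  cbind(x = easting, y = northing)
}
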