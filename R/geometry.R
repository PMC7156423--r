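# Self-contained geometric kernels. Coordinates are WGS84-style lon/lat
# decimal degrees; distances use a spherical Earth of radius 6371.0 km.
# Each kernel is deliberately simple enough to verify against a brute-force
# oracle (winding number, dense boundary sampling).

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0 km.
#' Vectorized over coordinate pairs with the usual recycling.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @param radius_km sphere radius.
#' @return Distance(s) in kilometers.
#' @examples
#' haversine_km(0, 0, 0, 1)    # one degree of latitude, ~111.195 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = EARTH_RADIUS_KM) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

# TRUE where point i lies on segment (x1,y1)-(x2,y2), within a tiny
# planar tolerance; vectorized over points
on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  scale <- pmax(abs(x2 - x1), abs(y2 - y1), 1)
  within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
    py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
  abs(cross) <= eps * scale & within
}

# even-odd crossing count of one ring (closed 2-col matrix), vectorized
# over points; boundary handled separately
ring_crossings <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

ring_boundary <- function(px, py, ring) {
  hit <- rep(FALSE, length(px))
  n <- nrow(ring) - 1L
  for (i in seq_len(n)) {
    hit <- hit | on_segment(px, py, ring[i, 1], ring[i, 2],
                            ring[i + 1, 1], ring[i + 1, 2])
  }
  hit
}

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting containment test for a polygon with optional holes,
#' vectorized over points. Points exactly on any boundary edge (outer ring
#' or hole ring) count as inside; interiors of holes count as outside.
#' Rings are treated as planar in lon/lat space, which is exact for the
#' polygon definitions themselves (no great-circle edges).
#'
#' @param lon,lat point coordinates, decimal degrees.
#' @param rings list of closed rings (2-column lon/lat matrices, first
#'   vertex repeated last); the first ring is the outer boundary, the rest
#'   are holes.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(lon))
  boundary <- rep(FALSE, length(lon))
  for (ring in rings) {
    inside <- xor(inside, ring_crossings(lon, lat, ring))
    boundary <- boundary | ring_boundary(lon, lat, ring)
  }
  inside | boundary
}

# densify one ring's segments to steps of at most `step` degrees
# (Chebyshev metric), endpoints included; returns a 2-col matrix
densify_ring <- function(ring, step = 0.01) {
  pts <- vector("list", nrow(ring) - 1L)
  for (i in seq_len(nrow(ring) - 1L)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    k <- max(1L, ceiling(max(abs(x2 - x1), abs(y2 - y1)) / step))
    t <- seq(0, 1, length.out = k + 1L)
    pts[[i]] <- cbind(x1 + t * (x2 - x1), y1 + t * (y2 - y1))
  }
  do.call(rbind, pts)
}

#' Distance from points to the nearest shoreline
#'
#' Minimum great-circle distance from each point to any boundary ring of a
#' polygon set. Every ring segment is densified to steps of at most
#' `step_deg` degrees and the minimum haversine distance over the densified
#' boundary points is returned; a point coinciding with a boundary vertex
#' yields 0.
#'
#' @param lon,lat point coordinates, decimal degrees.
#' @param land a [polygon_set()] (must be non-empty).
#' @param step_deg densification step in degrees.
#' @return Numeric vector of distances in kilometers.
#' @export
distance_to_shoreline_km <- function(lon, lat, land, step_deg = 0.01) {
  stopifnot(inherits(land, "polygon_set"))
  if (length(land$polygons) == 0) stop("empty polygon set: no shoreline")
  bnd <- boundary_points(land, step_deg)
  out <- numeric(length(lon))
  for (i in seq_along(lon)) {
    out[i] <- min(haversine_km(lon[i], lat[i], bnd[, 1], bnd[, 2]))
  }
  out
}

# densified boundary of a whole polygon set, cached on the object's
# environment is overkill here: sets are small, recompute per call site
boundary_points <- function(ps, step_deg = 0.01) {
  rings <- unlist(lapply(ps$polygons, `[[`, "rings"), recursive = FALSE)
  do.call(rbind, lapply(rings, densify_ring, step = step_deg))
}
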