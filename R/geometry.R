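#' Synthetic straight coastline
#'
#' A north-south coastline polyline at a fixed longitude, the synthetic
#' stand-in for the U.S. West Coast shoreline. Returned as a two-column
#' matrix of vertices (lon, lat), southern end first.
#'
#' @param lon longitude of the coastline, degrees east (negative = west).
#' @param lat_range two-element latitude range, degrees north.
#' @return matrix with columns \code{lon}, \code{lat}.
#' @export
synthetic_coastline <- function(lon = -124.5, lat_range = c(38, 49)) {
  cbind(lon = c(lon, lon), lat = sort(lat_range))
}

#' Synthetic EEZ polygon
#'
#' A rectangular Exclusive-Economic-Zone-like polygon extending offshore
#' from the synthetic coastline, used to mask habitat-suitability fields.
#' Closed ring, counter-clockwise, columns (lon, lat).
#'
#' @param coast_lon coastline longitude, degrees east.
#' @param offshore_lon western (offshore) boundary longitude, degrees east.
#' @param lat_range two-element latitude range, degrees north.
#' @return closed polygon matrix with columns \code{lon}, \code{lat}.
#' @export
synthetic_eez <- function(coast_lon = -124.5, offshore_lon = -130.5,
                          lat_range = c(38.5, 48.5)) {
  lo <- min(lat_range); hi <- max(lat_range)
  cbind(lon = c(coast_lon, coast_lon, offshore_lon, offshore_lon, coast_lon),
        lat = c(lo, hi, hi, lo, lo))
}

#' Great-circle distance from points to a coastline polyline
#'
#' For each point, the nearest point on each coastline segment is located in
#' a local equirectangular projection (exact for straight segments at these
#' scales) and the great-circle (haversine) distance to that nearest point is
#' returned, in kilometres, minimised over segments.
#'
#' @param lon,lat point coordinates, degrees.
#' @param coastline polyline vertex matrix with columns (lon, lat).
#' @return numeric vector of distances in km.
#' @export
dist_to_coast <- function(lon, lat, coastline) {
  if (is.null(coastline) || nrow(coastline) < 2L)
    stop("dist_to_coast: coastline must be a polyline with >= 2 vertices")
  n <- length(lon)
  best <- rep(Inf, n)
  km_per_deg_lat <- 110.574
  for (s in seq_len(nrow(coastline) - 1L)) {
    a <- coastline[s, ]; b <- coastline[s + 1L, ]
    ref_lat <- (a[2] + b[2]) / 2
    kx <- 111.320 * cos(ref_lat * pi / 180)
    ax <- a[1] * kx; ay <- a[2] * km_per_deg_lat
    bx <- b[1] * kx; by <- b[2] * km_per_deg_lat
    px <- lon * kx;  py <- lat * km_per_deg_lat
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, n) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    near_lon <- (ax + t * vx) / kx
    near_lat <- (ay + t * vy) / km_per_deg_lat
    d <- geosphere::distHaversine(cbind(lon, lat), cbind(near_lon, near_lat)) / 1000
    best <- pmin(best, d)
  }
  best
}

#' Test whether points fall inside a polygon
#'
#' Even-odd ray-casting point-in-polygon test in plain lon/lat coordinates
#' (adequate for the mid-latitude polygons used here). Points on an edge are
#' resolved by the half-open crossing rule.
#'
#' @param lon,lat point coordinates, degrees.
#' @param polygon closed or open ring matrix with columns (lon, lat).
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  m <- length(px)
  if (px[1] == px[m] && py[1] == py[m]) { px <- px[-m]; py <- py[-m]; m <- m - 1L }
  inside <- rep(FALSE, length(lon))
  j <- m
  for (i in seq_len(m)) {
    crosses <- ((py[i] > lat) != (py[j] > lat)) &
      (lon < (px[j] - px[i]) * (lat - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
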