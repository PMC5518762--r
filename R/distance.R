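#' Great-circle (haversine) distance
#'
#' Distance between lon/lat points on a sphere of radius 6371 km.  All
#' arguments are recycled to a common length; the result is symmetric and
#' non-negative.  Used to honour the pseudo-absence exclusion radius.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return numeric vector of distances in km.
#' @export
#' @examples
#' great_circle_km(0, 0, 1, 0)   # ~111.19 km, one degree along the equator
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 360, na.rm = TRUE))
    stop("coordinates out of range")
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}
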