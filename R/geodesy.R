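#' Geodesy constants
#'
#' Earth radius and the degree-to-kilometre conversion constant used
#' throughout the package. All great-circle computations use a spherical
#' Earth of radius 6378.137 km; one degree of arc on that sphere is
#' `t = r * 2 * pi / 360` kilometres (~111.3195 km). Longitude and latitude
#' degrees are treated with the same constant `t` (no cos-latitude factor),
#' which keeps the spread statistic isotropic in degree space; the optional
#' latitude-corrected planar projection is available via
#' [project_local_km()] and is used by the home-range module where metric
#' areas matter.
#'
#' @name geodesy-constants
#' @keywords internal
NULL

EARTH_RADIUS_KM <- 6378.137
KM_PER_DEGREE <- EARTH_RADIUS_KM * 2 * pi / 360

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude out of range [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6378.137 km. Vectorised over all
#' arguments (recycled to a common length).
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_distance(108.0, 34.0, 108.1, 34.0)  # ~9.23 km
#' @export
haversine_distance <- function(lon1, lat1, lon2, lat2) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Convert metres of ground distance to degrees of arc
#'
#' Uses the constant `t = 6378.137 * 2 * pi / 360` km per degree; the inverse
#' is [degrees_to_metres()]. The conversion is isotropic (no latitude
#' correction), matching the degree-space convention of the spread
#' statistic.
#'
#' @param x Distance in metres (nonnegative).
#' @return Arc in decimal degrees.
#' @examples
#' metres_to_degrees(513.12)  # ~0.004609 degrees
#' @export
metres_to_degrees <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("metres must be nonnegative and finite", call. = FALSE)
  x / (1000 * KM_PER_DEGREE)
}

#' @rdname metres_to_degrees
#' @param deg Arc in decimal degrees (nonnegative).
#' @export
degrees_to_metres <- function(deg) {
  if (any(!is.finite(deg)) || any(deg < 0))
    stop("degrees must be nonnegative and finite", call. = FALSE)
  deg * 1000 * KM_PER_DEGREE
}

#' Project coordinates to a local planar frame in kilometres
#'
#' Equirectangular projection about a reference point: x (east) scales
#' longitude by `cos(lat0)`, y (north) scales latitude; both use the
#' spherical degree length. Adequate for extents of a few tens of
#' kilometres, which covers collar home ranges.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param lon0,lat0 Reference point; defaults to the coordinate means.
#' @return A list with `x`, `y` (km) and the reference `lon0`, `lat0`.
#' @export
project_local_km <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  check_lonlat(lon, lat)
  list(
    x = (lon - lon0) * KM_PER_DEGREE * cos(lat0 * pi / 180),
    y = (lat - lat0) * KM_PER_DEGREE,
    lon0 = lon0, lat0 = lat0
  )
}
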