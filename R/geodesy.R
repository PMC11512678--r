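# Great-circle primitives on a sphere of radius 6371.0088 km (IUGG mean
# Earth radius). All tracks in a release experiment span < 50 km, where the
# sphere-vs-ellipsoid discrepancy is far below GPS noise.

#' Mean Earth radius in meters
#'
#' Sphere radius used by all great-circle computations in the package.
#' @export
EARTH_RADIUS_M <- 6371008.8

#' Great-circle (haversine) distance
#'
#' Distance in meters between points on the WGS84 sphere, computed with the
#' haversine formula, which is numerically stable at the short ranges
#' (< 50 km) typical of release-site work.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in meters.
#' @examples
#' geo_distance(43.657222, 10.303889, 43.657222, 10.303889) # 0
#' @export
geo_distance <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Bearing from the first point to the second, in degrees clockwise from
#' true north, in [0, 360).
#'
#' @inheritParams geo_distance
#' @return Numeric vector of bearings in degrees.
#' @export
geo_bearing <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1 - lat2) < 1e-12 & abs(lon1 - lon2) < 1e-12)) {
    stop("bearing undefined for coincident points")
  }
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Wrap an angle into (-180, 180]
#'
#' @param x Angle(s) in degrees; any real value.
#' @return Angle congruent to `x` modulo 360, in (-180, 180].
#' @examples
#' wrap_angle(270)  # -90
#' wrap_angle(-541) # 179
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

#' Destination point along a bearing
#'
#' Point reached after travelling `d` meters from a start point along an
#' initial great-circle bearing. Used to build sites from published
#' bearing/distance pairs and to lay out synthetic fixtures.
#'
#' @param lat,lon Start coordinates, decimal degrees.
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param d Distance in meters.
#' @return List with `lat` and `lon` of the destination.
#' @export
geo_destination <- function(lat, lon, bearing, d) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  th <- bearing * pi / 180
  dr <- d / EARTH_RADIUS_M
  phi2 <- asin(sin(phi) * cos(dr) + cos(phi) * sin(dr) * cos(th))
  lam2 <- lam + atan2(
    sin(th) * sin(dr) * cos(phi),
    cos(dr) - sin(phi) * sin(phi2)
  )
  list(
    lat = phi2 * 180 / pi,
    lon = (lam2 * 180 / pi + 540) %% 360 - 180
  )
}

#' Parse a degrees-minutes-seconds coordinate string
#'
#' Accepts strings such as `"43°39'26\"N"` (or with the Unicode prime marks)
#' and returns decimal degrees; S and W hemispheres are negative.
#'
#' @param x Character vector of DMS strings.
#' @return Numeric vector of decimal degrees.
#' @examples
#' parse_dms("43°39′26″N") # 43.65722...
#' @export
parse_dms <- function(x) {
  vapply(x, function(s) {
    nums <- regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s))[[1]]
    if (length(nums) < 1 || length(nums) > 3) {
      stop("cannot parse DMS string: ", s)
    }
    nums <- as.numeric(nums)
    deg <- nums[1] +
      (if (length(nums) >= 2) nums[2] / 60 else 0) +
      (if (length(nums) >= 3) nums[3] / 3600 else 0)
    hemi <- regmatches(s, regexpr("[NSEWnsew]", s))
    if (length(hemi) == 1 && toupper(hemi) %in% c("S", "W")) deg <- -deg
    deg
  }, numeric(1), USE.NAMES = FALSE)
}
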