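# The four per-bird navigation metrics, computed on a radius-bounded
# track segment: virtual vanishing time, mean vector (length/direction) of
# home-relative step directions, efficiency index and homing efficiency
# index.

segment_check <- function(segment) {
  if (!inherits(segment, "track_segment")) stop("not a track_segment")
  if (is_excluded(segment)) {
    stop("metrics undefined for excluded segment (", segment$excluded, ")")
  }
}

path_length_m <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) return(0)
  sum(geo_distance(fixes$lat[-n], fixes$lon[-n],
                   fixes$lat[-1], fixes$lon[-1]))
}

#' Home-relative step directions
#'
#' For each consecutive fix pair, the step's bearing minus the bearing to
#' the home loft at the step's start fix, wrapped to (-180, 180]. The
#' bearing to home is recomputed at every fix; within a few km of the
#' release point and ~35 km from home this differs from the fixed
#' release-site bearing by well under a degree, and the per-fix definition
#' is exact. Zero-displacement steps are skipped.
#'
#' @param segment A `track_segment`.
#' @param home List with `lat`, `lon` of the home loft.
#' @return Numeric vector of directions in degrees, home at 0.
#' @export
step_directions <- function(segment, home) {
  segment_check(segment)
  f <- segment$fixes
  n <- nrow(f)
  if (n < 2) stop("need at least 2 fixes for step directions")
  d <- geo_distance(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  keep <- d > 1e-9
  if (!any(keep)) stop("no step with nonzero displacement")
  i <- which(keep)
  step_b <- geo_bearing(f$lat[i], f$lon[i], f$lat[i + 1], f$lon[i + 1])
  home_b <- geo_bearing(f$lat[i], f$lon[i], home$lat, home$lon)
  wrap_angle(step_b - home_b)
}

#' Mean vector of a set of directions
#'
#' Cartesian average of the unit vectors of the given angles. The vector's
#' length (0-1) measures directional concentration; its angle is the mean
#' direction.
#'
#' @param dirs Directions in degrees.
#' @return List with `length` and `direction` (degrees, wrapped to
#'   (-180, 180]).
#' @export
mean_vector <- function(dirs) {
  if (length(dirs) < 1) stop("mean vector of no directions")
  th <- dirs * pi / 180
  cx <- mean(cos(th)); sy <- mean(sin(th))
  list(length = sqrt(cx^2 + sy^2),
       direction = wrap_angle(atan2(sy, cx) * 180 / pi))
}

#' Virtual vanishing time
#'
#' Seconds from release (timestamp of the bird's first raw fix) until the
#' track leaves the analysis radius for the final time (the segment's exit
#' fix).
#'
#' @param segment A `track_segment` with a valid exit fix.
#' @param release_time Optional override of the release timestamp; defaults
#'   to the `release_time` carried by the segment.
#' @return Time in seconds (> 0).
#' @export
vanishing_time <- function(segment, release_time = NULL) {
  segment_check(segment)
  if (is.na(segment$exit_index)) stop("segment has no exit fix")
  if (is.null(release_time)) release_time <- segment$release_time
  as.numeric(segment$fixes$t[segment$exit_index]) - as.numeric(release_time)
}

#' Efficiency index
#'
#' Straight-line distance between the segment's first and last (exit)
#' fixes divided by the segment's path length; 1 means a perfectly
#' straight section.
#'
#' @param segment A `track_segment`.
#' @return Value in (0, 1].
#' @export
efficiency_index <- function(segment) {
  segment_check(segment)
  f <- segment$fixes
  pl <- path_length_m(f)
  if (pl <= 0) stop("zero path length")
  n <- nrow(f)
  geo_distance(f$lat[1], f$lon[1], f$lat[n], f$lon[n]) / pl
}

#' Homing efficiency index
#'
#' Net reduction in distance-to-home over the segment divided by its path
#' length: (distance to home from the segment start minus distance to home
#' from the exit fix) / path length. Equals 1 iff the bird flew the
#' section in a straight line toward home; negative values mean net
#' movement away from home.
#'
#' @param segment A `track_segment`.
#' @param home List with `lat`, `lon` of the home loft.
#' @return Value in [-1, 1].
#' @export
homing_efficiency_index <- function(segment, home) {
  segment_check(segment)
  f <- segment$fixes
  pl <- path_length_m(f)
  if (pl <= 0) stop("zero path length")
  n <- nrow(f)
  d0 <- geo_distance(f$lat[1], f$lon[1], home$lat, home$lon)
  d1 <- geo_distance(f$lat[n], f$lon[n], home$lat, home$lon)
  (d0 - d1) / pl
}

#' Per-bird metric table
#'
#' Computes the four navigation metrics for every non-excluded segment at
#' every analysis radius.
#'
#' @param prep Output of [preprocess_tracks()].
#' @param tracks The `pigeon_trackset` (for design labels).
#' @param loft List with `lat`, `lon` of the home loft.
#' @return `data.frame` with one row per bird x radius: `bird_id`, `group`,
#'   `release_site`, `radius_m`, `vanishing_time_s`, `mean_vector_length`,
#'   `mean_direction_deg`, `efficiency_index`, `homing_efficiency_index`.
#' @export
compute_metrics <- function(prep, tracks, loft) {
  manifest <- trackset_manifest(tracks)
  segs <- list()
  radii <- numeric()
  for (r in names(prep$segments)) {
    keep <- Filter(Negate(is_excluded), prep$segments[[r]])
    segs <- c(segs, keep)
    radii <- c(radii, rep(as.numeric(r), length(keep)))
  }
  if (length(segs) == 0) stop("no analysable segments")
  mvs <- lapply(segs, function(s) mean_vector(step_directions(s, loft)))
  ids <- vapply(segs, `[[`, character(1), "bird_id")
  i <- match(ids, manifest$bird_id)
  data.frame(
    bird_id = ids,
    group = manifest$group[i],
    release_site = manifest$release_site[i],
    radius_m = radii,
    vanishing_time_s = vapply(segs, vanishing_time, numeric(1)),
    mean_vector_length = vapply(mvs, `[[`, numeric(1), "length"),
    mean_direction_deg = vapply(mvs, `[[`, numeric(1), "direction"),
    efficiency_index = vapply(segs, efficiency_index, numeric(1)),
    homing_efficiency_index =
      vapply(segs, homing_efficiency_index, numeric(1), home = loft))
}
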