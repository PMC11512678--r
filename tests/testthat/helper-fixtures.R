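# Fixture builders: small tracks laid out geometrically around a reference
# release point, and a reduced simulator configuration for fast tests.

T0 <- as.POSIXct("2021-08-11 06:35:00", tz = "UTC")
REF <- list(lat = 43.5, lon = 10.4)

# fixes placed at given distances/bearings from an origin
fixes_at <- function(dist_m, bearing_deg, origin = REF, speed = 60,
                     t0 = T0, dt = 1) {
  bearing_deg <- rep_len(bearing_deg, length(dist_m))
  pts <- Map(function(d, b) {
    if (d == 0) list(lat = origin$lat, lon = origin$lon)
    else geo_destination(origin$lat, origin$lon, b, d)
  }, dist_m, bearing_deg)
  data.frame(lat = vapply(pts, `[[`, numeric(1), "lat"),
             lon = vapply(pts, `[[`, numeric(1), "lon"),
             t = t0 + (seq_along(dist_m) - 1) * dt,
             speed = rep_len(speed, length(dist_m)))
}

mk_track <- function(fixes, bird_id = "b1", release_site = "1",
                     exposure_site = "1") {
  pigeon_track(bird_id, fixes, release_site, exposure_site)
}

# a beeline track from `origin` along `bearing`, one fix per `step_m`
beeline_fixes <- function(origin, bearing, step_m = 25, total_m = 2500,
                          speed = 90, t0 = T0) {
  fixes_at(seq(0, total_m, by = step_m), bearing, origin, speed, t0)
}

# reduced synthetic study: no followers, fewer birds, 2 km radius focus
small_sim <- function(seed, ...) {
  sim_config(seed = seed, n_birds_per_cell = c(4, 4, 4, 4),
             follower_pairs = 0, ...)
}

cfg_2km <- function(...) homing_config(analysis_radii_m = 2000, ...)

# run strip -> speed filter -> segment for a single track
segment_of <- function(track, release_point, radius,
                       escape = 500, min_speed = 5) {
  rt <- track$fixes$t[1]
  tr <- strip_escape_radius(track, release_point, escape)
  if (inherits(tr, "track_segment")) return(tr)
  tr <- filter_speed(tr, min_speed)
  final_exit_segment(tr, release_point, radius, release_time = rt)
}
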