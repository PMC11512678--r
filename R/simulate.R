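# Synthetic release studies: a biased correlated random walk (BCRW)
# generator emitting 1 Hz GPS fix streams with an initial undirected escape
# phase, stop episodes below the 5 km/h cut, site-specific directional bias
# and orientation-strength handicap, an optional treatment effect on
# orientation strength, follower dyads, and GPS noise.

#' The home loft used by the default study layout
#'
#' Arnino field-station coordinates (43 deg 39' 26" N, 10 deg 18' 14" E).
#'
#' @return List with `lat`, `lon`.
#' @export
default_loft <- function() {
  list(lat = parse_dms("43°39′26″N"),
       lon = parse_dms("10°18′14″E"))
}

site_from_home_vector <- function(site_id, loft, home_bearing,
                                  home_distance_km) {
  # place the site so that bearing(site -> loft) = home_bearing; one
  # correction pass absorbs great-circle convergence
  b <- (home_bearing + 180) %% 360
  p <- geo_destination(loft$lat, loft$lon, b, home_distance_km * 1000)
  err <- wrap_angle(geo_bearing(p$lat, p$lon, loft$lat, loft$lon) -
                      home_bearing)
  p <- geo_destination(loft$lat, loft$lon, (b - err) %% 360,
                       home_distance_km * 1000)
  release_site(site_id, p$lat, p$lon, home_bearing, home_distance_km)
}

#' Default release sites
#'
#' Two sites laid out from the loft by their published home bearings and
#' distances: site 1 at 34.2 km with home bearing 261 degrees, site 2 at
#' 39.3 km with home bearing 336 degrees.
#'
#' @param loft Home loft, default [default_loft()].
#' @return Named list of two [release_site()] records (`"1"`, `"2"`).
#' @export
default_sites <- function(loft = default_loft()) {
  list("1" = site_from_home_vector("1", loft, 261, 34.2),
       "2" = site_from_home_vector("2", loft, 336, 39.3))
}

#' Analysis configuration
#'
#' Thresholds of the preprocessing cascade; every default is the study
#' procedure's stated value.
#'
#' @param escape_radius_m Escape-strip radius, meters (default 500).
#' @param analysis_radii_m Analysis radii, meters (default 2000 and 5000).
#' @param min_speed_kmh Stop-filter threshold, km/h (default 5).
#' @param following List of following-surrogate thresholds: `d_max_m`
#'   (100), `t_min_s` (120), `slack_s` (2).
#' @param alpha Test size for all inference (default 0.05).
#' @param seed Seed for the same-group following exclusion draw.
#' @return List of class `homing_config`.
#' @export
homing_config <- function(escape_radius_m = 500,
                          analysis_radii_m = c(2000, 5000),
                          min_speed_kmh = 5,
                          following = list(d_max_m = 100, t_min_s = 120,
                                           slack_s = 2),
                          alpha = 0.05, seed = 1L) {
  structure(list(escape_radius_m = escape_radius_m,
                 analysis_radii_m = sort(analysis_radii_m),
                 min_speed_kmh = min_speed_kmh, following = following,
                 alpha = alpha, seed = as.integer(seed)),
            class = "homing_config")
}

#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The defaults emulate the
#' study's conditions: a 2 x 2 release-by-exposure design with cell counts
#' 12/12/12/13, 1 Hz sampling, cruising flight near 60 km/h, an initial
#' minute of undirected escape circling, occasional stops under the 5 km/h
#' cut, site-specific anticlockwise deflection of the goal direction with a
#' weaker orientation weight at site 2, follower dyads, and meter-scale GPS
#' noise. `treatment_effect = 0` encodes the study's null result; raise it
#' to inject a true exposure effect on orientation strength.
#'
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param n_birds_per_cell Cell counts, in the order released-at-1
#'   experimental, released-at-1 control, released-at-2 control,
#'   released-at-2 experimental.
#' @param sites Named list of [release_site()] records.
#' @param loft Home loft coordinates.
#' @param sampling_hz Fix rate; the generator emits 1 fix per second.
#' @param flight_speed_mean_kmh,flight_speed_sd_kmh Cruising speed
#'   distribution.
#' @param kappa Von Mises concentration of the heading noise.
#' @param bias_weight Baseline weight w of the homeward bias in the
#'   heading mixture, in [0, 1].
#' @param site_bias_offset_deg Named per-site angular deflection (degrees,
#'   negative = anticlockwise) added to the goal direction.
#' @param site_bias_w_decrement Named per-site decrement of `bias_weight`
#'   (release-site handicap).
#' @param treatment_effect Additive increment to w for experimental birds.
#' @param stop_rate_per_min Per-minute probability of entering a stop
#'   episode.
#' @param stop_mean_s Mean stop duration, seconds (geometric).
#' @param escape_phase_s Duration of the initial undirected phase, seconds.
#' @param follower_pairs Number of follower dyads to insert.
#' @param gps_noise_sd_m Positional noise SD, meters.
#' @param exit_distance_m Simulation stops once the bird is this far from
#'   the release point (default 6000 m, beyond the largest analysis
#'   radius).
#' @param max_duration_s Hard cap on track length, seconds.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_birds_per_cell = c(12, 12, 12, 13),
                       sites = default_sites(), loft = default_loft(),
                       sampling_hz = 1,
                       flight_speed_mean_kmh = 60,
                       flight_speed_sd_kmh = 8,
                       kappa = 6, bias_weight = 0.15,
                       site_bias_offset_deg = c("1" = -10, "2" = -25),
                       site_bias_w_decrement = c("1" = 0, "2" = 0.08),
                       treatment_effect = 0,
                       stop_rate_per_min = 0.5, stop_mean_s = 25,
                       escape_phase_s = 60, follower_pairs = 8,
                       gps_noise_sd_m = 3, exit_distance_m = 6000,
                       max_duration_s = 3600) {
  stopifnot(bias_weight >= 0, bias_weight + treatment_effect <= 1,
            flight_speed_mean_kmh > 0, kappa >= 0)
  structure(as.list(environment()), class = "sim_config")
}

local_to_latlon <- function(x, y, origin) {
  lat <- origin$lat + (y / EARTH_RADIUS_M) * 180 / pi
  lon <- origin$lon +
    (x / (EARTH_RADIUS_M * cos(origin$lat * pi / 180))) * 180 / pi
  list(lat = lat, lon = lon)
}

#' Simulate one bird's track
#'
#' Biased correlated random walk from a release site: each second the
#' heading is drawn from a von Mises distribution centred on the circular
#' mixture of the previous heading and the (site-deflected) bearing toward
#' home, weighted by the bird's effective bias weight. The walk starts with
#' an undirected escape phase and ends once the bird is
#' `exit_distance_m` from the release point (or at `max_duration_s`).
#'
#' @param cfg A [sim_config()].
#' @param bird_id Identifier for the track.
#' @param site_id Release-site key into `cfg$sites`.
#' @param group `"experimental"` or `"control"`.
#' @param exposure_site Exposure-site label (defaults to the design rule).
#' @param release_time `POSIXct` of the first fix.
#' @return A [pigeon_track()]; attribute `w_eff` records the generating
#'   bias weight.
#' @export
simulate_bird <- function(cfg, bird_id, site_id, group,
                          exposure_site = NULL,
                          release_time = as.POSIXct("2021-08-11 06:35:00",
                                                    tz = "UTC")) {
  site <- cfg$sites[[as.character(site_id)]]
  w_eff <- cfg$bias_weight +
    (group == "experimental") * cfg$treatment_effect -
    unname(cfg$site_bias_w_decrement[as.character(site_id)])
  w_eff <- min(1, max(0, w_eff))
  home_b <- geo_bearing(site$lat, site$lon, cfg$loft$lat, cfg$loft$lon)
  home_d <- geo_distance(site$lat, site$lon, cfg$loft$lat, cfg$loft$lon)
  m <- bcrw_simulate_cpp(
    w = w_eff, kappa = cfg$kappa,
    speed_mean_kmh = cfg$flight_speed_mean_kmh,
    speed_sd_kmh = cfg$flight_speed_sd_kmh,
    home_x = home_d * sin(home_b * pi / 180),
    home_y = home_d * cos(home_b * pi / 180),
    bias_offset_rad =
      unname(cfg$site_bias_offset_deg[as.character(site_id)]) * pi / 180,
    stop_rate_per_min = cfg$stop_rate_per_min,
    stop_mean_s = cfg$stop_mean_s,
    escape_s = as.integer(cfg$escape_phase_s),
    gps_noise_sd = cfg$gps_noise_sd_m,
    exit_distance_m = cfg$exit_distance_m,
    max_steps = as.integer(cfg$max_duration_s * cfg$sampling_hz))
  ll <- local_to_latlon(m[, "x"], m[, "y"],
                        list(lat = site$lat, lon = site$lon))
  fixes <- data.frame(lat = ll$lat, lon = ll$lon,
                      t = release_time + seq_len(nrow(m)) - 1,
                      speed = m[, "speed_kmh"])
  if (is.null(exposure_site)) {
    exposure_site <- if (group == "experimental") {
      site_id
    } else {
      setdiff(names(cfg$sites), as.character(site_id))[1]
    }
  }
  tr <- pigeon_track(bird_id, fixes, site_id, exposure_site, group)
  attr(tr, "w_eff") <- w_eff
  tr
}

#' Simulate a complete release study
#'
#' Generates the 2 x 2 design (release site x treatment group) with the
#' configured cell counts, staggered individual releases on two release
#' days (one per site), and the configured number of follower dyads: each
#' follower's track is replaced by its leader's path with meter-scale
#' lateral jitter so the dyad is detectable by [detect_following()]. The
#' per-bird generating parameters are returned as a truth table for
#' parameter-recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_study`: `tracks` (a `pigeon_trackset`),
#'   `manifest`, and `truth` (`data.frame` with per-bird `w_eff`,
#'   `follower_of`, `release_time`).
#' @export
simulate_study <- function(cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cells <- data.frame(
    release_site = c("1", "1", "2", "2"),
    group = c("experimental", "control", "control", "experimental"),
    n = cfg$n_birds_per_cell)
  day <- c("1" = as.POSIXct("2021-08-11 06:35:00", tz = "UTC"),
           "2" = as.POSIXct("2021-08-13 06:35:00", tz = "UTC"))
  # interleave treatments within a release day (released alternately)
  birds <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    if (cells$n[i] == 0) return(NULL)
    data.frame(release_site = cells$release_site[i],
               group = cells$group[i], ord = seq_len(cells$n[i]))
  }))
  birds <- birds[order(birds$release_site, birds$ord, birds$group), ]
  birds$bird_id <- sprintf("b%02d", seq_len(nrow(birds)))
  slot <- stats::ave(seq_len(nrow(birds)), birds$release_site,
                     FUN = seq_along)
  birds$release_time <- day[birds$release_site] + (slot - 1) * 360

  tracks <- vector("list", nrow(birds))
  names(tracks) <- birds$bird_id
  for (i in seq_len(nrow(birds))) {
    tracks[[i]] <- simulate_bird(cfg, birds$bird_id[i],
                                 birds$release_site[i], birds$group[i],
                                 release_time = birds$release_time[i])
  }
  truth <- data.frame(
    bird_id = birds$bird_id,
    release_site = vapply(tracks, `[[`, character(1), "release_site"),
    exposure_site = vapply(tracks, `[[`, character(1), "exposure_site"),
    group = vapply(tracks, `[[`, character(1), "group"),
    w_eff = vapply(tracks, function(t) attr(t, "w_eff"), numeric(1)),
    follower_of = NA_character_,
    release_time = birds$release_time)
  rownames(truth) <- NULL

  n_pairs <- min(cfg$follower_pairs, floor(nrow(birds) / 2))
  if (n_pairs > 0) {
    for (k in seq_len(n_pairs)) {
      # draw a leader and a same-site partner not yet in any dyad
      free <- truth$bird_id[is.na(truth$follower_of) &
                              !truth$bird_id %in% truth$follower_of]
      leaders <- sample(free, length(free))
      pair <- NULL
      for (ld in leaders) {
        site_ld <- truth$release_site[truth$bird_id == ld]
        mates <- setdiff(free[truth$release_site[match(free, truth$bird_id)]
                              == site_ld], ld)
        if (length(mates) > 0) {
          pair <- c(ld, sample(mates, 1))
          break
        }
      }
      if (is.null(pair)) break
      lead <- tracks[[pair[1]]]
      fol <- tracks[[pair[2]]]
      ang <- stats::runif(1, 0, 2 * pi)
      off <- local_to_latlon(30 * sin(ang), 30 * cos(ang),
                             list(lat = 0, lon = 0))  # ~30 m offset
      f2 <- lead$fixes
      nse <- local_to_latlon(stats::rnorm(nrow(f2), 0, 8),
                             stats::rnorm(nrow(f2), 0, 8),
                             list(lat = 0, lon = 0))
      f2$lat <- f2$lat + off$lat + (nse$lat - 0)
      f2$lon <- f2$lon + off$lon + (nse$lon - 0)
      fol$fixes <- f2
      tracks[[pair[2]]] <- fol
      truth$follower_of[truth$bird_id == pair[2]] <- pair[1]
      truth$release_time[truth$bird_id == pair[2]] <-
        truth$release_time[truth$bird_id == pair[1]]
    }
  }
  tracks <- structure(tracks, class = "pigeon_trackset")
  list(tracks = tracks, manifest = trackset_manifest(tracks),
       truth = truth)
}

#' Calibrate the treatment effect for a target partial eta-squared
#'
#' Finds the `treatment_effect` increment whose induced standardized group
#' difference on a chosen metric matches a target partial eta-squared in
#' the additive model at a given sample size. The target standardized
#' difference is d = 2 sqrt(f2) (balanced groups, f2 = eta / (1 - eta));
#' the mapping from increment to achieved d is estimated by simulation on
#' a grid and inverted by linear interpolation.
#'
#' @param cfg Base [sim_config()] (its `treatment_effect` is ignored).
#' @param target_eta_sq Target partial eta-squared (default 0.26).
#' @param metric Metric used for calibration (default efficiency index).
#' @param radius_m Analysis radius (default 2000).
#' @param deltas Candidate increments.
#' @param reps Simulated studies per candidate.
#' @param config Analysis configuration.
#' @return The calibrated increment (numeric), with the grid of achieved
#'   standardized differences as attribute `"grid"`.
#' @export
calibrate_treatment_effect <- function(cfg, target_eta_sq = 0.26,
                                       metric = "efficiency_index",
                                       radius_m = 2000,
                                       deltas = c(0.04, 0.06, 0.08),
                                       reps = 160,
                                       config = homing_config()) {
  f2 <- target_eta_sq / (1 - target_eta_sq)
  d_target <- 2 * sqrt(f2)
  mean_d <- function(dl) {
    cfg2 <- cfg
    cfg2$treatment_effect <- dl
    mean(vapply(seq_len(reps), function(r) {
      cfg2$seed <- cfg$seed + 1000L * r
      st <- simulate_study(cfg2)
      prep <- preprocess_tracks(st$tracks, cfg2$sites,
                                within_radii(config, radius_m))
      met <- compute_metrics(prep, st$tracks, cfg2$loft)
      effect_sizes(fit_metric_model(met, metric, radius_m),
                   "group")$cohens_d
    }, numeric(1)))
  }
  deltas <- sort(deltas)
  achieved <- vapply(deltas, mean_d, numeric(1))
  # widen the grid until it brackets the target effect
  tries <- 0
  while (d_target < min(achieved) && min(deltas) > 0.005 && tries < 4) {
    dl <- min(deltas) / 2
    deltas <- c(dl, deltas)
    achieved <- c(mean_d(dl), achieved)
    tries <- tries + 1
  }
  while (d_target > max(achieved) &&
         max(deltas) < 1 - cfg$bias_weight && tries < 8) {
    dl <- min(1.5 * max(deltas), 1 - cfg$bias_weight)
    deltas <- c(deltas, dl)
    achieved <- c(achieved, mean_d(dl))
    tries <- tries + 1
  }
  grid <- data.frame(delta = deltas, d = achieved)
  delta_star <- stats::approx(achieved, deltas, xout = d_target,
                              rule = 2, ties = "ordered")$y
  attr(delta_star, "grid") <- grid
  delta_star
}

within_radii <- function(config, radii) {
  config$analysis_radii_m <- radii
  config
}
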