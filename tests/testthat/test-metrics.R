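# home ~34 km west of the reference release point, like the study layout
HOME_W <- geo_destination(REF$lat, REF$lon, 261, 34200)

test_that("step directions are zero toward home and 180 away from it", {
  b_home <- geo_bearing(REF$lat, REF$lon, HOME_W$lat, HOME_W$lon)
  seg <- segment_of(mk_track(fixes_at(seq(600, 2400, by = 200), b_home)),
                    REF, 2000)
  toward <- step_directions(seg, HOME_W)
  expect_true(all(abs(toward) < 0.1))
  away <- segment_of(
    mk_track(fixes_at(seq(600, 2400, by = 200), (b_home + 180) %% 360)),
    REF, 2000)
  expect_true(all(abs(abs(step_directions(away, HOME_W)) - 180) < 0.1))
})

test_that("square-path step directions match a planar oracle within 0.1 degree", {
  # home close (3 km south) so the flat-earth oracle is exact to ~0.01 deg
  HOME_N <- geo_destination(REF$lat, REF$lon, 180, 3000)
  # legs east, north, west, each 200 m, starting 600 m east of release
  p0 <- geo_destination(REF$lat, REF$lon, 90, 600)
  p1 <- geo_destination(p0$lat, p0$lon, 90, 200)
  p2 <- geo_destination(p1$lat, p1$lon, 0, 200)
  p3 <- geo_destination(p2$lat, p2$lon, 270, 200)
  fx <- data.frame(lat = c(p0$lat, p1$lat, p2$lat, p3$lat),
                   lon = c(p0$lon, p1$lon, p2$lon, p3$lon),
                   t = T0 + 0:3, speed = 60)
  seg <- track_segment("sq", 2000, fx, REF, exit_index = 4,
                       release_time = T0)
  got <- step_directions(seg, HOME_N)
  # planar oracle: local east/north meters relative to the release point
  to_xy <- function(p) {
    c(x = geo_distance(REF$lat, REF$lon, REF$lat, p$lon) *
        sign(p$lon - REF$lon),
      y = geo_distance(REF$lat, REF$lon, p$lat, REF$lon) *
        sign(p$lat - REF$lat))
  }
  pts <- rbind(to_xy(p0), to_xy(p1), to_xy(p2), to_xy(p3))
  home <- to_xy(HOME_N)
  oracle <- sapply(1:3, function(i) {
    step_b <- atan2(pts[i + 1, 1] - pts[i, 1], pts[i + 1, 2] - pts[i, 2])
    home_b <- atan2(home[1] - pts[i, 1], home[2] - pts[i, 2])
    wrap_angle((step_b - home_b) * 180 / pi)
  })
  expect_equal(got, unname(oracle), tolerance = 0.1)
})

test_that("mean vector matches closed forms", {
  expect_equal(mean_vector(rep(37, 5))$length, 1, tolerance = 1e-12)
  expect_equal(mean_vector(rep(37, 5))$direction, 37)
  expect_lt(mean_vector(c(0, 90, 180, 270))$length, 1e-9)
  mv <- mean_vector(c(0, 90))
  expect_equal(mv$length, cos(pi / 4), tolerance = 1e-12)
  expect_equal(mv$direction, 45, tolerance = 1e-9)
  expect_error(mean_vector(numeric()), "no directions")
})

test_that("mean vector length is rotation invariant; direction rotates along", {
  set.seed(4)
  dirs <- runif(40, -180, 180)
  base <- mean_vector(dirs)
  for (rot in c(30, 123, -77)) {
    r <- mean_vector(wrap_angle(dirs + rot))
    expect_equal(r$length, base$length, tolerance = 1e-12)
    expect_equal(wrap_angle(r$direction - base$direction - rot), 0,
                 tolerance = 1e-9)
  }
})

test_that("vanishing time is exit-fix time minus the raw release time", {
  # 75.6 km/h beeline: 21 m/s, one fix per second from the release point
  fx <- fixes_at(seq(0, 2500, by = 21), 45, speed = 21 * 3.6)
  tr <- mk_track(fx)
  seg <- segment_of(tr, REF, 2000)
  # last fix inside 2000 m is 1995 m at t = 95 s; exit fix at t = 96 s
  expect_equal(vanishing_time(seg), 96)
  # loitering inside the radius counts toward the vanishing time
  d_loiter <- c(seq(0, 1000, by = 60 / 3.6),
                rep(c(1000, 1010), 300),
                seq(1010, 2500, by = 60 / 3.6))
  loiter <- mk_track(fixes_at(d_loiter, 45, speed = 60))
  seg_l <- segment_of(loiter, REF, 2000)
  expect_gt(vanishing_time(seg_l), 600)
})

test_that("vanishing time at 5 km is never below vanishing time at 2 km", {
  st <- simulate_study(small_sim(5))
  prep <- preprocess_tracks(st$tracks, default_sites(), homing_config())
  met <- compute_metrics(prep, st$tracks, default_loft())
  wide <- merge(met[met$radius_m == 2000, c("bird_id", "vanishing_time_s")],
                met[met$radius_m == 5000, c("bird_id", "vanishing_time_s")],
                by = "bird_id", suffixes = c("_2", "_5"))
  expect_gt(nrow(wide), 5)
  expect_true(all(wide$vanishing_time_s_5 >= wide$vanishing_time_s_2))
})

test_that("efficiency index: straight = 1, right angle = 5/7, out-and-back ~ 0", {
  straight <- segment_of(mk_track(fixes_at(seq(600, 2400, by = 100), 45)),
                         REF, 2000)
  expect_equal(efficiency_index(straight), 1, tolerance = 1e-6)

  # 3 km east then 4 km north, no radius truncation: EI = 5/7
  east <- fixes_at(seq(0, 3000, by = 100), 90)
  corner <- list(lat = east$lat[nrow(east)], lon = east$lon[nrow(east)])
  north <- fixes_at(seq(100, 4000, by = 100), 0, origin = corner,
                    t0 = T0 + nrow(east))
  fx <- rbind(east, north)
  seg <- track_segment("ra", 10000, fx, REF, exit_index = nrow(fx),
                       release_time = T0)
  expect_equal(efficiency_index(seg), 5 / 7, tolerance = 1e-3)

  # out at 45 degrees and back, ending 20 m from the start fix
  fxo <- rbind(fixes_at(seq(600, 2600, by = 100), 45),
               fixes_at(c(seq(2500, 700, by = -100), 620), 45,
                        t0 = T0 + 21))
  seg_ob <- track_segment("ob", 2650, fxo, REF,
                          exit_index = nrow(fxo), release_time = T0)
  expect_lt(efficiency_index(seg_ob), 0.01)
})

test_that("homing efficiency: 1 toward home, ~0 crosswind, -1 away", {
  b_home <- geo_bearing(REF$lat, REF$lon, HOME_W$lat, HOME_W$lon)
  toward <- segment_of(mk_track(beeline_fixes(REF, b_home)), REF, 2000)
  expect_equal(homing_efficiency_index(toward, HOME_W), 1,
               tolerance = 1e-6)
  cross <- segment_of(mk_track(beeline_fixes(REF, b_home + 90)), REF, 2000)
  expect_lt(abs(homing_efficiency_index(cross, HOME_W)), 0.05)
  away <- segment_of(mk_track(beeline_fixes(REF, b_home + 180)), REF, 2000)
  expect_equal(homing_efficiency_index(away, HOME_W), -1,
               tolerance = 1e-6)
})

test_that("homing efficiency never exceeds efficiency; duplicates change nothing", {
  st <- simulate_study(small_sim(13))
  prep <- preprocess_tracks(st$tracks, default_sites(), homing_config())
  loft <- default_loft()
  n_checked <- 0
  for (r in names(prep$segments)) {
    for (s in prep$segments[[r]]) {
      if (is_excluded(s)) next
      n_checked <- n_checked + 1
      expect_lte(homing_efficiency_index(s, loft),
                 efficiency_index(s) + 1e-12)
    }
  }
  expect_gt(n_checked, 10)

  # duplicate a mid-track fix (same position, new timestamp): all four
  # metrics are unchanged
  s <- Filter(Negate(is_excluded), prep$segments[["2000"]])[[1]]
  f <- s$fixes
  k <- floor(nrow(f) / 2)
  dup <- f[k, ]
  dup$t <- dup$t + 0.5
  s2 <- s
  s2$fixes <- rbind(f[1:k, ], dup, f[(k + 1):nrow(f), ])
  s2$exit_index <- s$exit_index + 1
  expect_equal(efficiency_index(s2), efficiency_index(s), tolerance = 1e-9)
  expect_equal(homing_efficiency_index(s2, loft),
               homing_efficiency_index(s, loft), tolerance = 1e-9)
  expect_equal(vanishing_time(s2), vanishing_time(s))
  expect_equal(mean_vector(step_directions(s2, loft))$length,
               mean_vector(step_directions(s, loft))$length,
               tolerance = 1e-9)
})
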