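test_that("escape strip removes only the leading run inside the escape radius", {
  tr <- mk_track(fixes_at(c(100, 300, 600, 400, 900), 45))
  out <- strip_escape_radius(tr, REF, 500)
  d <- round(geo_distance(out$fixes$lat, out$fixes$lon, REF$lat, REF$lon))
  expect_equal(d, c(600, 400, 900))  # re-entry at 400 m retained

  all_in <- mk_track(fixes_at(rep(50, 5), 45))
  out2 <- strip_escape_radius(all_in, REF, 500)
  expect_s3_class(out2, "track_segment")
  expect_identical(out2$excluded, "never_exited")

  clear <- mk_track(fixes_at(c(700, 800, 900), 45))
  out3 <- strip_escape_radius(clear, REF, 500)
  expect_identical(out3$fixes, clear$fixes)
})

test_that("speed filter drops fixes strictly below the threshold", {
  tr <- mk_track(fixes_at(c(600, 700, 800, 900), 45,
                          speed = c(0, 4.9, 5.0, 60)))
  out <- filter_speed(tr, 5)
  expect_equal(out$fixes$speed, c(5.0, 60))
  fast <- mk_track(fixes_at(c(600, 700), 45, speed = c(10, 20)))
  expect_identical(filter_speed(fast, 5)$fixes, fast$fixes)
})

test_that("final-exit segmentation matches the hand-traced definition", {
  tr <- mk_track(fixes_at(c(600, 1500, 2100, 1800, 2500, 3000), 45))
  seg <- final_exit_segment(tr, REF, 2000)
  expect_false(is_excluded(seg))
  expect_equal(nrow(seg$fixes), 5)     # up to and including the 2500 m fix
  expect_equal(seg$exit_index, 5)
  d_exit <- geo_distance(seg$fixes$lat[5], seg$fixes$lon[5],
                         REF$lat, REF$lon)
  expect_equal(round(d_exit), 2500)
})

test_that("oscillating tracks segment at the final exit; monotone tracks at the only exit", {
  osc <- c(600, 2100, 900, 2200, 1000, 2300, 1100, 2400, 2600, 3000)
  seg <- final_exit_segment(mk_track(fixes_at(osc, 45)), REF, 2000)
  expect_equal(seg$exit_index, 8)  # last inside = 1100 m (idx 7), exit = 2400 m
  expect_equal(nrow(seg$fixes), 8)
  mono <- final_exit_segment(mk_track(fixes_at(seq(600, 3000, by = 300),
                                               45)), REF, 2000)
  expect_equal(mono$exit_index, which(seq(600, 3000, by = 300) > 2000)[1])
})

test_that("degenerate tracks are excluded with the right reason", {
  stays <- mk_track(fixes_at(c(600, 900, 1200, 1500), 45))
  expect_identical(final_exit_segment(stays, REF, 2000)$excluded,
                   "never_exited")
  tiny <- mk_track(fixes_at(c(600, 2500), 45))
  expect_identical(final_exit_segment(tiny, REF, 2000)$excluded,
                   "too_few_fixes")
})

test_that("the 2 km segment is a prefix of the 5 km segment of the same track", {
  set.seed(21)
  st <- simulate_study(small_sim(77))
  sites <- default_sites()
  for (tr in st$tracks[1:6]) {
    rp <- list(lat = sites[[tr$release_site]]$lat,
               lon = sites[[tr$release_site]]$lon)
    s2 <- segment_of(tr, rp, 2000)
    s5 <- segment_of(tr, rp, 5000)
    if (is_excluded(s2) || is_excluded(s5)) next
    n2 <- nrow(s2$fixes)
    expect_true(nrow(s5$fixes) >= n2)
    expect_equal(s5$fixes[seq_len(n2 - 1), ], s2$fixes[seq_len(n2 - 1), ])
  }
})

test_that("following detection finds constructed dyads and ignores disjoint tracks", {
  path <- seq(600, 5000, by = 18)  # ~65 km/h beeline
  lead <- mk_track(fixes_at(path, 45), "L")
  # same path shifted 30 m sideways
  off <- geo_destination(REF$lat, REF$lon, 135, 30)
  fol <- mk_track(fixes_at(path, 45, origin = off), "F")
  ev <- detect_following(list(lead, fol), d_max = 100, t_min = 120)
  expect_equal(nrow(ev), 1)
  expect_setequal(c(ev$bird_a, ev$bird_b), c("L", "F"))
  expect_lt(ev$median_separation_m, 50)

  late <- mk_track(fixes_at(path, 45, t0 = T0 + 7200), "F")
  expect_equal(nrow(detect_following(list(lead, late))), 0)

  clone <- mk_track(fixes_at(path, 45), "L")  # same id: never a pair
  expect_equal(nrow(detect_following(list(lead, clone))), 0)
})

test_that("exclusion rule: one of a same-group pair, both of a cross-group pair", {
  fx <- fixes_at(c(600, 700, 800), 45)
  mk <- function(id, exposure) mk_track(fx, id, "1", exposure)
  tracks <- structure(list(a = mk("a", "1"), b = mk("b", "1"),
                           c = mk("c", "2")), class = "pigeon_trackset")
  same <- data.frame(bird_a = "a", bird_b = "b")
  ex1 <- apply_following_exclusions(same, tracks, seed = 5)
  expect_length(ex1, 1)
  expect_true(ex1 %in% c("a", "b"))
  cross <- data.frame(bird_a = "a", bird_b = "c")
  expect_setequal(apply_following_exclusions(cross, tracks, seed = 5),
                  c("a", "c"))
  expect_length(apply_following_exclusions(same[0, ], tracks, seed = 5), 0)
  # idempotent across repeated events, reproducible under the same seed
  both <- rbind(same, same, cross)
  exb <- apply_following_exclusions(both, tracks, seed = 5)
  expect_identical(exb, apply_following_exclusions(both, tracks, seed = 5))
  expect_true(all(c("a", "c") %in% exb))
})

test_that("exclusion bookkeeping: analysed birds = input birds - exclusions", {
  st <- simulate_study(sim_config(seed = 31))
  prep <- preprocess_tracks(st$tracks, default_sites(), homing_config())
  met <- compute_metrics(prep, st$tracks, default_loft())
  for (r in c(2000, 5000)) {
    n_excl <- sum(prep$exclusions$radius_m == r, na.rm = TRUE) +
      sum(is.na(prep$exclusions$radius_m))
    expect_equal(sum(met$radius_m == r), length(st$tracks) - n_excl)
  }
  # same seed reproduces the identical exclusion set
  prep2 <- preprocess_tracks(st$tracks, default_sites(), homing_config())
  expect_identical(prep$exclusions, prep2$exclusions)
})
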