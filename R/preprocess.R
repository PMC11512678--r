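# Track filtering and release-site segmentation: escape-radius strip,
# stop (slow-fix) removal, final-exit segmentation at an analysis radius,
# and dyadic following detection with the group-dependent exclusion rule.

#' Construct a track segment
#'
#' The radius-bounded analysis section of one bird's filtered track. Not
#' normally called directly; produced by [final_exit_segment()] and
#' [preprocess_tracks()].
#'
#' @param bird_id Bird identifier.
#' @param radius Analysis radius in meters.
#' @param fixes Fix `data.frame` (ending at the exit fix when not excluded).
#' @param release_point List with `lat`, `lon` of the release point.
#' @param exit_index Index (into `fixes`) of the exit fix, or `NA`.
#' @param release_time `POSIXct` timestamp of the bird's first raw fix.
#' @param excluded Exclusion reason: `"none"`, `"following"`,
#'   `"never_exited"` or `"too_few_fixes"`.
#' @return Object of class `track_segment`.
#' @export
track_segment <- function(bird_id, radius, fixes, release_point,
                          exit_index = NA_integer_, release_time = NULL,
                          excluded = "none") {
  excluded <- match.arg(excluded,
                        c("none", "following", "never_exited",
                          "too_few_fixes"))
  structure(list(bird_id = as.character(bird_id), radius = radius,
                 fixes = fixes, release_point = release_point,
                 exit_index = exit_index, release_time = release_time,
                 excluded = excluded),
            class = "track_segment")
}

#' @export
print.track_segment <- function(x, ...) {
  if (x$excluded == "none") {
    cat(sprintf("<track_segment> bird %s at %g m: %d fixes, exit fix #%d\n",
                x$bird_id, x$radius, nrow(x$fixes), x$exit_index))
  } else {
    cat(sprintf("<track_segment> bird %s at %g m: excluded (%s)\n",
                x$bird_id, x$radius, x$excluded))
  }
  invisible(x)
}

#' Is a segment excluded?
#' @param x A `track_segment`.
#' @return Logical.
#' @export
is_excluded <- function(x) !identical(x$excluded, "none")

dist_to_point <- function(fixes, point) {
  geo_distance(fixes$lat, fixes$lon, point$lat, point$lon)
}

#' Remove the initial escape-phase fixes
#'
#' Drops the leading run of fixes within `r_escape` of the release point;
#' later re-entries into the escape circle are kept (only the *initial*
#' fixes capture the escape response).
#'
#' @param track A `pigeon_track`.
#' @param release_point List with `lat`, `lon`.
#' @param r_escape Escape radius in meters (default 500).
#' @return The stripped `pigeon_track`, or a `track_segment` flagged
#'   `never_exited` when no fix lies beyond `r_escape`.
#' @export
strip_escape_radius <- function(track, release_point, r_escape = 500) {
  d <- dist_to_point(track$fixes, release_point)
  out <- which(d > r_escape)
  if (length(out) == 0) {
    return(track_segment(track$bird_id, r_escape, track$fixes[0, ],
                         release_point,
                         release_time = track$fixes$t[1],
                         excluded = "never_exited"))
  }
  first_out <- out[1]
  if (first_out > 1) {
    track$fixes <- track$fixes[first_out:nrow(track$fixes), , drop = FALSE]
    rownames(track$fixes) <- NULL
  }
  track
}

#' Remove stop fixes by logger speed
#'
#' Drops fixes with recorded speed strictly below `min_speed` km/h (the
#' boundary value is kept); removal count is logged via `message()`.
#'
#' @param track A `pigeon_track`.
#' @param min_speed Threshold in km/h (default 5).
#' @param quiet Suppress the removal-count message.
#' @return The filtered `pigeon_track` (possibly with < 2 fixes).
#' @export
filter_speed <- function(track, min_speed = 5, quiet = TRUE) {
  keep <- track$fixes$speed >= min_speed
  n_drop <- sum(!keep)
  if (n_drop > 0 && !quiet) {
    message("bird ", track$bird_id, ": ", n_drop, " stop fix(es) removed")
  }
  track$fixes <- track$fixes[keep, , drop = FALSE]
  rownames(track$fixes) <- NULL
  track
}

#' Final-exit segmentation at an analysis radius
#'
#' Truncates a (previously escape-stripped and speed-filtered) track at its
#' last departure from the circle of the given radius around the release
#' point. The segment runs from the track's first fix to the exit fix — the
#' first fix beyond the radius following the last fix inside it — so loops
#' back into the circle are included.
#'
#' @param track A `pigeon_track` after [strip_escape_radius()] and
#'   [filter_speed()].
#' @param release_point List with `lat`, `lon`.
#' @param radius Analysis radius in meters.
#' @param release_time Timestamp of the bird's first *raw* fix (used later
#'   as the vanishing-time origin); defaults to the first fix in `track`.
#' @return A `track_segment`; flagged `never_exited` when the track never
#'   leaves the radius after its last interior fix, `too_few_fixes` when
#'   the segment would have fewer than 3 fixes.
#' @export
final_exit_segment <- function(track, release_point, radius,
                               release_time = NULL) {
  if (is.null(release_time)) release_time <- track$fixes$t[1]
  n <- nrow(track$fixes)
  if (n < 3) {
    return(track_segment(track$bird_id, radius, track$fixes, release_point,
                         release_time = release_time,
                         excluded = "too_few_fixes"))
  }
  d <- dist_to_point(track$fixes, release_point)
  inside <- which(d <= radius)
  if (length(inside) == 0) {
    return(track_segment(track$bird_id, radius, track$fixes, release_point,
                         release_time = release_time,
                         excluded = "too_few_fixes"))
  }
  last_inside <- inside[length(inside)]
  if (last_inside == n) {  # logger died (or track ends) inside the radius
    return(track_segment(track$bird_id, radius, track$fixes, release_point,
                         release_time = release_time,
                         excluded = "never_exited"))
  }
  seg <- track$fixes[seq_len(last_inside + 1L), , drop = FALSE]
  rownames(seg) <- NULL
  if (nrow(seg) < 3) {
    return(track_segment(track$bird_id, radius, seg, release_point,
                         release_time = release_time,
                         excluded = "too_few_fixes"))
  }
  track_segment(track$bird_id, radius, seg, release_point,
                exit_index = last_inside + 1L, release_time = release_time)
}

#' Detect dyadic following between tracks
#'
#' Algorithmic surrogate for visual following inspection: two birds are
#' flagged when their nearest-in-time fix pairs (within `slack_s` seconds)
#' stay within `d_max` meters for a contiguous run of at least `t_min`
#' seconds. When `windows` is given, comparison is restricted to each
#' bird's analysis-segment time window.
#'
#' @param tracks A `pigeon_trackset` (or list of `pigeon_track`).
#' @param d_max Maximum separation in meters (default 100).
#' @param t_min Minimum contiguous co-flight duration in seconds
#'   (default 120).
#' @param slack_s Nearest-timestamp pairing slack in seconds (default 2).
#' @param windows Optional named list (by bird) of `c(start, end)` times.
#' @return `data.frame` with one row per following event: `bird_a`,
#'   `bird_b`, `overlap_start`, `overlap_end`, `median_separation_m`.
#' @export
detect_following <- function(tracks, d_max = 100, t_min = 120, slack_s = 2,
                             windows = NULL) {
  tracks <- unname(as.list(tracks))
  empty <- data.frame(bird_a = character(), bird_b = character(),
                      overlap_start = as.POSIXct(character(), tz = "UTC"),
                      overlap_end = as.POSIXct(character(), tz = "UTC"),
                      median_separation_m = numeric())
  if (length(tracks) < 2) return(empty)
  win_of <- function(tr) {
    if (!is.null(windows) && tr$bird_id %in% names(windows)) {
      as.numeric(windows[[tr$bird_id]])
    } else {
      range(as.numeric(tr$fixes$t))
    }
  }
  events <- list()
  for (i in seq_len(length(tracks) - 1)) {
    for (j in seq(i + 1, length(tracks))) {
      a <- tracks[[i]]; b <- tracks[[j]]
      if (identical(a$bird_id, b$bird_id)) next
      wa <- win_of(a); wb <- win_of(b)
      lo <- max(wa[1], wb[1]); hi <- min(wa[2], wb[2])
      if (hi - lo < t_min) next
      ta <- as.numeric(a$fixes$t); tb <- as.numeric(b$fixes$t)
      sel <- which(ta >= lo & ta <= hi)
      if (length(sel) < 2) next
      # nearest fix of b for each selected fix of a
      idx <- findInterval(ta[sel], tb, all.inside = TRUE)
      idx2 <- pmin(idx + 1L, length(tb))
      use_next <- abs(tb[idx2] - ta[sel]) < abs(tb[idx] - ta[sel])
      nearest <- ifelse(use_next, idx2, idx)
      dt_ok <- abs(tb[nearest] - ta[sel]) <= slack_s
      sep <- geo_distance(a$fixes$lat[sel], a$fixes$lon[sel],
                          b$fixes$lat[nearest], b$fixes$lon[nearest])
      close <- dt_ok & sep <= d_max
      if (!any(close)) next
      # longest contiguous close run (fix gaps <= slack allowed)
      runs <- rle(close)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      best <- 0; bi <- NA
      for (k in which(runs$values)) {
        dur <- ta[sel[ends[k]]] - ta[sel[starts[k]]]
        if (dur > best) { best <- dur; bi <- k }
      }
      if (!is.na(bi) && best >= t_min) {
        rng <- sel[starts[bi]:ends[bi]]
        events[[length(events) + 1]] <- data.frame(
          bird_a = a$bird_id, bird_b = b$bird_id,
          overlap_start = a$fixes$t[rng[1]],
          overlap_end = a$fixes$t[rng[length(rng)]],
          median_separation_m =
            stats::median(sep[starts[bi]:ends[bi]])
        )
      }
    }
  }
  if (length(events) == 0) return(empty)
  do.call(rbind, events)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

#' Apply the following exclusion rule
#'
#' Birds flying together in the same treatment group: one of the pair,
#' chosen by a seeded uniform draw, is excluded. Birds in different
#' treatment groups: both are excluded (behaviour cannot be attributed to
#' either treatment). Exclusion is idempotent across events.
#'
#' @param events Event table from [detect_following()].
#' @param tracks The `pigeon_trackset` the events refer to.
#' @param seed Integer seed for the same-group random draw.
#' @return Character vector of excluded bird ids (possibly empty).
#' @export
apply_following_exclusions <- function(events, tracks, seed = 1L) {
  manifest <- trackset_manifest(tracks)
  if (is.null(manifest) || nrow(events) == 0) return(character())
  grp <- stats::setNames(manifest$group, manifest$bird_id)
  excluded <- character()
  with_preserved_rng({
    set.seed(seed)
    ord <- order(events$bird_a, events$bird_b)
    for (k in ord) {
      a <- events$bird_a[k]; b <- events$bird_b[k]
      if (!all(c(a, b) %in% names(grp))) {
        stop("following event references unknown bird(s): ", a, ", ", b)
      }
      if (grp[[a]] == grp[[b]]) {
        pick <- if (stats::runif(1) < 0.5) a else b
        excluded <- union(excluded, pick)
      } else {
        excluded <- union(excluded, c(a, b))
      }
    }
  })
  sort(excluded)
}

#' Preprocess a trackset into analysis segments
#'
#' Runs the full filtering cascade in the study's order — escape-radius
#' strip, stop (speed) filter, final-exit segmentation at each analysis
#' radius — then detects following dyads within the smallest-radius segment
#' windows and applies the group-dependent exclusion rule.
#'
#' @param tracks A `pigeon_trackset`.
#' @param sites Named list of [release_site()] records keyed by site id.
#' @param config Configuration from [homing_config()].
#' @return List with `segments` (list per radius, named by meters, each a
#'   named list of `track_segment`), `exclusions` (`data.frame` of
#'   `bird_id`, `radius_m`, `reason`) and `following_events`.
#' @export
preprocess_tracks <- function(tracks, sites, config = homing_config()) {
  radii <- sort(config$analysis_radii_m)
  rp_of <- function(tr) {
    s <- sites[[tr$release_site]]
    if (is.null(s)) stop("no site record for site ", tr$release_site)
    list(lat = s$lat, lon = s$lon)
  }
  release_times <- lapply(tracks, function(tr) tr$fixes$t[1])

  cleaned <- list()
  excl <- list()
  for (tr in tracks) {
    rp <- rp_of(tr)
    st <- strip_escape_radius(tr, rp, config$escape_radius_m)
    if (inherits(st, "track_segment")) {
      excl[[length(excl) + 1]] <- data.frame(
        bird_id = tr$bird_id, radius_m = NA_real_, reason = st$excluded)
      next
    }
    st <- filter_speed(st, config$min_speed_kmh)
    cleaned[[tr$bird_id]] <- list(track = st, release_point = rp)
  }

  segments <- stats::setNames(
    lapply(radii, function(r) {
      segs <- lapply(cleaned, function(cl) {
        final_exit_segment(cl$track, cl$release_point, r,
                           release_time =
                             release_times[[cl$track$bird_id]])
      })
      stats::setNames(segs, names(cleaned))
    }),
    as.character(radii))

  # following inspection on the smallest-radius segment windows
  win <- lapply(segments[[1]], function(s) {
    if (is_excluded(s)) NULL else range(s$fixes$t)
  })
  win <- Filter(Negate(is.null), win)
  events <- detect_following(tracks[names(tracks) %in% names(cleaned)],
                             d_max = config$following$d_max_m,
                             t_min = config$following$t_min_s,
                             slack_s = config$following$slack_s,
                             windows = win)
  followers <- apply_following_exclusions(events, tracks,
                                          seed = config$seed)

  for (r in names(segments)) {
    for (b in names(segments[[r]])) {
      s <- segments[[r]][[b]]
      if (b %in% followers && !is_excluded(s)) {
        s$excluded <- "following"
        segments[[r]][[b]] <- s
      }
      if (is_excluded(s)) {
        excl[[length(excl) + 1]] <- data.frame(
          bird_id = b, radius_m = as.numeric(r), reason = s$excluded)
      }
    }
  }
  exclusions <- if (length(excl)) {
    do.call(rbind, excl)
  } else {
    data.frame(bird_id = character(), radius_m = numeric(),
               reason = character())
  }
  list(segments = segments, exclusions = exclusions,
       following_events = events,
       params = list(escape_radius_m = config$escape_radius_m,
                     min_speed_kmh = config$min_speed_kmh,
                     following = config$following, seed = config$seed))
}
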