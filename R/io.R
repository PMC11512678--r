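# Track containers and file ingest. A track is one bird's time-ordered fix
# stream plus its design labels; a trackset is the study-level collection.

#' Construct a pigeon track
#'
#' @param bird_id Identifier, coerced to character.
#' @param fixes `data.frame` with columns `lat`, `lon` (decimal degrees),
#'   `t` (`POSIXct`, UTC) and `speed` (km/h, logger-reported).
#' @param release_site,exposure_site Site identifiers (character).
#' @param group `"experimental"` or `"control"`. If `NULL`, derived from the
#'   design rule: experimental iff `exposure_site == release_site`.
#' @return Object of class `pigeon_track`.
#' @export
pigeon_track <- function(bird_id, fixes, release_site, exposure_site,
                         group = NULL) {
  stopifnot(is.data.frame(fixes),
            all(c("lat", "lon", "t", "speed") %in% names(fixes)))
  if (nrow(fixes) < 2) stop("a track needs at least 2 fixes")
  if (is.unsorted(fixes$t, strictly = FALSE)) {
    fixes <- fixes[order(fixes$t), , drop = FALSE]
  }
  dup <- duplicated(fixes$t)
  if (any(dup)) fixes <- fixes[!dup, , drop = FALSE]  # keep first fix at a tie
  if (is.unsorted(as.numeric(fixes$t), strictly = TRUE)) {
    stop("fix timestamps must be strictly increasing")
  }
  implied <- if (identical(as.character(exposure_site),
                           as.character(release_site))) {
    "experimental"
  } else {
    "control"
  }
  if (is.null(group)) {
    group <- implied
  } else {
    group <- match.arg(group, c("experimental", "control"))
    if (!identical(group, implied)) {
      warning("group label for bird ", bird_id,
              " contradicts the exposure/release design rule")
    }
  }
  rownames(fixes) <- NULL
  structure(
    list(bird_id = as.character(bird_id), fixes = fixes,
         release_site = as.character(release_site),
         exposure_site = as.character(exposure_site), group = group),
    class = "pigeon_track"
  )
}

#' @export
print.pigeon_track <- function(x, ...) {
  cat(sprintf(
    "<pigeon_track> bird %s: %d fixes, %s, released at %s (exposed at %s)\n",
    x$bird_id, nrow(x$fixes), x$group, x$release_site, x$exposure_site))
  invisible(x)
}

#' Construct a site record
#'
#' @param site_id Identifier.
#' @param lat,lon Site coordinates, decimal degrees.
#' @param home_bearing Bearing from the site to the home loft, degrees
#'   clockwise from true north, in [0, 360).
#' @param home_distance Distance from the site to the loft, km.
#' @return Object of class `release_site`.
#' @export
release_site <- function(site_id, lat, lon, home_bearing, home_distance) {
  stopifnot(home_bearing >= 0, home_bearing < 360, home_distance > 0)
  structure(list(site_id = as.character(site_id), lat = lat, lon = lon,
                 home_bearing = home_bearing, home_distance = home_distance),
            class = "release_site")
}

#' Check a site's stored bearing/distance against its coordinates
#'
#' Compares the recorded home bearing and distance with the values implied
#' by the site and loft coordinates.
#'
#' @param site A `release_site`.
#' @param loft List with `lat` and `lon` of the loft.
#' @return Named list with the absolute bearing error (degrees) and the
#'   relative distance error.
#' @export
site_consistency <- function(site, loft) {
  b <- geo_bearing(site$lat, site$lon, loft$lat, loft$lon)
  d <- geo_distance(site$lat, site$lon, loft$lat, loft$lon) / 1000
  list(bearing_error_deg = abs(wrap_angle(b - site$home_bearing)),
       distance_error_rel = abs(d - site$home_distance) / site$home_distance)
}

#' Read a bird assignment manifest
#'
#' Delimited table with columns `bird_id`, `release_site`, `exposure_site`
#' and optional `group`.
#'
#' @param path File path.
#' @return `data.frame` keyed by `bird_id`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("bird_id", "release_site", "exposure_site")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$bird_id)) stop("duplicate bird_id in manifest")
  m
}

validate_fix_rows <- function(df) {
  ok <- is.finite(df$lat) & is.finite(df$lon) & is.finite(df$speed) &
    df$lat >= -90 & df$lat <= 90 & df$lon > -180 & df$lon <= 180 &
    df$speed >= 0 & !is.na(df$t)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(n_bad, " fix row(s) rejected (invalid coordinates, speed or time)")
  }
  df[ok, , drop = FALSE]
}

track_from_rows <- function(bird, rows, manifest) {
  i <- match(bird, manifest$bird_id)
  if (is.na(i)) stop("bird ", bird, " has no manifest entry")
  grp <- if ("group" %in% names(manifest)) manifest$group[i] else NULL
  pigeon_track(bird, rows[, c("lat", "lon", "t", "speed")],
               release_site = manifest$release_site[i],
               exposure_site = manifest$exposure_site[i], group = grp)
}

#' Read GPS tracks
#'
#' Reads per-bird 1 Hz fix streams from either the CSV logger dialect
#' (`bird_id,datetime,lat,lon,speed_kmh`, ISO 8601 datetimes, UTC) or GPX
#' 1.1 (one `<trk>` per bird, `<trkpt>` with `<time>`, speed in a
#' `<speed_kmh>` extension or a GPX `<speed>` tag in m/s). Rows violating
#' coordinate/speed invariants are dropped with a logged count; duplicate
#' timestamps within a bird keep the first fix.
#'
#' @param path File path.
#' @param format `"csv"` or `"gpx"`.
#' @param manifest `data.frame` from [read_manifest()] (or equivalent)
#'   assigning every bird to release/exposure sites.
#' @return Object of class `pigeon_trackset`: a named list of
#'   [pigeon_track()] objects.
#' @export
read_tracks <- function(path, format = c("csv", "gpx"), manifest) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- switch(format, csv = read_fix_csv(path), gpx = read_fix_gpx(path))
  if (nrow(df) == 0) {
    warning("no valid fixes in ", path)
    return(structure(list(), class = "pigeon_trackset"))
  }
  df <- validate_fix_rows(df)
  tracks <- lapply(split(df, df$bird_id), function(rows) {
    track_from_rows(rows$bird_id[1], rows, manifest)
  })
  structure(tracks[order(names(tracks))], class = "pigeon_trackset")
}

read_fix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "datetime", "lat", "lon", "speed_kmh")
  if (nrow(df) == 0) {
    return(data.frame(bird_id = character(), lat = numeric(),
                      lon = numeric(),
                      t = as.POSIXct(character(), tz = "UTC"),
                      speed = numeric()))
  }
  if (!all(need %in% names(df))) {
    stop("fix CSV must have columns: ", paste(need, collapse = ", "))
  }
  t <- as.POSIXct(df$datetime, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  data.frame(bird_id = as.character(df$bird_id),
             lat = as.numeric(df$lat), lon = as.numeric(df$lon),
             t = t, speed = as.numeric(df$speed_kmh))
}

read_fix_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  out <- lapply(xml2::xml_find_all(doc, ".//trk"), function(trk) {
    bird <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    if (length(pts) == 0) return(NULL)
    spd <- vapply(pts, function(p) {
      v <- xml2::xml_find_first(p, ".//speed_kmh")
      if (!inherits(v, "xml_missing")) {
        return(as.numeric(xml2::xml_text(v)))
      }
      v <- xml2::xml_find_first(p, ".//speed")  # GPX convention: m/s
      if (!inherits(v, "xml_missing")) {
        return(as.numeric(xml2::xml_text(v)) * 3.6)
      }
      NA_real_
    }, numeric(1))
    data.frame(
      bird_id = bird,
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      t = as.POSIXct(vapply(pts, function(p)
        xml2::xml_text(xml2::xml_find_first(p, "./time")), character(1)),
        tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%OS")),
      speed = spd
    )
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Write tracks to the CSV logger dialect
#'
#' Inverse of [read_tracks()] for `format = "csv"`; coordinates are written
#' with enough digits to round-trip to 1e-6 degrees.
#'
#' @param tracks A `pigeon_trackset` or list of `pigeon_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(bird_id = tr$bird_id,
               datetime = format(tr$fixes$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               lat = sprintf("%.7f", tr$fixes$lat),
               lon = sprintf("%.7f", tr$fixes$lon),
               speed_kmh = sprintf("%.3f", tr$fixes$speed))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the manifest of a trackset
#'
#' @param tracks A `pigeon_trackset`.
#' @return `data.frame` with one row per bird.
#' @export
trackset_manifest <- function(tracks) {
  tr <- unname(as.list(tracks))
  if (length(tr) == 0) return(NULL)
  data.frame(
    bird_id = vapply(tr, `[[`, character(1), "bird_id"),
    release_site = vapply(tr, `[[`, character(1), "release_site"),
    exposure_site = vapply(tr, `[[`, character(1), "exposure_site"),
    group = vapply(tr, `[[`, character(1), "group"))
}

#' @export
print.pigeon_trackset <- function(x, ...) {
  cat(sprintf("<pigeon_trackset> %d birds, %d fixes total\n", length(x),
              sum(vapply(x, function(t) nrow(t$fixes), numeric(1)))))
  invisible(x)
}
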