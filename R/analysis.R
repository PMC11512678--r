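# Study-level orchestration: one call runs preprocessing, the four
# metrics, the directional comparisons, the eight linear models and the
# power grid, returning a single classed result object.

#' Run the full track analysis
#'
#' Applies the preprocessing cascade at every analysis radius, computes
#' the per-bird metric table, compares directional distributions between
#' treatment groups and between release sites with two-sample Hotelling's
#' T-squared tests, fits the additive `metric ~ group + release_site`
#' Type II models for all four metrics at every radius, and evaluates the
#' analytic power grid (the conventional effect-size rows plus the
#' observed mean release-site partial eta-squared, at the smallest and
#' largest model sample sizes).
#'
#' @param tracks A `pigeon_trackset` (from [read_tracks()] or
#'   [simulate_study()]).
#' @param sites Named list of [release_site()] records.
#' @param loft Home loft coordinates (list with `lat`, `lon`).
#' @param config Analysis configuration from [homing_config()].
#' @return Object of class `homing_analysis` with elements `prep`,
#'   `metrics`, `vectors` (per-radius bird points and second-order
#'   summaries), `hotelling` (per-radius group and site tests), `models`
#'   (per metric x radius fits with effect reports and diagnostics),
#'   `power` (grid `data.frame`), `counts`, `config`.
#' @export
homing_analysis <- function(tracks, sites = default_sites(),
                            loft = default_loft(),
                            config = homing_config()) {
  prep <- preprocess_tracks(tracks, sites, config)
  metrics <- compute_metrics(prep, tracks, loft)
  radii <- sort(unique(metrics$radius_m))

  vectors <- list()
  hotelling <- list()
  for (r in radii) {
    pts <- bird_vector_points(metrics, r)
    cells <- split(pts, list(pts$group, pts$release_site), drop = TRUE)
    vectors[[as.character(r)]] <- list(
      points = pts,
      second_order = lapply(cells, second_order_mean_vector))
    hotelling[[as.character(r)]] <- list(
      group = hotelling_two_sample(pts[pts$group == "experimental", ],
                                   pts[pts$group == "control", ]),
      release_site = hotelling_two_sample(
        pts[pts$release_site == sort(unique(pts$release_site))[1], ],
        pts[pts$release_site == sort(unique(pts$release_site))[2], ]))
  }

  models <- fit_all_models(metrics, radii)
  site_etas <- vapply(models, function(m) m$release_site$partial_eta_sq,
                      numeric(1))
  ns <- vapply(models, function(m) m$model$n, numeric(1))
  eta_rows <- c(mean(site_etas), 0.14, 0.06, 0.01)
  power <- power_table(eta_rows, sort(unique(range(ns))),
                       alpha = config$alpha)

  counts <- data.frame(
    radius_m = radii,
    n_in = length(tracks),
    n_analysed = vapply(radii, function(r)
      sum(metrics$radius_m == r), numeric(1)),
    n_excluded = vapply(radii, function(r)
      sum(prep$exclusions$radius_m == r, na.rm = TRUE) +
        sum(is.na(prep$exclusions$radius_m)), numeric(1)))

  structure(list(prep = prep, metrics = metrics, vectors = vectors,
                 hotelling = hotelling, models = models, power = power,
                 counts = counts, config = config,
                 mean_site_eta_sq = mean(site_etas)),
            class = "homing_analysis")
}

#' @export
print.homing_analysis <- function(x, ...) {
  cat("Homing-pigeon release analysis\n")
  cat(sprintf("  birds in: %d\n", x$counts$n_in[1]))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  radius %g m: %d analysed (%d exclusions)\n",
                x$counts$radius_m[i], x$counts$n_analysed[i],
                x$counts$n_excluded[i]))
  }
  for (r in names(x$hotelling)) {
    h <- x$hotelling[[r]]
    cat(sprintf(
      "  %s m directional tests: group T2 = %.3g (p = %.3g), site T2 = %.3g (p = %.3g)\n",
      r, h$group$statistic, h$group$p_value,
      h$release_site$statistic, h$release_site$p_value))
  }
  cat(sprintf("  mean release-site eta2p across models: %.3g\n",
              x$mean_site_eta_sq))
  invisible(x)
}

#' @export
summary.homing_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-term effect reports:\n")
  for (m in object$models) {
    print(m$group)
    print(m$release_site)
  }
  cat("\nPower grid (percent):\n")
  print(object$power, row.names = FALSE)
  invisible(object)
}

#' Flatten the model reports of an analysis
#'
#' @param x A `homing_analysis`.
#' @return `data.frame` with one row per model x term carrying N, F, df,
#'   p, partial eta-squared, fitted mean difference and Cohen's d with
#'   confidence intervals, and the Shapiro-Wilk diagnostic.
#' @export
model_report_table <- function(x) {
  rows <- lapply(x$models, function(m) {
    do.call(rbind, lapply(list(m$group, m$release_site), function(e) {
      data.frame(metric = e$metric, radius_m = e$radius_m, term = e$term,
                 n = e$n, F = e$F, df_num = e$df_num, df_den = e$df_den,
                 p = e$p, partial_eta_sq = e$partial_eta_sq,
                 mean_difference = e$mean_difference,
                 mean_difference_lo = e$mean_difference_ci[1],
                 mean_difference_hi = e$mean_difference_ci[2],
                 cohens_d = e$cohens_d,
                 cohens_d_lo = e$cohens_d_ci[1],
                 cohens_d_hi = e$cohens_d_ci[2],
                 shapiro_W = m$diagnostics$shapiro_W,
                 shapiro_p = m$diagnostics$shapiro_p)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- homing_config(
    escape_radius_m = y$escape_radius_m %||% 500,
    analysis_radii_m = unlist(y$analysis_radii_m %||% c(2000, 5000)),
    min_speed_kmh = y$min_speed_kmh %||% 5,
    following = list(d_max_m = y$following$d_max_m %||% 100,
                     t_min_s = y$following$t_min_s %||% 120,
                     slack_s = y$following$slack_s %||% 2),
    alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1L)
  sim <- do.call(sim_config, c(list(seed = cfg$seed), y$sim %||% list()))
  list(config = cfg, sim = sim, simulate = isTRUE(y$simulate),
       tracks = y$tracks, format = y$format %||% "csv",
       manifest = y$manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a reproducible end-to-end analysis into an output directory
#'
#' Ingests (or simulates) a study, runs [homing_analysis()], and writes
#' the metric table, the Hotelling comparisons (JSON), the per-model
#' effect reports, the exclusion log, the power grid, circular and box
#' figures, and a run manifest capturing the configuration, seed, input
#' checksums and per-stage record counts.
#'
#' @param out_dir Output directory (created if needed).
#' @param config_file Optional YAML configuration file; keys
#'   `escape_radius_m`, `analysis_radii_m`, `min_speed_kmh`,
#'   `following:{d_max_m,t_min_s,slack_s}`, `seed`, `simulate`, `sim`
#'   (simulator overrides), or `tracks`/`format`/`manifest` for real data.
#' @param tracks Optional `pigeon_trackset` (overrides file input).
#' @param simulate Simulate a synthetic study when no tracks are given.
#' @param sim Simulator configuration for `simulate = TRUE`.
#' @param sites,loft Study geometry.
#' @param config Analysis configuration.
#' @param figures Write PNG figures (default TRUE).
#' @return The `homing_analysis` object, invisibly; side effect: files
#'   under `out_dir`.
#' @export
run_full_analysis <- function(out_dir, config_file = NULL, tracks = NULL,
                              simulate = is.null(tracks),
                              sim = sim_config(),
                              sites = default_sites(),
                              loft = default_loft(),
                              config = homing_config(),
                              figures = TRUE) {
  checksums <- NULL
  if (!is.null(config_file)) {
    rc <- read_run_config(config_file)
    config <- rc$config
    sim <- rc$sim
    simulate <- rc$simulate || is.null(rc$tracks)
    if (!is.null(rc$tracks)) {
      manifest <- read_manifest(rc$manifest)
      tracks <- read_tracks(rc$tracks, rc$format, manifest)
      simulate <- FALSE
      checksums <- tools::md5sum(c(rc$tracks, rc$manifest))
    }
  }
  if (is.null(tracks)) {
    if (!simulate) stop("no tracks given and simulate = FALSE")
    sim$seed <- sim$seed %||% config$seed
    study <- simulate_study(sim)
    tracks <- study$tracks
  }
  res <- homing_analysis(tracks, sites, loft, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(res$prep$exclusions,
                   file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  utils::write.csv(model_report_table(res),
                   file.path(out_dir, "model_reports.csv"),
                   row.names = FALSE)
  utils::write.csv(res$power, file.path(out_dir, "power.csv"),
                   row.names = FALSE)
  hot <- lapply(res$hotelling, function(h) {
    lapply(h, function(t) list(comparison = NULL, n = t$n_total,
                               T2 = t$statistic, F = t$F, df = t$df,
                               p = t$p_value))
  })
  jsonlite::write_json(hot, file.path(out_dir, "hotelling.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("homingnav")),
    seed = config$seed,
    config = unclass(config),
    simulated = simulate,
    input_checksums = as.list(checksums),
    counts = res$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (figures) {
    grDevices::png(file.path(out_dir, "mean_vectors.png"), width = 1200,
                   height = 600, res = 120)
    op <- graphics::par(mfrow = c(1, length(res$vectors)))
    for (r in names(res$vectors)) {
      plot_mean_vectors(res$vectors[[r]]$points,
                        main = paste0(r, " m radius"))
    }
    graphics::par(op)
    grDevices::dev.off()
    for (m in METRIC_COLUMNS) {
      grDevices::png(file.path(out_dir, paste0("box_", m, ".png")),
                     width = 1000, height = 600, res = 120)
      plot_metric_boxes(res$metrics, m)
      grDevices::dev.off()
    }
  }
  invisible(res)
}
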