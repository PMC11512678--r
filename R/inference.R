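# Per-metric linear models: Metric ~ Treatment group + Release site,
# assessed with Type II sums of squares, partial eta-squared, fitted mean
# differences, Cohen's d with noncentral-t confidence intervals, and
# residual normality diagnostics.

METRIC_COLUMNS <- c("vanishing_time_s", "mean_vector_length",
                    "efficiency_index", "homing_efficiency_index")

#' Fit the additive treatment + site model for one metric
#'
#' Ordinary least squares of `metric ~ group + release_site` (no
#' interaction) on the per-bird metric table at one analysis radius, with
#' Type II sums of squares for each term. Virtual vanishing time is
#' natural-log transformed before fitting (the only transformed metric);
#' its reported differences stay on the log scale.
#'
#' Factor coding fixes the sign convention: positive differences mean
#' greater metric values in the experimental group than the control group,
#' and in the second site than the first (site levels sorted).
#'
#' @param metrics Metric table from [compute_metrics()].
#' @param metric One of `"vanishing_time_s"`, `"mean_vector_length"`,
#'   `"efficiency_index"`, `"homing_efficiency_index"`.
#' @param radius_m Analysis radius to select, meters.
#' @param transform `"auto"` (natural log for vanishing time, identity
#'   otherwise), `"identity"` or `"log"`.
#' @return Object of class `metric_model`: the `lm` fit, the Type II
#'   ANOVA table, and metadata.
#' @export
fit_metric_model <- function(metrics, metric, radius_m,
                             transform = c("auto", "identity", "log")) {
  metric <- match.arg(metric, METRIC_COLUMNS)
  transform <- match.arg(transform)
  if (transform == "auto") {
    transform <- if (metric == "vanishing_time_s") "log" else "identity"
  }
  dat <- metrics[metrics$radius_m == radius_m, , drop = FALSE]
  if (nrow(dat) == 0) stop("no metric rows at radius ", radius_m)
  if (anyNA(dat[[metric]])) stop("missing values in ", metric)
  y <- dat[[metric]]
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform needs positive values")
    y <- log(y)
  }
  grp <- factor(dat$group, levels = c("control", "experimental"))
  site <- factor(dat$release_site, levels = sort(unique(dat$release_site)))
  if (nlevels(droplevels(grp)) < 2) stop("a treatment group level is absent")
  if (nlevels(droplevels(site)) < 2) stop("a release-site level is absent")
  df <- data.frame(y = y, group = grp, release_site = site)
  fit <- stats::lm(y ~ group + release_site, data = df)
  ss_res <- sum(stats::residuals(fit)^2)
  if (ss_res < 1e-12 && stats::var(y) < 1e-12) {
    # constant response: define both term F statistics as 0
    an <- data.frame(`Sum Sq` = c(0, 0, 0), Df = c(1, 1, fit$df.residual),
                     `F value` = c(0, 0, NA), `Pr(>F)` = c(1, 1, NA),
                     check.names = FALSE,
                     row.names = c("group", "release_site", "Residuals"))
  } else {
    an <- as.data.frame(car::Anova(fit, type = 2))
  }
  structure(list(fit = fit, anova = an, metric = metric,
                 radius_m = radius_m, transform = transform, data = df,
                 n = nrow(df)),
            class = "metric_model")
}

#' @export
print.metric_model <- function(x, ...) {
  cat(sprintf("<metric_model> %s at %g m (%s), N = %d\n", x$metric,
              x$radius_m,
              if (x$transform == "log") "log scale" else "raw scale", x$n))
  print(x$anova)
  invisible(x)
}

# Noncentrality interval of a t statistic: ncp values whose noncentral-t
# distributions put the observed t at the 97.5th / 2.5th percentile.
ncp_interval <- function(t_obs, df, level = 0.95) {
  a <- (1 - level) / 2
  bound <- abs(t_obs) + 15 + 6 * sqrt(df)
  solve_ncp <- function(prob) {
    # pt() with ncp warns about its ~1e-12 precision floor; irrelevant here
    f <- function(ncp) {
      suppressWarnings(stats::pt(t_obs, df, ncp = ncp)) - prob
    }
    if (f(-bound) * f(bound) > 0) return(sign(t_obs) * bound)
    stats::uniroot(f, c(-bound, bound), tol = 1e-9)$root
  }
  c(lower = solve_ncp(1 - a), upper = solve_ncp(a))
}

#' Effect-size report for one model term
#'
#' Gives, for the `group` or `release_site` term of a fitted
#' [fit_metric_model()] object: the Type II F statistic and degrees of
#' freedom, partial eta-squared SS_term / (SS_term + SS_resid), the fitted
#' mean difference (the term's indicator coefficient, positive =
#' experimental > control or site 2 > site 1) with its t-based 95%
#' confidence interval, and Cohen's d = t * sqrt(1/n1 + 1/n2) with a
#' noncentral-t confidence interval.
#'
#' @param model A `metric_model`.
#' @param term `"group"` or `"release_site"`.
#' @param level Confidence level (default 0.95).
#' @return List of class `effect_report`.
#' @export
effect_sizes <- function(model, term = c("group", "release_site"),
                         level = 0.95) {
  term <- match.arg(term)
  an <- model$anova
  if (!term %in% rownames(an)) stop("term not in model: ", term)
  ss_term <- an[term, "Sum Sq"]
  ss_res <- an["Residuals", "Sum Sq"]
  df_den <- an["Residuals", "Df"]
  fstat <- an[term, "F value"]
  p <- an[term, "Pr(>F)"]
  eta <- if (ss_term + ss_res > 0) ss_term / (ss_term + ss_res) else 0
  cf <- stats::coef(model$fit)
  cname <- grep(paste0("^", term), names(cf), value = TRUE)[1]
  est <- unname(cf[cname])
  se <- sqrt(diag(stats::vcov(model$fit)))[cname]
  counts <- table(model$data[[term]])
  inv_n <- sum(1 / counts[1:2])
  if (se < 1e-14) {
    tstat <- 0; ci <- c(0, 0); d <- 0; d_ci <- c(0, 0)
  } else {
    tstat <- est / se
    ci <- est + stats::qt(c((1 - level) / 2, 1 - (1 - level) / 2),
                          df_den) * se
    d <- tstat * sqrt(inv_n)
    d_ci <- unname(ncp_interval(tstat, df_den, level) * sqrt(inv_n))
  }
  structure(list(metric = model$metric, radius_m = model$radius_m,
                 term = term, n = model$n, F = unname(fstat),
                 df_num = an[term, "Df"], df_den = df_den,
                 p = unname(p), partial_eta_sq = unname(eta),
                 mean_difference = est, mean_difference_ci = unname(ci),
                 cohens_d = unname(d), cohens_d_ci = d_ci,
                 level = level),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf(
    "%s at %g m, %s: N = %d, F(%d, %d) = %.3g, eta2p = %.3g,\n  mean diff = %.3g, CI (%.3g, %.3g), d = %.3g, CI (%.3g, %.3g), p = %.3g\n",
    x$metric, x$radius_m, x$term, x$n, x$df_num, x$df_den, x$F,
    x$partial_eta_sq, x$mean_difference, x$mean_difference_ci[1],
    x$mean_difference_ci[2], x$cohens_d, x$cohens_d_ci[1],
    x$cohens_d_ci[2], x$p))
  invisible(x)
}

#' Residual normality diagnostics
#'
#' Standardized residuals, normal Q-Q points and the Shapiro-Wilk test of
#' the model residuals.
#'
#' @param model A `metric_model`.
#' @return List of class `diagnostics_report`: `shapiro_W`, `shapiro_p`,
#'   `qq_points` (`data.frame` of ordered theoretical and sample
#'   quantiles).
#' @export
residual_diagnostics <- function(model) {
  r <- stats::rstandard(model$fit)
  if (length(r) < 3) stop("need at least 3 residuals")
  sw <- stats::shapiro.test(stats::residuals(model$fit))
  qq <- stats::qqnorm(r, plot.it = FALSE)
  ord <- order(qq$x)
  structure(list(shapiro_W = unname(sw$statistic),
                 shapiro_p = sw$p.value,
                 qq_points = data.frame(theoretical = unname(qq$x[ord]),
                                        sample = unname(qq$y[ord]))),
            class = "diagnostics_report")
}

#' Fit all metric models of a study
#'
#' One additive model per metric per analysis radius (the study's eight
#' models at the default two radii), each with both term reports and
#' residual diagnostics.
#'
#' @param metrics Metric table from [compute_metrics()].
#' @param radii Radii to fit at; defaults to those present.
#' @return Named list (one element per metric x radius) of lists with
#'   `model`, `group` and `release_site` effect reports, `diagnostics`.
#' @export
fit_all_models <- function(metrics, radii = sort(unique(metrics$radius_m))) {
  out <- list()
  for (r in radii) {
    for (m in METRIC_COLUMNS) {
      key <- paste0(m, "_", r)
      mod <- fit_metric_model(metrics, m, r)
      out[[key]] <- list(
        model = mod,
        group = effect_sizes(mod, "group"),
        release_site = effect_sizes(mod, "release_site"),
        diagnostics = residual_diagnostics(mod))
    }
  }
  out
}
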