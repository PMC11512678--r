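# Group-level directional statistics: each bird is embedded as one
# bivariate point — the Cartesian components of its mean vector of
# home-relative step directions — and groups are summarized by second-order
# mean vectors and compared with two-sample Hotelling's T-squared tests.

#' Per-bird mean-vector points
#'
#' Embeds each bird of a metric table as the Cartesian point
#' (length * cos(direction), length * sin(direction)) of its individual
#' mean vector, preserving both concentration and direction. With
#' `unit_vectors = TRUE` each bird contributes its unit mean-direction
#' vector instead.
#'
#' @param metrics Metric table from [compute_metrics()].
#' @param radius_m Analysis radius to select, meters.
#' @param unit_vectors Use unit vectors rather than full mean vectors.
#' @return `data.frame` with `bird_id`, `group`, `release_site`, `x`, `y`.
#' @export
bird_vector_points <- function(metrics, radius_m, unit_vectors = FALSE) {
  m <- metrics[metrics$radius_m == radius_m, , drop = FALSE]
  if (nrow(m) == 0) stop("no metric rows at radius ", radius_m)
  len <- if (unit_vectors) 1 else m$mean_vector_length
  th <- m$mean_direction_deg * pi / 180
  data.frame(bird_id = m$bird_id, group = m$group,
             release_site = m$release_site,
             x = len * cos(th), y = len * sin(th))
}

#' Second-order mean vector
#'
#' Vector average of individual birds' mean vectors, summarizing a group's
#' directional distribution.
#'
#' @param points `data.frame` with columns `x`, `y` (one row per bird).
#' @return List with `length`, `direction` (degrees) and the mean
#'   components `x`, `y`.
#' @export
second_order_mean_vector <- function(points) {
  if (nrow(points) < 1) stop("no points")
  mx <- mean(points$x); my <- mean(points$y)
  list(length = sqrt(mx^2 + my^2),
       direction = wrap_angle(atan2(my, mx) * 180 / pi),
       x = mx, y = my)
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares the bivariate means of two groups of mean-vector points under
#' a pooled covariance. Reports the classical T-squared statistic and its
#' exact F transform F = (n - p - 1) / (p (n - 2)) * T2 on
#' (p, n - p - 1) degrees of freedom with p = 2.
#'
#' @param a,b Matrices or data frames with columns `x`, `y`, one row per
#'   bird, for the two groups.
#' @return List of class `hotelling_test`: `n_total`, `n_a`, `n_b`,
#'   `statistic` (T2), `F`, `df`, `p_value`, `group_means`.
#' @export
hotelling_two_sample <- function(a, b) {
  xa <- as.matrix(as.data.frame(a)[, c("x", "y")])
  xb <- as.matrix(as.data.frame(b)[, c("x", "y")])
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 3 || nb < 3) stop("each group needs at least 3 points")
  ma <- colMeans(xa); mb <- colMeans(xb)
  sp <- ((na - 1) * stats::cov(xa) + (nb - 1) * stats::cov(xb)) /
    (na + nb - 2)
  if (abs(det(sp)) < 1e-300) {
    stop("singular pooled covariance; degenerate point configuration")
  }
  d <- ma - mb
  t2 <- as.numeric((na * nb) / (na + nb) *
                     crossprod(d, solve(sp, d)))
  n <- na + nb
  fstat <- (n - 3) / (2 * (n - 2)) * t2
  p <- stats::pf(fstat, 2, n - 3, lower.tail = FALSE)
  structure(list(n_total = n, n_a = na, n_b = nb, statistic = t2,
                 F = fstat, df = c(2, n - 3), p_value = p,
                 group_means = list(a = ma, b = mb)),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf(
    "Two-sample Hotelling's T-squared\n  N = %d (%d vs %d), T2 = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
    x$n_total, x$n_a, x$n_b, x$statistic, x$df[1], x$df[2], x$F,
    x$p_value))
  invisible(x)
}

#' Von Mises random angles
#'
#' Best-Fisher envelope sampler; drawn from R's RNG stream so results are
#' reproducible under `set.seed()`. The degenerate `kappa = 0` case is
#' uniform on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  wrap_angle(rvonmises_cpp(as.integer(n), mu * pi / 180, kappa) * 180 / pi)
}
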