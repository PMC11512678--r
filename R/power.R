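# Analytic post hoc power for the treatment term of the additive
# two-predictor linear model, via the noncentral F distribution.

#' Power for a partial eta-squared effect in the additive model
#'
#' Analytic power of the single-df F test of one predictor in an OLS model
#' with one other predictor (intercept + 2 coefficients fitted, so
#' denominator df = N - 3). Uses the fixed-effects regression
#' parameterisation: Cohen's f2 = eta2p / (1 - eta2p), noncentrality
#' lambda = f2 * N, and power = P[F'(1, N - 3, lambda) > F_crit(alpha)].
#'
#' @param partial_eta_sq Assumed partial eta-squared of the tested
#'   predictor, in (0, 1).
#' @param n_total Total sample size (> 3).
#' @param alpha Test size (default 0.05).
#' @return List of class `power_result`: `power_percent`, `f_squared`,
#'   `lambda`, `df_num`, `df_den`, `alpha`, `n_total`.
#' @export
power_for_eta_sq <- function(partial_eta_sq, n_total, alpha = 0.05) {
  if (partial_eta_sq <= 0 || partial_eta_sq >= 1) {
    stop("partial_eta_sq must lie strictly in (0, 1)")
  }
  if (n_total <= 3) stop("n_total must exceed 3")
  f2 <- partial_eta_sq / (1 - partial_eta_sq)
  lambda <- f2 * n_total
  df_den <- n_total - 3
  crit <- stats::qf(1 - alpha, 1, df_den)
  pw <- stats::pf(crit, 1, df_den, ncp = lambda, lower.tail = FALSE)
  structure(list(power_percent = 100 * pw, f_squared = f2,
                 lambda = lambda, df_num = 1, df_den = df_den,
                 alpha = alpha, n_total = n_total),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "power = %.1f%% (f2 = %.4g, lambda = %.4g, F(1, %d), alpha = %g, N = %d)\n",
    x$power_percent, x$f_squared, x$lambda, x$df_den, x$alpha, x$n_total))
  invisible(x)
}

#' Power grid over effect sizes and sample sizes
#'
#' @param eta_values Partial eta-squared values (rows).
#' @param n_values Total sample sizes (columns).
#' @param alpha Test size (default 0.05).
#' @return `data.frame` in long form: `partial_eta_sq`, `n_total`,
#'   `power_percent`, `f_squared`, `lambda`.
#' @export
power_table <- function(eta_values = c(0.26, 0.14, 0.06, 0.01),
                        n_values = c(31, 34), alpha = 0.05) {
  if (length(eta_values) == 0 || length(n_values) == 0) {
    stop("empty grid")
  }
  grid <- expand.grid(partial_eta_sq = eta_values, n_total = n_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- Map(function(e, n) power_for_eta_sq(e, n, alpha),
             grid$partial_eta_sq, grid$n_total)
  grid$power_percent <- vapply(res, `[[`, numeric(1), "power_percent")
  grid$f_squared <- vapply(res, `[[`, numeric(1), "f_squared")
  grid$lambda <- vapply(res, `[[`, numeric(1), "lambda")
  grid
}
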