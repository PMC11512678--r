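# 2x2 balanced fixture: 2 birds per group x site cell
balanced_metrics <- function(y) {
  data.frame(bird_id = sprintf("b%d", 1:8),
             group = rep(c("control", "experimental"), each = 4),
             release_site = rep(c("1", "1", "2", "2"), 2),
             radius_m = 2000,
             vanishing_time_s = exp(y),
             mean_vector_length = pmin(pmax(y, 0), 1),
             efficiency_index = y,
             homing_efficiency_index = y - 0.1)
}

test_that("balanced 2x2: Type II equals Type I and matches hand-computed sums of squares", {
  y <- c(1.0, 1.2, 0.7, 0.9, 1.4, 1.6, 1.1, 1.3)
  met <- balanced_metrics(y)
  mod <- fit_metric_model(met, "efficiency_index", 2000)
  # hand-computed marginal sums of squares (balance makes terms orthogonal):
  # SS_term = sum over levels of n_level * (level mean - grand mean)^2
  ss_group <- 4 * sum((tapply(y, met$group, mean) - mean(y))^2)
  ss_site <- 4 * sum((tapply(y, met$release_site, mean) - mean(y))^2)
  expect_equal(mod$anova["group", "Sum Sq"], ss_group, tolerance = 1e-12)
  expect_equal(mod$anova["release_site", "Sum Sq"], ss_site,
               tolerance = 1e-12)
  type1 <- anova(mod$fit)
  expect_equal(mod$anova["group", "Sum Sq"], type1["group", "Sum Sq"])
  expect_equal(mod$anova["release_site", "Sum Sq"],
               type1["release_site", "Sum Sq"])
  # coefficients equal the marginal cell-mean contrasts
  es <- effect_sizes(mod, "group")
  expect_equal(es$mean_difference,
               mean(y[met$group == "experimental"]) -
                 mean(y[met$group == "control"]), tolerance = 1e-12)
  es2 <- effect_sizes(mod, "release_site")
  expect_equal(es2$mean_difference,
               mean(y[met$release_site == "2"]) -
                 mean(y[met$release_site == "1"]), tolerance = 1e-12)
})

test_that("constant response yields F = 0 for both terms", {
  met <- balanced_metrics(rep(0.5, 8))
  mod <- fit_metric_model(met, "efficiency_index", 2000)
  expect_equal(mod$anova["group", "F value"], 0)
  expect_equal(mod$anova["release_site", "F value"], 0)
  es <- effect_sizes(mod, "group")
  expect_equal(es$cohens_d, 0)
  expect_equal(es$cohens_d_ci, c(0, 0))
})

test_that("vanishing time is fitted on the natural-log scale; others raw", {
  y <- c(1.0, 1.2, 0.7, 0.9, 1.4, 1.6, 1.1, 1.3)
  met <- balanced_metrics(y)
  mod <- fit_metric_model(met, "vanishing_time_s", 2000)
  expect_identical(mod$transform, "log")
  expect_equal(unname(mod$fit$model$y), y)  # exp(y) logged back to y
  mod2 <- fit_metric_model(met, "mean_vector_length", 2000)
  expect_identical(mod2$transform, "identity")
})

test_that("partial eta squared satisfies the F/(F + df_den) identity on every fit", {
  set.seed(33)
  met <- balanced_metrics(rnorm(8, 1, 0.3))
  for (term in c("group", "release_site")) {
    es <- effect_sizes(fit_metric_model(met, "efficiency_index", 2000),
                       term)
    expect_equal(es$partial_eta_sq,
                 es$F / (es$F + es$df_den), tolerance = 1e-12)
  }
})

test_that("relabelling groups and sites flips signed effects, keeps F, eta2p, p", {
  set.seed(8)
  met <- balanced_metrics(rnorm(8, 1, 0.4))
  flip <- met
  flip$group <- ifelse(met$group == "control", "experimental", "control")
  flip$release_site <- ifelse(met$release_site == "1", "2", "1")
  a <- effect_sizes(fit_metric_model(met, "efficiency_index", 2000),
                    "group")
  b <- effect_sizes(fit_metric_model(flip, "efficiency_index", 2000),
                    "group")
  expect_equal(b$mean_difference, -a$mean_difference, tolerance = 1e-12)
  expect_equal(b$cohens_d, -a$cohens_d, tolerance = 1e-10)
  expect_equal(b$cohens_d_ci, -rev(a$cohens_d_ci), tolerance = 1e-6)
  expect_equal(b$F, a$F, tolerance = 1e-12)
  expect_equal(b$partial_eta_sq, a$partial_eta_sq, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("null group term rejects at the nominal rate with a site effect present", {
  set.seed(101)
  n_rep <- 1000
  rej <- logical(n_rep)
  grp <- rep(c("control", "experimental"), each = 16)
  site <- rep(rep(c("1", "2"), each = 8), 2)
  for (i in seq_len(n_rep)) {
    y <- 0.5 * (site == "2") + rnorm(32)
    met <- data.frame(bird_id = sprintf("b%d", 1:32), group = grp,
                      release_site = site, radius_m = 2000,
                      vanishing_time_s = 1, mean_vector_length = 0,
                      efficiency_index = y, homing_efficiency_index = 0)
    mod <- fit_metric_model(met, "efficiency_index", 2000)
    rej[i] <- mod$anova["group", "Pr(>F)"] < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Cohen's d noncentral-t interval covers a true effect of 0.8 in >= 93% of replicates", {
  set.seed(202)
  n_rep <- 500
  cover <- logical(n_rep)
  grp <- rep(c("control", "experimental"), each = 16)
  site <- rep(rep(c("1", "2"), each = 8), 2)
  for (i in seq_len(n_rep)) {
    y <- 0.8 * (grp == "experimental") + 0.4 * (site == "2") + rnorm(32)
    met <- data.frame(bird_id = sprintf("b%d", 1:32), group = grp,
                      release_site = site, radius_m = 2000,
                      vanishing_time_s = 1, mean_vector_length = 0,
                      efficiency_index = y, homing_efficiency_index = 0)
    es <- effect_sizes(fit_metric_model(met, "efficiency_index", 2000),
                       "group")
    cover[i] <- es$cohens_d_ci[1] <= 0.8 && 0.8 <= es$cohens_d_ci[2]
  }
  expect_gte(mean(cover), 0.93)
})

test_that("zero-effect fixture gives d = 0 with an interval symmetric about 0", {
  y <- c(1, 2, 1.5, 2.5, 1, 2, 1.5, 2.5)  # identical group patterns
  met <- balanced_metrics(y)
  es <- effect_sizes(fit_metric_model(met, "efficiency_index", 2000),
                     "group")
  expect_equal(es$cohens_d, 0, tolerance = 1e-12)
  expect_equal(es$cohens_d_ci[1], -es$cohens_d_ci[2], tolerance = 1e-6)
})

test_that("Shapiro p-values are uniform for normal residuals and detect heavy tails", {
  set.seed(77)
  ps <- replicate(500, {
    met <- balanced_metrics(0)
    met <- met[rep(1:8, 4), ]
    met$bird_id <- sprintf("b%d", 1:32)
    met$efficiency_index <- rnorm(32)
    residual_diagnostics(
      fit_metric_model(met, "efficiency_index", 2000))$shapiro_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  set.seed(78)
  rej_t2 <- mean(replicate(500, {
    met <- balanced_metrics(0)
    met <- met[rep(1:8, 5)[1:33], ]
    met$bird_id <- sprintf("b%d", 1:33)
    met$efficiency_index <- rt(33, df = 2)
    residual_diagnostics(
      fit_metric_model(met, "efficiency_index", 2000))$shapiro_p < 0.05
  }))
  expect_gt(rej_t2, 0.5)
})

test_that("qq points are the ordered standardized residuals against normal quantiles", {
  set.seed(5)
  met <- balanced_metrics(0)
  met <- met[rep(1:8, 3), ]
  met$bird_id <- sprintf("b%d", 1:24)
  # residuals built from exact normal scores, alternately projected onto
  # the design's orthogonal complement so the fit leaves them untouched
  scores <- qnorm(ppoints(24))
  e <- scores[sample(24)]
  for (k in 1:100) {
    e <- resid(lm(e ~ group + release_site, data = met))
    e <- scores[rank(e)]
  }
  met$efficiency_index <- resid(lm(e ~ group + release_site, data = met))
  mod <- fit_metric_model(met, "efficiency_index", 2000)
  dg <- residual_diagnostics(mod)
  expect_equal(dg$qq_points$sample, unname(sort(rstandard(mod$fit))))
  expect_equal(dg$qq_points$theoretical, scores, tolerance = 1e-12)
  # standardized normal scores sit close to the identity line
  expect_lt(max(abs(dg$qq_points$sample - dg$qq_points$theoretical)), 0.1)
  expect_gt(cor(dg$qq_points$sample, dg$qq_points$theoretical), 0.999)
  expect_gt(dg$shapiro_W, 0.99)
})
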