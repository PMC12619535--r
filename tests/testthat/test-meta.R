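test_that("md_effect follows the two-group summary formula", {
  arm <- function(n, mean, sd) list(study_id = "s", n = n, mean_mcid = mean,
                                    sd_mcid = sd)
  same <- md_effect(arm(30, 7, 1.1), arm(30, 7, 1.1))
  expect_identical(same$md, 0)
  # unified outcomes of the first demonstration study at table precision
  e1 <- md_effect(arm(22, 8.9, 1.2), arm(21, 8.8, 1.3))
  expect_equal(e1$md, 0.1)
  expect_equal(e1$variance, 1.2^2 / 22 + 1.3^2 / 21)
  expect_identical(e1$se, sqrt(e1$variance))
  e6 <- md_effect(arm(45, 5.8, 1.0), arm(46, 5.0, 1.2))
  expect_equal(e6$md, 0.8)
  expect_error(md_effect(arm(30, 7, 0), arm(30, 7, 0)), "degenerate")
  other <- list(study_id = "t", n = 30, mean_mcid = 7, sd_mcid = 1)
  expect_error(md_effect(arm(30, 7, 1), other), "different studies")
})

test_that("REML matches brute-force grid search and metafor", {
  t2 <- reml_tau2(c(0, 1), c(0.1, 0.1))
  expect_lt(abs(as.numeric(t2) - grid_reml_oracle(c(0, 1), c(0.1, 0.1))),
            1e-5)
  # zero dispersion forces tau2 = 0
  expect_identical(as.numeric(reml_tau2(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))), 0)
  set.seed(202)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    vi <- runif(k, 0.02, 0.3)
    yi <- rnorm(k, 0.4, sqrt(runif(1, 0, 0.3) + vi))
    ours <- as.numeric(reml_tau2(yi, vi))
    expect_lt(abs(ours - grid_reml_oracle(yi, vi)), 1e-5)
    mf <- suppressWarnings(metafor::rma(yi, vi, method = "REML"))
    expect_lt(abs(ours - as.numeric(mf$tau2)), 1e-4)
  }
  expect_error(reml_tau2(1, 0.1), "at least two")
})

test_that("REML recovers the true between-study variance in simulation", {
  set.seed(31)
  k <- 100
  reps <- 200
  est <- replicate(reps, {
    vi <- rep(0.01, k)
    yi <- rnorm(k, 0, sqrt(0.09 + vi))
    as.numeric(reml_tau2(yi, vi))
  })
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.09), 3 * mc_se)
})

test_that("pooling reduces correctly in the classic special cases", {
  effects <- data.frame(study_id = c("a", "b", "c"),
                        md = c(0.2, 0.5, 0.8),
                        variance = c(0.04, 0.04, 0.04))
  # equal variances: pooled mean is the arithmetic mean
  p <- pool_random_effects(effects, tau2 = 0)
  expect_equal(p$mu, mean(effects$md))
  expect_equal(sum(p$weights), 1, tolerance = 1e-12)
  # tau2 = 0 equals the fixed-effect pool
  fe_w <- 1 / effects$variance
  expect_equal(p$mu, sum(fe_w * effects$md) / sum(fe_w))
  expect_equal(p$se_mu, sqrt(1 / sum(fe_w)))
  # single study: its own effect and SE
  one <- pool_random_effects(effects[1, ], tau2 = 0)
  expect_equal(one$mu, 0.2)
  expect_equal(one$ci_low, 0.2 - qnorm(0.975) * 0.2)
  # huge tau2: weights become equal, mu the unweighted mean
  uneq <- data.frame(md = c(0, 1, 5), variance = c(0.01, 0.5, 2))
  p_inf <- pool_random_effects(uneq, tau2 = 1e6)
  expect_equal(as.numeric(p_inf$weights), rep(1 / 3, 3), tolerance = 1e-5)
  expect_equal(p_inf$mu, 2, tolerance = 1e-4)
})

test_that("heterogeneity statistics and banding follow the Q/I2 rules", {
  h <- heterogeneity_stats(data.frame(md = c(0, 2), variance = c(0.1, 0.1)))
  expect_equal(h$q, 20)
  expect_identical(h$df, 1L)
  expect_equal(h$i2, 95)
  expect_identical(h$band, "high")
  same <- heterogeneity_stats(data.frame(md = c(1, 1, 1),
                                         variance = c(0.1, 0.2, 0.1)))
  expect_equal(same$q, 0)
  expect_equal(same$i2, 0)
  expect_identical(same$band, "low")
  # Q below df clamps I2 at zero
  low <- heterogeneity_stats(data.frame(md = c(0.5, 0.52, 0.48),
                                        variance = c(1, 1, 1)))
  expect_lt(low$q, low$df)
  expect_identical(low$i2, 0)
  expect_error(heterogeneity_stats(data.frame(md = 1, variance = 0.1)),
               "at least two")
})

test_that("I2 band boundaries are moderate", {
  band_of <- function(i2) if (i2 < 25) "low" else if (i2 > 75) "high"
                          else "moderate"
  # construct Q giving I2 exactly 25 and 75: I2 = (1 - df/Q)*100
  for (target in c(25, 75)) {
    df <- 3L
    q <- df / (1 - target / 100)
    i2 <- max(0, (q - df) / q) * 100
    expect_equal(i2, target)
    expect_identical(band_of(i2), "moderate")
  }
  fit <- mcid_meta(c(0, 2), c(0.1, 0.1))
  expect_identical(fit$band, "high")
})

test_that("mcid_meta agrees with metafor on the demonstration studies", {
  res <- mcid_pipeline(demo_hip_studies())
  fit <- res$fit
  mf <- metafor::rma(yi = res$effects$md, vi = res$effects$variance,
                     method = "REML")
  expect_equal(fit$mu, as.numeric(mf$beta), tolerance = 1e-6)
  expect_equal(fit$se_mu, mf$se, tolerance = 1e-6)
  expect_equal(fit$tau2, mf$tau2, tolerance = 1e-6)
  expect_equal(fit$q, mf$QE, tolerance = 1e-6)
  expect_equal(fit$i2, as.numeric(mf$I2), tolerance = 1e-4)
  # pooled estimate lies inside the span of the study effects
  expect_gte(fit$mu, min(fit$yi))
  expect_lte(fit$mu, max(fit$yi))
})

test_that("the mcid_meta object supports the standard model methods", {
  fit <- mcid_meta(c(0.1, 0.56, 0.3), c(0.146, 0.033, 0.041),
                   slab = c("A", "B", "C"))
  expect_s3_class(fit, "mcid_meta")
  expect_named(coef(fit), "mu")
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(fit$ci_low, fit$ci_high))
  expect_lte(ci[1, 1], coef(fit))
  expect_gte(ci[1, 2], coef(fit))
  w <- weights(fit)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_named(w, c("A", "B", "C"))
  r <- residuals(fit)
  expect_equal(as.numeric(r), fit$yi - fit$mu)
  pr <- predict(fit)
  expect_lte(pr$pi_low, pr$ci_low)
  expect_gte(pr$pi_high, pr$ci_high)
  expect_output(print(fit), "Pooled MD")
  expect_output(print(summary(fit)), "Per-study effects")
  # Knapp-Hartung widens the CI via a t critical value
  kh <- mcid_meta(fit$yi, fit$vi, knapp_hartung = TRUE)
  expect_equal(kh$mu, fit$mu)
  expect_identical(kh$crit, qt(0.975, df = 2))
})

test_that("forest data carry per-study CIs and weights summing to 100", {
  fit <- mcid_meta(c(0.1, 0.56, 0.3), c(0.146, 0.033, 0.041))
  rows <- forest_data(fit)
  expect_identical(nrow(rows), 4L)
  expect_identical(rows$label[4], "RE pooled")
  expect_equal(sum(rows$weight_percent[1:3]), 100, tolerance = 0.1)
  expect_equal(rows$ci_low[1:3], fit$yi - qnorm(0.975) * sqrt(fit$vi))
  one <- forest_data(mcid_meta(0.4, 0.02))
  expect_equal(one$weight_percent[1], 100)
  # equal variances at tau2 = 0 give equal weights
  eq <- forest_data(mcid_meta(c(0.1, 0.2, 0.3), rep(0.05, 3), method = "FE"))
  expect_equal(eq$weight_percent[1:3], rep(100 / 3, 3))
})

test_that("render_forest writes deterministic image files", {
  fit <- mcid_pipeline(demo_hip_studies())$fit
  path <- tempfile(fileext = ".png")
  render_forest(fit, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
  # identical annotations on a second render
  expect_identical(forest_data(fit), forest_data(fit))
  expect_error(render_forest(fit, tempfile(fileext = ".pdf")),
               "unsupported extension")
  expect_error(render_forest(fit, file.path(tempdir(), "no-such-dir",
                                            "deep", "f.png")))
})
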