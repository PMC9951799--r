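test_that("zero residuals give a null Egger regression", {
  se <- runif(20, 0.1, 0.5)
  eg <- egger_test(rep(0, 20), se)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(eg$slope, 0, tolerance = 1e-12)
  expect_false(eg$bias_flagged)
  expect_error(egger_test(c(0, 0), c(0.1, 0.1)), "at least 3")
})

test_that("Egger estimates equal an independent normal-equations solution", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    se <- runif(n, 0.05, 0.6)
    r <- rnorm(n, 0.1 * se, se)
    eg <- egger_test(r, se)
    # weighted least squares by explicit normal equations
    X <- cbind(1, se)
    W <- diag(1 / se^2)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% r)
    expect_equal(eg$intercept, beta[1], tolerance = 1e-8)
    expect_equal(eg$slope, beta[2], tolerance = 1e-8)
  }
})

test_that("induced suppression asymmetry is detected, symmetric funnels are not", {
  flag_asym <- 0
  flag_sym <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 250
    se <- runif(n, 0.05, 0.8)
    r <- rnorm(n, 0, se)
    # suppress most negative low-precision effects (classic file drawer)
    drop <- r < 0 & se > 0.3 & runif(n) < 0.9
    eg_a <- egger_test(r[!drop], se[!drop])
    if (eg_a$bias_flagged) flag_asym <- flag_asym + 1
    eg_s <- egger_test(r, se)
    if (!eg_s$bias_flagged) flag_sym <- flag_sym + 1
  }
  expect_gte(flag_asym, 15)
  expect_gte(flag_sym, 18)
})

test_that("funnel contour bounds collapse at zero sampling error", {
  eg <- egger_test(rnorm(10, 0, 0.1), rep(0.2, 10))
  f <- eg$funnel
  expect_true(all(f$upper_95 > 0 & f$lower_95 < 0))
  # bounds are proportional to se, so they vanish as se -> 0
  expect_equal(unname(unlist(f[1, -(1:2)])) / f$se[1] * 1e-9,
               rep(0, 6), tolerance = 1e-6)
})

test_that("residuals from a fitted model are centered and complete", {
  fits <- small_fits()
  r <- meta_residuals(fits$intercept)
  expect_length(r, fits$intercept$design$n)
  expect_lt(abs(mean(r)), 0.1)
  eg <- egger_test(r, fits$intercept$design$se)
  expect_length(eg$funnel$residual, length(r))
})

test_that("the year-trend slope interval covers zero when no trend exists", {
  p <- small_pipeline()
  yt <- suppressWarnings(
    year_trend_fit(p$effects, p$sim$tree, chains = 2, iter = 800,
                   warmup = 400, seed = 5))
  expect_lt(yt$slope_ci[1], 0)
  expect_gt(yt$slope_ci[2], 0)
  one_year <- p$effects
  one_year$year_published <- 2000L
  expect_error(year_trend_fit(one_year, p$sim$tree), "constant")
})

test_that("an injected publication-year trend is detected", {
  p <- small_pipeline()
  eff <- p$effects
  logyear <- log(eff$year_published - min(eff$year_published) + 1)
  eff$d <- eff$d + 0.5 * logyear
  yt <- suppressWarnings(
    year_trend_fit(eff, p$sim$tree, chains = 2, iter = 800,
                   warmup = 400, seed = 6))
  expect_gt(yt$slope_ci[1], 0) # interval excludes zero on the correct side
  # year varies only between studies (8 here), so the point estimate is
  # noisy; it must still land in the right neighbourhood
  expect_lt(abs(yt$slope - 0.5), 0.4)
})

test_that("meta-analytic power has its closed-form anchors", {
  # no effect: power equals the significance level
  expect_equal(power_meta(23, 20, 20, 0), 0.05, tolerance = 1e-10)
  # the reference design under the calibrated high-heterogeneity convention
  expect_equal(round(100 * power_meta(23, 20, 20, 0.288, "high")), 86)
  # the classical tau^2 = v convention is available numerically
  expect_equal(round(100 * power_meta(23, 20, 20, 0.288, 1)), 87)
  # huge k: power approaches 1
  expect_gt(power_meta(1e6, 20, 20, 0.1, "high"), 0.999)
  expect_error(power_meta(23, 20, 20, -0.1), "magnitude")
})

test_that("power is monotone in k and d, and decreasing in heterogeneity", {
  ks <- c(2, 5, 10, 23, 50, 200)
  pw <- power_curve(ks, 20, 20, 0.288, "high")$power
  expect_true(all(diff(pw) > 0))
  ds <- seq(0, 1, by = 0.1)
  pd <- vapply(ds, function(d) power_meta(23, 20, 20, d, "high"), numeric(1))
  expect_true(all(diff(pd) > 0))
  p_low <- power_meta(23, 20, 20, 0.288, "low")
  p_mod <- power_meta(23, 20, 20, 0.288, "moderate")
  p_high <- power_meta(23, 20, 20, 0.288, "high")
  expect_gt(p_low, p_mod)
  expect_gt(p_mod, p_high)
})
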