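test_that("degenerate and symmetric draws give the expected decisions", {
  dr <- cbind(beta_grass = rep(-0.2, 500))
  f <- fake_fit(dr)
  h <- hypothesis_test(f, "beta_grass", "negative")
  expect_equal(h$estimate, -0.2)
  expect_equal(h$ci_low, -0.2)
  expect_equal(h$ci_high, -0.2)
  expect_equal(h$p_direction, 1)

  set.seed(2)
  dr2 <- cbind(beta_grass = c(rnorm(5000)))
  dr2 <- rbind(dr2, -dr2) # exactly symmetric around 0
  f2 <- fake_fit(dr2)
  h2 <- hypothesis_test(f2, "beta_grass", "negative")
  expect_equal(h2$p_direction, 0.5)
  expect_lt(h2$ci_low, 0)
  expect_gt(h2$ci_high, 0)
  expect_false(h2$supported)
  expect_error(hypothesis_test(f2, "no_such_par"), "unknown parameter")
})

test_that("interval endpoints equal a sorting oracle and are monotone in level", {
  set.seed(3)
  dr <- cbind(b = rnorm(4000, -0.1, 0.2))
  f <- fake_fit(dr)
  sorted <- sort(dr[, "b"])
  for (level in c(0.5, 0.9, 0.95)) {
    h <- hypothesis_test(f, "b", level = level)
    a <- (1 - level) / 2
    # sorting-based empirical quantile (nearest order statistics)
    n_s <- length(sorted)
    lo_idx <- max(2, floor(a * n_s))
    hi_idx <- min(n_s - 1, ceiling((1 - a) * n_s))
    # equal-tailed endpoints must sit between adjacent order statistics
    expect_gte(h$ci_low, sorted[lo_idx - 1])
    expect_lte(h$ci_low, sorted[lo_idx + 2])
    expect_lte(h$ci_high, sorted[hi_idx + 1])
    expect_gte(h$ci_high, sorted[hi_idx - 2])
  }
  w95 <- hypothesis_test(f, "b", level = 0.95)
  w90 <- hypothesis_test(f, "b", level = 0.90)
  expect_lt(w95$ci_low, w90$ci_low)
  expect_gt(w95$ci_high, w90$ci_high)
})

test_that("linear-combination contrasts are evaluated per draw", {
  dr <- cbind(a = c(1, 2, 3), b = c(0.5, 0.5, 0.5))
  f <- fake_fit(dr)
  h <- hypothesis_test(f, c(a = 1, b = -2), direction = "positive")
  expect_equal(h$estimate, mean(dr[, "a"] - 2 * dr[, "b"]))
})

test_that("variance decomposition reproduces closed-form shares", {
  groups <- list(study = 1L, method = 1L)
  # tau = sigma = 1: a 50/50 split between one factor and the residual
  dr <- cbind(tau_study = rep(1, 100), sigma = rep(1, 100),
              nu = rep(10, 100))
  f <- fake_fit(dr, groups = list(study = 1L))
  vd <- variance_decomposition(f)
  expect_equal(vd$proportion, c(0.5, 0.5))
  # taus (3, 4) with sigma = 0: shares 9/25 and 16/25
  dr2 <- cbind(tau_study = rep(3, 50), tau_method = rep(4, 50),
               sigma = rep(1e-12, 50), nu = rep(10, 50))
  f2 <- fake_fit(dr2, groups = groups)
  vd2 <- variance_decomposition(f2)
  expect_equal(vd2$proportion[1:2], c(9, 16) / 25, tolerance = 1e-6)
  expect_equal(vd2$percent[1:2], c(36, 64))
})

test_that("decomposition shares always sum to one", {
  fits <- small_fits()
  vd <- variance_decomposition(fits$intercept)
  expect_equal(sum(vd$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(vd$proportion_of_means), 1, tolerance = 1e-9)
  vdt <- variance_decomposition(fits$intercept, inflate_t = TRUE)
  expect_equal(sum(vdt$proportion), 1, tolerance = 1e-9)
  # t-inflation can only grow the residual share
  expect_gte(vdt$proportion[nrow(vdt)], vd$proportion[nrow(vd)])
})

test_that("WAIC's lppd term matches the closed form for fixed parameters", {
  # constant draws: lppd_i must equal the pointwise log density exactly
  set.seed(4)
  n <- 30
  y <- rnorm(n)
  se <- rep(0.5, n)
  S <- 200
  dr <- cbind(matrix(0, S, n, dimnames = list(NULL, paste0("mu[", 1:n, "]"))),
              sigma = rep(1, S), nu = rep(1e6, S))
  f <- fake_fit(dr, y = y, se = se)
  res <- suppressWarnings(loo_waic(f))
  closed <- dnorm(y, 0, sqrt(1 + 0.25), log = TRUE)
  expect_equal(res$pointwise[, "lppd"], closed, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res$p_waic, 0, tolerance = 1e-10)
})

test_that("a model compared with itself has zero elpd difference", {
  fits <- small_fits()
  l <- loo_waic(fits$intercept)
  cmp <- compare_models(fits$intercept, fits$intercept, loo_a = l, loo_b = l)
  expect_equal(cmp$elpd_diff, c(0, 0))
  expect_true(all(is.finite(l$pareto_k) | is.na(l$pareto_k)))
  expect_lt(l$p_loo, fits$intercept$design$n)
})

test_that("cell predictions are additive in the origin contrasts", {
  fits <- small_fits()
  nn <- predict_cell(fits$full, "nonnative", "native")
  na <- predict_cell(fits$full, "native", "native")
  # the cell difference equals the grass-origin contrast up to the smooth
  # evaluated at the two cells' mean distances
  bs_nn <- predict_spline_basis(fits$full$design$basis, nn$logpd)
  bs_na <- predict_spline_basis(fits$full$design$basis, na$logpd)
  smooth_diff <- fits$full$draws[, "beta_pd"] * (bs_nn$linear - bs_na$linear)
  wcols <- grep("^bw\\[", fits$full$params, value = TRUE)
  if (length(wcols) > 0) {
    smooth_diff <- smooth_diff + drop(
      fits$full$draws[, wcols, drop = FALSE] %*%
        (drop(bs_nn$wiggly) - drop(bs_na$wiggly)))
  }
  expect_equal(nn$draws - na$draws,
               fits$full$draws[, "beta_grass"] + smooth_diff,
               tolerance = 1e-10, ignore_attr = TRUE)
  # the same cell subtracted from itself is exactly zero
  expect_equal(nn$draws - nn$draws, rep(0, length(nn$draws)),
               ignore_attr = TRUE)
})
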