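test_that("spline basis is centered, decomposes, and handles degeneracy", {
  set.seed(5)
  x <- runif(200, 0, 2)
  b <- spline_basis(x, k = 10)
  expect_s3_class(b, "pd_smooth")
  expect_equal(mean(b$linear), 0, tolerance = 1e-8)
  expect_true(all(abs(colMeans(b$wiggly)) < 1e-8))
  expect_equal(ncol(b$wiggly), 8) # k - null space (constant absorbed, linear)
  # two distinct values: linear column only
  expect_message(b2 <- spline_basis(rep(c(0, 1), 10), k = 10), "reduced")
  expect_equal(ncol(b2$wiggly), 0)
  expect_error(spline_basis(rep(1, 10)), "constant")
})

test_that("least squares on the basis recovers a known linear trend", {
  set.seed(42)
  x <- runif(300, 0, 3)
  y <- 2 * x + rnorm(300, 0, 0.05)
  b <- spline_basis(x, k = 10)
  X <- cbind(1, b$linear, b$wiggly)
  beta <- qr.solve(X, y)
  expect_equal(beta[2], 2, tolerance = 0.02)      # linear component slope
  # the fitted wiggly contribution stays at the noise scale
  wig_fit <- drop(b$wiggly %*% beta[-(1:2)])
  expect_lt(max(abs(wig_fit)), 0.06)
})

test_that("basis prediction reproduces training columns at training points", {
  set.seed(6)
  x <- runif(80, 0, 1.5)
  b <- spline_basis(x, k = 8)
  pr <- predict_spline_basis(b, x)
  expect_equal(pr$linear, b$linear, tolerance = 1e-8)
  expect_equal(pr$wiggly, b$wiggly, tolerance = 1e-8)
})

test_that("design assembly produces a complete, partitioning factor inventory", {
  p <- small_pipeline()
  d <- build_design(p$effects, p$sim$tree, model = "full")
  expect_setequal(names(d$groups),
                  c("study", "substudy", "trait_in_substudy", "method",
                    "duration_in_method", "dose_category", "grass_species",
                    "recipient_species", "grass_species_tree",
                    "recipient_species_tree"))
  for (f in names(d$groups)) {
    idx <- d$groups[[f]]
    expect_false(anyNA(idx))
    expect_setequal(unique(idx), seq_along(d$levels[[f]]))
  }
  # conspecific rows sit at zero on the distance scale
  consp <- p$effects$grass_species == p$effects$recipient_species
  if (any(consp)) expect_true(all(d$logpd[consp] == 0))
  # native reference coding: all-native rows have zero fixed-effect values
  nat <- p$effects$grass_origin == "native" &
    p$effects$recipient_origin == "native"
  expect_true(all(d$nng[nat] == 0 & d$nnr[nat] == 0))
  # intercept model drops fixed effects and smooth
  di <- build_design(p$effects, p$sim$tree, model = "intercept")
  expect_null(di$basis)
})

test_that("species missing from the tree are fatal and named", {
  p <- small_pipeline()
  eff <- p$effects
  eff$grass_species[1] <- "unknown_species"
  expect_error(build_design(eff, p$sim$tree), "unknown_species")
})

test_that("the Student-t measurement-error density has the right limits", {
  # large nu agrees with the normal log density
  expect_equal(log_likelihood_point(0.7, 0.2, 0.3, 1e6, 0.1),
               dnorm(0.7, 0.2, sqrt(0.3^2 + 0.1^2), log = TRUE),
               tolerance = 1e-6)
  # se = 0 reduces to a plain scaled-shifted Student t
  expect_equal(log_likelihood_point(1.1, 0, 2, 5, 0),
               dt(1.1 / 2, df = 5, log = TRUE) - log(2))
  # matches the closed-form density on a grid (independent lgamma formula)
  y <- seq(-3, 3, length.out = 100)
  nu <- 4.5; sigma <- 0.4; se <- 0.25; mu <- 0.1
  sc <- sqrt(sigma^2 + se^2)
  z <- (y - mu) / sc
  ref <- lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) -
    log(sc) - (nu + 1) / 2 * log1p(z^2 / nu)
  expect_equal(log_likelihood_point(y, mu, sigma, nu, se), ref,
               tolerance = 1e-12)
})

test_that("near-zero heterogeneity is recovered and the intercept sum is identified", {
  cfg <- synthetic_config(
    n_studies = 10, seed = 21,
    true_b0_study = -0.3, true_b0_species = 0,
    true_beta_grass = 0, true_beta_recipient = 0, true_pd_slope = 0,
    taus = c(study = 0, substudy = 0, trait_in_substudy = 0, method = 0,
             duration_in_method = 0, dose_category = 0, grass_species = 0,
             recipient_species = 0, grass_species_tree = 0,
             recipient_species_tree = 0),
    sigma = 0.03, nu = 30, cv_range = c(0.05, 0.15),
    group_n_range = c(10, 20), geary_stress_frac = 0)
  sim <- simulate_dataset(cfg)
  rec <- validate_study_table(sim$records)$records
  es <- compute_effect_sizes(rec, quiet = TRUE)
  imp <- impute_dose(es$kept, m = 5, seed = 1)
  d <- build_design(imp$completed, sim$tree, model = "intercept")
  fit <- suppressWarnings(
    fit_meta_model(d, chains = 2, iter = 1500, warmup = 700, seed = 3))
  # every tau's 95% interval reaches below 0.05
  for (f in names(d$groups)) {
    q <- quantile(fit$draws[, paste0("tau_", f)], 0.025)
    expect_lt(unname(q), 0.05)
  }
  # the SUM of the two intercepts is data-identified near the truth
  expect_equal(mean(fit$draws[, "b0_sum"]), -0.3, tolerance = 0.05)
  expect_equal(fit$draws[, "b0_sum"],
               fit$draws[, "b0_study"] + fit$draws[, "b0_species"])
})

test_that("with known error and large fixed nu the intercept matches the inverse-variance mean", {
  set.seed(8)
  n <- 40
  se <- runif(n, 0.05, 0.3)
  truth <- -0.2
  y <- rnorm(n, truth, se)
  eff <- data.frame(
    study_id = "s1", substudy_id = "a", trait = "germination",
    growth_compartment = "n/a", method_category = "m", duration_days = 10,
    grass_species = "sp_01", recipient_species = "sp_01",
    grass_origin = "native", recipient_origin = "native",
    dose_value = 1, dose_unit = "g/L", material_condition = "fresh",
    material_part = "mixed", solvent_polarity = "polar",
    year_published = 2000L, d = y, se = se, v = se^2,
    dose_category = "g/L:1", stringsAsFactors = FALSE)
  tree <- parse_newick("(sp_01:1,sp_02:1);")
  expect_warning(des <- build_design(eff, tree, model = "intercept"),
                 "single-level")
  expect_length(des$groups, 0)
  fit <- suppressWarnings(
    fit_meta_model(des, chains = 2, iter = 3000, warmup = 500, seed = 4,
                   fix_nu = 1e6, fix_sigma = 1e-4))
  # conjugate closed form: precision-weighted mean with the N(0, 2) prior
  # on the intercept sum contributing precision 1/2
  w <- 1 / se^2
  post_mean <- sum(w * y) / (sum(w) + 0.5)
  expect_equal(mean(fit$draws[, "b0_sum"]), post_mean, tolerance = 0.01)
  expect_equal(unique(fit$draws[, "nu"]), 1e6)
})

test_that("the sampler is deterministic under a fixed seed", {
  p <- small_pipeline()
  d <- build_design(p$effects, p$sim$tree, model = "intercept")
  f1 <- suppressWarnings(fit_meta_model(d, chains = 1, iter = 300,
                                        warmup = 150, seed = 11))
  f2 <- suppressWarnings(fit_meta_model(d, chains = 1, iter = 300,
                                        warmup = 150, seed = 11))
  expect_identical(f1$draws, f2$draws)
})
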