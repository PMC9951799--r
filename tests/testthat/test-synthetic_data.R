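test_that("simulated trees are ultrametric, unit height, and deterministic", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(sort(tr$tip.label), c("sp_01", "sp_02"))
  tr50 <- simulate_tree(50, seed = 2)
  depths <- ape::node.depth.edgelength(tr50)[1:50]
  expect_equal(depths, rep(1, 50), tolerance = 1e-9)
  expect_identical(ape::write.tree(simulate_tree(12, seed = 9)),
                   ape::write.tree(simulate_tree(12, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_tree(12, seed = 9)),
                         ape::write.tree(simulate_tree(12, seed = 10))))
})

test_that("the generator is deterministic and records its ground truth", {
  cfg <- synthetic_config(n_studies = 4, seed = 31)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$y, s2$truth$y)
  expect_length(s1$truth$mu, nrow(s1$records))
  expect_named(s1$truth$group_effects,
               c("study", "substudy", "trait_in_substudy", "method",
                 "duration_in_method", "dose_category", "grass_species",
                 "recipient_species", "grass_species_tree",
                 "recipient_species_tree"))
})

test_that("a null configuration generates effects consistent with zero", {
  cfg <- synthetic_config(
    n_studies = 8, seed = 5,
    true_b0_study = 0, true_b0_species = 0,
    true_beta_grass = 0, true_beta_recipient = 0, true_pd_slope = 0,
    taus = c(study = 0, substudy = 0, trait_in_substudy = 0, method = 0,
             duration_in_method = 0, dose_category = 0, grass_species = 0,
             recipient_species = 0, grass_species_tree = 0,
             recipient_species_tree = 0),
    sigma = 0, geary_stress_frac = 0)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$y == 0))
  rec <- validate_study_table(sim$records)$records
  es <- compute_effect_sizes(rec, quiet = TRUE)$kept
  z <- abs(es$d) / es$se
  expect_gte(mean(z < 3), 0.99)
  expect_true(all(z < 5))
})

test_that("origin contrasts in the raw effects match the configured beta", {
  cfg <- synthetic_config(
    n_studies = 60, seed = 77, true_beta_grass = -0.15,
    true_beta_recipient = 0, true_pd_slope = 0,
    true_b0_study = 0, true_b0_species = 0,
    taus = c(study = 0.05, substudy = 0.05, trait_in_substudy = 0.05,
             method = 0.05, duration_in_method = 0.05, dose_category = 0.05,
             grass_species = 0.05, recipient_species = 0.05,
             grass_species_tree = 0, recipient_species_tree = 0),
    sigma = 0.1, geary_stress_frac = 0)
  sim <- simulate_dataset(cfg)
  rec <- validate_study_table(sim$records)$records
  es <- compute_effect_sizes(rec, quiet = TRUE)$kept
  expect_gt(nrow(es), 1000)
  on_native <- es$recipient_origin == "native"
  diff <- mean(es$d[on_native & es$grass_origin == "nonnative"]) -
    mean(es$d[on_native & es$grass_origin == "native"])
  expect_equal(diff, -0.15, tolerance = 0.05)
})

test_that("dose missingness hits its configured rate", {
  cfg <- synthetic_config(n_studies = 80, seed = 3,
                          missing_dose_frac = 0.23)
  sim <- simulate_dataset(cfg)
  expect_gt(nrow(sim$records), 1500)
  frac <- mean(is.na(sim$records$dose_value))
  expect_gte(frac, 0.21)
  expect_lte(frac, 0.25)
})

test_that("the default scale mirrors the compiled literature", {
  cfg <- synthetic_config(seed = 1)
  expect_equal(cfg$n_studies, 23)
  expect_equal(cfg$missing_dose_frac, 0.23)
  sim <- simulate_dataset(cfg)
  # around 520-560 comparisons under the default design
  expect_gt(nrow(sim$records), 350)
  expect_lt(nrow(sim$records), 750)
  # empirical variance decomposition roughly matches the configured shares:
  # study-design factors jointly dominate species terms
  expect_equal(length(unique(sim$records$study_id)), 23)
})
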