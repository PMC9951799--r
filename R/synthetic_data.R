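#' Configuration for the synthetic study generator
#'
#' Defaults emulate the compiled grass-allelopathy literature the package's
#' model is built for: 23 studies with nested sub-studies and traits,
#' roughly 520-560 control/treatment comparisons, 23\% of doses missing,
#' native and non-native grasses and recipients over a shared phylogeny,
#' variance shares across the random-effect factors matching a published
#' intercept-model decomposition (study 15\%, sub-study 8\%, trait 11\%,
#' method 10\%, duration 15\%, dose 9\%, grass species 9\%, recipient
#' species 15\%, tree-linked <1\%, residual 7\%) on a total-variance scale
#' of 0.5, and true fixed effects at the published full-model estimates.
#'
#' @param n_studies Number of studies.
#' @param max_substudies Max sub-studies per study (uniform 1..max).
#' @param traits_per_substudy Max traits measured per sub-study.
#' @param n_grass,n_recipient Species-pool sizes (pools may overlap through
#'   conspecific pairs).
#' @param frac_nonnative_grass,frac_nonnative_recipient Fraction of each
#'   species pool that is non-native.
#' @param frac_conspecific Probability a comparison pairs a grass with
#'   itself (phylogenetic distance 0).
#' @param true_b0_study,true_b0_species Component intercepts.
#' @param true_beta_grass,true_beta_recipient Origin fixed effects
#'   (non-native vs native).
#' @param true_pd_slope Slope of the default (linear) distance smooth.
#' @param smooth_fn Function of log-scaled distance giving the species-side
#'   smooth contribution; default `true_pd_slope * logpd`.
#' @param taus Named SDs of the random-effect factors.
#' @param sigma Residual scale of the Student-t observation noise.
#' @param nu Student-t degrees of freedom.
#' @param pairs_range,doses_range Ranges (min, max) of species pairs per
#'   trait and dose levels per pair.
#' @param group_n_range Per-group sample-size range.
#' @param cv_range Within-group coefficient-of-variation range.
#' @param geary_stress_frac Fraction of records generated at tiny n and
#'   extreme CV so the Geary screen has work to do.
#' @param missing_dose_frac Fraction of doses blanked completely at random.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    n_studies = 23, max_substudies = 3, traits_per_substudy = 2,
    n_grass = 15, n_recipient = 30,
    frac_nonnative_grass = 0.5, frac_nonnative_recipient = 0.5,
    frac_conspecific = 0.03,
    true_b0_study = 0.02, true_b0_species = -0.28,
    true_beta_grass = -0.14, true_beta_recipient = 0.09,
    true_pd_slope = -0.22, smooth_fn = NULL,
    taus = c(study = sqrt(0.075), substudy = sqrt(0.040),
             trait_in_substudy = sqrt(0.055), method = sqrt(0.050),
             duration_in_method = sqrt(0.075), dose_category = sqrt(0.045),
             grass_species = sqrt(0.045), recipient_species = sqrt(0.075),
             grass_species_tree = sqrt(0.0025),
             recipient_species_tree = sqrt(0.0025)),
    sigma = sqrt(0.035), nu = 5,
    pairs_range = c(2, 6), doses_range = c(1, 3),
    group_n_range = c(4, 20), cv_range = c(0.10, 0.40),
    geary_stress_frac = 0.01, missing_dose_frac = 0.23, seed = 42) {
  stopifnot(
    n_studies >= 2,
    frac_nonnative_grass >= 0 && frac_nonnative_grass <= 1,
    frac_nonnative_recipient >= 0 && frac_nonnative_recipient <= 1,
    missing_dose_frac >= 0 && missing_dose_frac < 1,
    all(taus >= 0), sigma >= 0, nu > 1)
  if (is.null(smooth_fn)) {
    force(true_pd_slope)
    smooth_fn <- function(logpd) true_pd_slope * logpd
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' Unit-height pure-birth tree with labelled tips (`sp_01`, ...),
#' deterministic under a fixed seed; a stand-in for a taxonomy-derived tree.
#'
#' @param n_species Number of tips, `>= 2`.
#' @param seed Integer seed.
#' @return An [ape::phylo].
#' @export
simulate_tree <- function(n_species, seed = 1) {
  stopifnot(n_species >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp_%02d", seq_len(n_species))
  tree
}

# positive truncated normal sample (observed group mean must stay positive)
.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= 0
  tries <- 0
  while (any(bad) && tries < 200) {
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
    bad <- x <= 0
    tries <- tries + 1
  }
  x[bad] <- mean[bad] * 0.01
  x
}

#' Simulate a full study-level dataset with known ground truth
#'
#' Generates raw control/treatment study records whose latent effect sizes
#' follow the package's hierarchical model exactly: group effects drawn from
#' their factor SDs (tree-linked effects from `MVN(0, tau^2 A)`), a linear
#' predictor combining both component intercepts, origin fixed effects and
#' the distance smooth, Student-t observation noise, and raw group summaries
#' realized from lognormal control means and normal within-group sampling.
#' Dose values are blanked completely at random at the configured rate.
#'
#' @param config A [synthetic_config()].
#' @param tree Optional [ape::phylo] covering at least
#'   `n_grass + n_recipient` species; simulated when NULL.
#' @return List with `records` (a study table ready for
#'   [validate_study_table()]), `truth` (per-row `mu`, `y`, `logpd`, the
#'   group effects, and the generating parameters), and `tree`.
#' @export
simulate_dataset <- function(config, tree = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n_species <- config$n_grass + config$n_recipient
  if (is.null(tree)) {
    tree <- simulate_tree(n_species, seed = config$seed + 1)
  }
  if (length(tree$tip.label) < n_species) {
    stop("tree has fewer tips than n_grass + n_recipient")
  }
  set.seed(config$seed)

  grass_pool <- tree$tip.label[seq_len(config$n_grass)]
  recipient_pool <- tree$tip.label[config$n_grass + seq_len(config$n_recipient)]
  origin_of <- function(pool, frac) {
    o <- rep("native", length(pool))
    o[sample.int(length(pool), round(frac * length(pool)))] <- "nonnative"
    stats::setNames(o, pool)
  }
  grass_origin <- origin_of(grass_pool, config$frac_nonnative_grass)
  recip_origin <- c(origin_of(recipient_pool, config$frac_nonnative_recipient),
                    grass_origin) # grasses keep their origin when recipients

  methods <- c("leachate", "extract", "residue", "soil_legacy", "exudate")
  durations <- c(7, 14, 21, 30, 60, 90)
  units <- c("g/L", "g/kg", "percent")

  rows <- list()
  ri <- 0L
  for (s in seq_len(config$n_studies)) {
    study_id <- sprintf("study_%02d", s)
    year <- sample(1985:2020, 1)
    n_sub <- sample.int(config$max_substudies, 1)
    for (b in seq_len(n_sub)) {
      substudy_id <- sprintf("sub_%d", b)
      method <- sample(methods, 1)
      duration <- sample(durations, 1)
      unit <- sample(units, 1)
      mat_cond <- sample(c("fresh", "dry"), 1)
      mat_part <- sample(c("aboveground", "belowground", "mixed"), 1)
      solvent <- sample(c("polar", "nonpolar", "aqueous"), 1)
      n_traits <- sample.int(config$traits_per_substudy, 1)
      traits <- sample(c("germination", "growth"), n_traits)
      for (trait in traits) {
        compartment <- if (trait == "growth") {
          sample(c("aboveground", "belowground", "total"), 1)
        } else "n/a"
        n_pairs <- sample(config$pairs_range[1]:config$pairs_range[2], 1)
        for (p in seq_len(n_pairs)) {
          g_sp <- sample(grass_pool, 1)
          r_sp <- if (stats::runif(1) < config$frac_conspecific) g_sp else
            sample(recipient_pool, 1)
          n_doses <- sample(config$doses_range[1]:config$doses_range[2], 1)
          dose_vals <- sort(exp(stats::rnorm(n_doses, 0.5, 0.75)))
          for (dv in dose_vals) {
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              study_id = study_id, substudy_id = substudy_id,
              trait = trait, growth_compartment = compartment,
              method_category = method, duration_days = duration,
              grass_species = g_sp, recipient_species = r_sp,
              grass_origin = unname(grass_origin[g_sp]),
              recipient_origin = unname(recip_origin[r_sp]),
              dose_value = dv, dose_unit = unit,
              material_condition = mat_cond, material_part = mat_part,
              solvent_polarity = solvent, year_published = year,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)

  # latent group effects, mirroring the model's factor inventory
  fac <- list(
    study = tab$study_id,
    substudy = paste(tab$study_id, tab$substudy_id, sep = "."),
    trait_in_substudy = paste(tab$study_id, tab$substudy_id, tab$trait,
                              sep = "."),
    method = tab$method_category,
    duration_in_method = paste(tab$method_category, tab$duration_days,
                               sep = "."),
    dose_category = dose_to_category(tab$dose_value, tab$dose_unit),
    grass_species = tab$grass_species,
    recipient_species = tab$recipient_species)
  group_effects <- list()
  mu <- rep(config$true_b0_study + config$true_b0_species, n)
  for (f in names(fac)) {
    lv <- unique(fac[[f]])
    eff <- stats::rnorm(length(lv), 0, config$taus[[f]])
    names(eff) <- lv
    group_effects[[f]] <- eff
    mu <- mu + eff[fac[[f]]]
  }
  A <- phylo_correlation(tree)
  for (f in c("grass_species_tree", "recipient_species_tree")) {
    sp_col <- if (f == "grass_species_tree") tab$grass_species else
      tab$recipient_species
    lv <- unique(sp_col)
    Af <- A[lv, lv, drop = FALSE]
    L <- chol(Af + diag(1e-8, nrow(Af)))
    eff <- config$taus[[f]] * drop(t(L) %*% stats::rnorm(length(lv)))
    names(eff) <- lv
    group_effects[[f]] <- eff
    mu <- mu + eff[sp_col]
  }

  pd <- patristic_matrix(tree)
  logpd <- log_scaled_distance(pd[cbind(tab$grass_species,
                                        tab$recipient_species)])
  mu <- mu + config$true_beta_grass * (tab$grass_origin == "nonnative") +
    config$true_beta_recipient * (tab$recipient_origin == "nonnative") +
    config$smooth_fn(logpd)
  mu <- unname(mu)
  y <- mu + config$sigma * stats::rt(n, df = config$nu)

  # realize raw group summaries
  stress <- stats::runif(n) < config$geary_stress_frac
  n_c <- sample(config$group_n_range[1]:config$group_n_range[2], n,
                replace = TRUE)
  n_t <- sample(config$group_n_range[1]:config$group_n_range[2], n,
                replace = TRUE)
  cv <- stats::runif(n, config$cv_range[1], config$cv_range[2])
  n_c[stress] <- sample(2:3, sum(stress), replace = TRUE)
  n_t[stress] <- sample(2:3, sum(stress), replace = TRUE)
  cv[stress] <- stats::runif(sum(stress), 1.2, 2.0)

  m_c <- exp(stats::rnorm(n, 2, 0.5))
  m_t <- m_c * exp(y)
  sd_c <- cv * m_c
  sd_t <- cv * m_t
  obs_m_c <- .rnorm_pos(n, m_c, sd_c / sqrt(n_c))
  obs_m_t <- .rnorm_pos(n, m_t, sd_t / sqrt(n_t))
  obs_sd_c <- sd_c * sqrt(stats::rchisq(n, n_c - 1) / (n_c - 1))
  obs_sd_t <- sd_t * sqrt(stats::rchisq(n, n_t - 1) / (n_t - 1))

  kind <- sample(c("sd", "se"), n, replace = TRUE)
  tab$mean_control <- obs_m_c
  tab$dispersion_control <- ifelse(kind == "se", obs_sd_c / sqrt(n_c), obs_sd_c)
  tab$n_control <- n_c
  tab$mean_treatment <- obs_m_t
  tab$dispersion_treatment <- ifelse(kind == "se", obs_sd_t / sqrt(n_t),
                                     obs_sd_t)
  tab$n_treatment <- n_t
  tab$dispersion_kind <- kind

  tab$dose_value[stats::runif(n) < config$missing_dose_frac] <- NA_real_
  rownames(tab) <- NULL

  list(records = tab,
       truth = list(mu = mu, y = y, logpd = logpd,
                    group_effects = group_effects,
                    params = config[c("true_b0_study", "true_b0_species",
                                      "true_beta_grass",
                                      "true_beta_recipient",
                                      "true_pd_slope", "sigma", "nu")],
                    taus = config$taus),
       tree = tree)
}

#' Simulation-based parameter-recovery experiment
#'
#' Runs the full pipeline (simulate raw records, effect sizes + Geary
#' screen, dose imputation, full-model fit, hypothesis contrasts) on
#' independent synthetic replicates and reports bias, RMSE and equal-tailed
#' interval coverage for the three hypothesis parameters.
#'
#' @param config A [synthetic_config()].
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate `r` uses derived seeds below 2^31.
#' @param level Interval level to assess coverage at, default 0.95.
#' @param chains,iter,warmup MCMC settings per replicate fit.
#' @param impute_m Imputations per replicate, default 10.
#' @return List with `per_replicate` (one row per replicate x parameter) and
#'   `summary` (bias, RMSE, coverage per parameter).
#' @export
recovery_experiment <- function(config, n_replicates = 20, seed = 1,
                                level = 0.95, chains = 2, iter = 1500,
                                warmup = 750, impute_m = 10) {
  truths <- c(beta_grass = config$true_beta_grass,
              beta_recipient = config$true_beta_recipient,
              beta_pd = config$true_pd_slope)
  res <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- (seed * 1009 + r * 9973) %% 2147483629L
    sim <- simulate_dataset(cfg)
    val <- validate_study_table(sim$records)
    es <- compute_effect_sizes(val$records, quiet = TRUE)
    imp <- impute_dose(es$kept, m = impute_m, seed = cfg$seed + 1)
    design <- build_design(imp$completed, sim$tree, model = "full")
    fit <- fit_meta_model(design, chains = chains, iter = iter,
                          warmup = warmup, seed = cfg$seed + 2)
    for (p in names(truths)) {
      ht <- hypothesis_test(fit, p, "negative", level = level)
      res[[length(res) + 1]] <- data.frame(
        replicate = r, param = p, estimate = ht$estimate,
        ci_low = ht$ci_low, ci_high = ht$ci_high, truth = truths[[p]],
        covered = truths[[p]] >= ht$ci_low & truths[[p]] <= ht$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$param), function(d) {
    data.frame(param = d$param[1],
               bias = mean(d$estimate - d$truth),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               coverage = mean(d$covered),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_replicate = per_rep, summary = summ)
}
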