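# Shared fixtures. Expensive MCMC fits are computed once per test run and
# cached in this environment.
.fx <- new.env(parent = emptyenv())

# A tiny, fully valid study table written by hand.
tiny_study_table <- function() {
  data.frame(
    study_id = c("s1", "s1", "s2"),
    substudy_id = c("a", "a", "a"),
    trait = c("germination", "growth", "germination"),
    growth_compartment = c("n/a", "aboveground", "n/a"),
    method_category = c("leachate", "leachate", "extract"),
    duration_days = c(14, 14, 7),
    grass_species = c("sp_01", "sp_01", "sp_02"),
    recipient_species = c("sp_03", "sp_03", "sp_04"),
    grass_origin = c("nonnative", "nonnative", "native"),
    recipient_origin = c("native", "native", "native"),
    dose_value = c(10, 10, NA),
    dose_unit = c("g/L", "g/L", "g/L"),
    material_condition = c("fresh", "fresh", "dry"),
    material_part = c("aboveground", "aboveground", "mixed"),
    solvent_polarity = c("polar", "polar", "aqueous"),
    year_published = c(2005L, 2005L, 2011L),
    mean_control = c(10, 8, 12),
    dispersion_control = c(2, 0.5, 3),
    n_control = c(10L, 16L, 8L),
    mean_treatment = c(7, 6, 11),
    dispersion_treatment = c(2, 0.4, 2.5),
    n_treatment = c(10L, 16L, 8L),
    dispersion_kind = c("sd", "se", "sd"),
    stringsAsFactors = FALSE)
}

# Small synthetic dataset carried through effects + imputation, shared by
# several test files.
small_pipeline <- function() {
  if (is.null(.fx$pipeline)) {
    cfg <- synthetic_config(n_studies = 8, seed = 7)
    sim <- simulate_dataset(cfg)
    val <- validate_study_table(sim$records)
    es <- compute_effect_sizes(val$records, quiet = TRUE)
    imp <- impute_dose(es$kept, m = 10, seed = 3)
    .fx$pipeline <- list(cfg = cfg, sim = sim, val = val, es = es,
                         effects = imp$completed)
  }
  .fx$pipeline
}

# Short-chain full-model and intercept-model fits on the small dataset.
small_fits <- function() {
  if (is.null(.fx$fits)) {
    p <- small_pipeline()
    df <- build_design(p$effects, p$sim$tree, model = "full")
    di <- build_design(p$effects, p$sim$tree, model = "intercept")
    ff <- suppressWarnings(fit_meta_model(df, chains = 2, iter = 1000,
                                          warmup = 500, seed = 1))
    fi <- suppressWarnings(fit_meta_model(di, chains = 2, iter = 1000,
                                          warmup = 500, seed = 2))
    .fx$fits <- list(full = ff, intercept = fi,
                     design_full = df, design_intercept = di)
  }
  .fx$fits
}

# Hand-built posterior object for draw-level functions that need no MCMC.
fake_fit <- function(draws, groups = NULL, y = NULL, se = NULL,
                     model = "full") {
  if (is.null(groups)) groups <- list()
  design <- list(groups = groups, y = y, se = se,
                 n = if (is.null(y)) NA_integer_ else length(y))
  structure(list(draws = draws, params = colnames(draws), design = design,
                 model = model,
                 chain = rep(1L, nrow(draws))),
            class = "meta_fit")
}
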