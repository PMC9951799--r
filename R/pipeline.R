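#' Configuration for an end-to-end analysis run
#'
#' @param input Path to a study-table CSV/TSV, or an in-memory data frame.
#' @param tree Path to a Newick file, or an [ape::phylo].
#' @param out_dir Output directory for stage tables; `NULL` writes nothing.
#' @param sep Field separator of `input` when it is a path.
#' @param seed Master seed; stage seeds are derived from it and recorded.
#' @param geary_threshold,geary_rule Screen settings, see
#'   [apply_geary_filter()].
#' @param variance_order Effect-size variance order, see [delta_lrr()].
#' @param impute_m Number of dose imputations, default 25.
#' @param chains,iter,warmup MCMC settings shared by all model fits.
#' @param priors Prior settings, see [default_priors()].
#' @param egger_variant `"weighted"` or `"snd"`.
#' @param decomposition_inflate_t Student-t inflation of the residual
#'   variance share, see [variance_decomposition()].
#' @param run_year_trend Fit the publication-year trend model, default TRUE.
#' @param power_d,power_n Expected mean difference and per-group n for the
#'   a-priori power computation (defaults 0.288 and 20).
#' @param power_heterogeneity Heterogeneity level for [power_meta()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input, tree, out_dir = NULL, sep = ",", seed = 1,
                       geary_threshold = 3, geary_rule = "both",
                       variance_order = 2, impute_m = 25,
                       chains = 4, iter = 2000, warmup = 1000,
                       priors = default_priors(),
                       egger_variant = "weighted",
                       decomposition_inflate_t = FALSE,
                       run_year_trend = TRUE,
                       power_d = 0.288, power_n = 20,
                       power_heterogeneity = "high") {
  structure(as.list(environment()), class = "run_config")
}

.write_stage <- function(x, out_dir, name, sep = ",") {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(x, file.path(out_dir, paste0(name, ".csv")), sep = sep,
                     row.names = FALSE, quote = TRUE)
}

#' Run the full meta-analytic pipeline
#'
#' Executes the stages in their methodological order: read/validate records,
#' Geary screen and delta-LRR effect sizes, dose imputation, intercept-model
#' and full-model fits, hypothesis contrasts, variance decomposition,
#' LOO/WAIC model comparison, Egger regression on the intercept-model
#' residuals, the publication-year trend model, and the a-priori power
#' computation. Every stage's output and seed is collected into a single
#' report; stage tables are written under `out_dir` when given.
#'
#' @param config A [run_config()].
#' @return A list of class `"run_report"` with stage outputs, row-count
#'   bookkeeping (`counts`: input = analyzed + screened-out +
#'   validation-rejected), seeds, and MCMC diagnostics.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(master = config$seed,
                impute = config$seed + 101,
                fit_intercept = config$seed + 202,
                fit_full = config$seed + 303,
                fit_year = config$seed + 404)

  tree <- if (inherits(config$tree, "phylo")) config$tree else
    parse_newick(path = config$tree)
  loaded <- if (is.data.frame(config$input)) {
    validate_study_table(config$input)
  } else {
    read_study_table(config$input, sep = config$sep)
  }
  .write_stage(loaded$rejects, config$out_dir, "rejects", config$sep)

  es <- compute_effect_sizes(loaded$records,
                             threshold = config$geary_threshold,
                             rule = config$geary_rule,
                             variance_order = config$variance_order,
                             quiet = TRUE)
  imp <- impute_dose(es$kept, m = config$impute_m, seed = seeds$impute)
  effects <- imp$completed
  .write_stage(effects, config$out_dir, "effect_sizes", config$sep)

  design_int <- build_design(effects, tree, model = "intercept")
  fit_int <- fit_meta_model(design_int, chains = config$chains,
                            iter = config$iter, warmup = config$warmup,
                            seed = seeds$fit_intercept,
                            priors = config$priors)
  design_full <- build_design(effects, tree, model = "full")
  fit_full <- fit_meta_model(design_full, chains = config$chains,
                             iter = config$iter, warmup = config$warmup,
                             seed = seeds$fit_full, priors = config$priors)

  hypotheses <- test_hypotheses(fit_full)
  hypotheses$percent_change <- percent_change(hypotheses$estimate)
  .write_stage(hypotheses, config$out_dir, "hypotheses", config$sep)

  decomposition <- variance_decomposition(
    fit_int, inflate_t = config$decomposition_inflate_t)
  .write_stage(decomposition, config$out_dir, "variance_decomposition",
               config$sep)

  comparison <- compare_models(fit_full, fit_int)
  .write_stage(comparison, config$out_dir, "model_comparison", config$sep)

  residuals <- meta_residuals(fit_int)
  egger <- egger_test(residuals, design_int$se,
                      variant = config$egger_variant)
  .write_stage(egger$funnel, config$out_dir, "funnel", config$sep)

  year_trend <- NULL
  if (config$run_year_trend) {
    year_trend <- year_trend_fit(effects, tree, chains = config$chains,
                                 iter = config$iter, warmup = config$warmup,
                                 seed = seeds$fit_year,
                                 priors = config$priors)
  }

  k_studies <- length(unique(effects$study_id))
  power <- power_meta(k = k_studies, n1 = config$power_n,
                      n2 = config$power_n, d = config$power_d,
                      heterogeneity = config$power_heterogeneity)
  curve <- power_curve(seq(2, max(30, k_studies)), n1 = config$power_n,
                       n2 = config$power_n, d = config$power_d,
                       heterogeneity = config$power_heterogeneity)
  .write_stage(curve, config$out_dir, "power_curve", config$sep)

  counts <- list(
    input = nrow(loaded$records) + nrow(loaded$rejects),
    validation_rejected = nrow(loaded$rejects),
    geary_dropped = es$n_dropped,
    analyzed = nrow(effects),
    dose_imputed = sum(imp$imputed_flag),
    dose_imputed_frac = mean(imp$imputed_flag))
  stopifnot(counts$input == counts$analyzed + counts$geary_dropped +
              counts$validation_rejected)

  intercepts <- t(apply(
    fit_int$draws[, c("b0_study", "b0_species", "b0_sum")], 2,
    function(d) c(mean = mean(d), stats::quantile(d, c(0.025, 0.975)))))

  report <- structure(list(
    counts = counts, seeds = seeds,
    intercept_model = list(fit = fit_int, intercepts = intercepts,
                           diagnostics = fit_int$diagnostics),
    full_model = list(fit = fit_full, diagnostics = fit_full$diagnostics),
    hypotheses = hypotheses,
    decomposition = decomposition,
    comparison = comparison,
    egger = egger,
    year_trend = year_trend,
    power = list(power = power, k = k_studies, curve = curve),
    config = config[setdiff(names(config), c("input", "tree"))]),
    class = "run_report")
  if (!is.null(config$out_dir)) {
    summary_json <- list(
      counts = counts, seeds = seeds,
      intercepts = as.data.frame(intercepts),
      power_percent = round(100 * power))
    jsonlite::write_json(summary_json,
                         file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Allelopathy meta-analysis run\n")
  cat(sprintf("  records: %d in = %d analyzed + %d Geary-dropped + %d rejected\n",
              x$counts$input, x$counts$analyzed, x$counts$geary_dropped,
              x$counts$validation_rejected))
  cat(sprintf("  dose imputed for %d records (%.0f%%)\n",
              x$counts$dose_imputed, 100 * x$counts$dose_imputed_frac))
  cat("  component intercepts (intercept model):\n")
  print(round(x$intercept_model$intercepts, 3))
  cat("  hypotheses (full model):\n")
  print(x$hypotheses[, c("name", "estimate", "ci_low", "ci_high",
                         "supported")], row.names = FALSE)
  cat(sprintf("  a-priori power: %.0f%% (k = %d)\n",
              100 * x$power$power, x$power$k))
  invisible(x)
}
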