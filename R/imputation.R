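# Bayesian linear-regression parameter draw (the "norm.draw" step of
# chained-equation imputation): sigma^2 from the scaled inverse chi-square,
# beta from its normal conditional. A small ridge keeps X'X invertible when
# factor columns are collinear.
.norm_draw <- function(X, y, ridge = 1e-5) {
  p <- ncol(X)
  XtX <- crossprod(X) + diag(ridge * diag(crossprod(X)) + 1e-10, p)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  resid <- y - X %*% beta_hat
  df <- max(length(y) - p, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  beta_star <- beta_hat +
    backsolve(R, stats::rnorm(p)) * sqrt(sigma2)
  list(beta_hat = beta_hat, beta_star = beta_star)
}

# Predictive-mean-matching draw for one incomplete numeric variable.
.pmm_draw <- function(X_obs, y_obs, X_mis, donors = 5) {
  par <- .norm_draw(X_obs, y_obs)
  yhat_obs <- drop(X_obs %*% par$beta_hat)
  yhat_mis <- drop(X_mis %*% par$beta_star)
  vapply(yhat_mis, function(yh) {
    idx <- order(abs(yhat_obs - yh))[seq_len(min(donors, length(y_obs)))]
    y_obs[idx[sample.int(length(idx), 1)]]
  }, numeric(1))
}

.default_dose_predictors <- c(
  "d", "se", "study_id", "trait", "method_category", "duration_days",
  "grass_origin", "recipient_origin")

#' Impute missing dose values by chained equations
#'
#' Fills in missing `dose_value` entries with predictive-mean-matching (PMM)
#' chained-equation imputation: a Bayesian linear regression of (log) dose on
#' the effect size, its standard error and the model's moderators is drawn
#' `m` times, each missing entry is matched to its `donors` nearest observed
#' records by predicted value, and a donor's observed dose is taken. The
#' working value for each record is the median of its `m` draws; observed
#' doses are never modified. Because dose spans orders of magnitude and units
#' differ between assay types, imputation runs on the log10 scale within each
#' `dose_unit` class by default.
#'
#' Dose is the only incomplete variable, so the chained-equation cycle
#' converges after its first pass; `iterations` is retained for interface
#' completeness.
#'
#' @param effects Effect table (kept records from [compute_effect_sizes()]),
#'   with `dose_value`, `dose_unit`, `d`, `se` and moderator columns.
#' @param m Number of imputations, default 25. Must be `>= 2`.
#' @param iterations Chained-equation iterations (see Details), default 10.
#' @param seed Integer seed; fixed seed reproduces draws exactly.
#' @param donors PMM donor-pool size per draw, default 5.
#' @param log_scale Impute on log10(dose) within unit class (default TRUE).
#' @param predictors Predictor columns for the imputation model.
#' @return A list of class `"dose_imputation"`: `completed` (the effect table
#'   with `dose_value` completed, `dose_category` and logical `imputed`
#'   columns), `draws` (matrix, one row per imputed record, `m` columns),
#'   `m`, and `imputed_flag`.
#' @export
impute_dose <- function(effects, m = 25, iterations = 10, seed = NULL,
                        donors = 5, log_scale = TRUE,
                        predictors = .default_dose_predictors) {
  if (m < 2) stop("m must be >= 2")
  miss <- is.na(effects$dose_value)
  if (all(miss)) stop("all doses missing: no donors to match against")
  if (!is.null(seed)) set.seed(seed)

  completed <- effects
  draws <- matrix(numeric(0), nrow = 0, ncol = m)
  if (any(miss)) {
    predictors <- intersect(predictors, names(effects))
    # single-level predictors carry no information and break dummy coding
    multi <- vapply(predictors, function(p) {
      length(unique(effects[[p]])) > 1
    }, logical(1))
    predictors <- predictors[multi]
    form <- stats::as.formula(
      if (length(predictors) == 0) "~ 1" else
        paste("~", paste(predictors, collapse = " + ")))
    X_all <- stats::model.matrix(form, data = effects)

    unit <- as.character(effects$dose_unit)
    unit[is.na(unit)] <- "(none)"
    draws <- matrix(NA_real_, nrow = sum(miss), ncol = m)
    rownames(draws) <- rownames(effects)[miss]
    miss_pos <- which(miss)
    for (u in unique(unit[miss])) {
      in_u <- unit == u
      obs_u <- which(in_u & !miss)
      mis_u <- which(in_u & miss)
      if (length(obs_u) < 3) {
        stop("unit class '", u, "' has fewer than 3 observed doses; ",
             "cannot impute within it")
      }
      y_obs <- effects$dose_value[obs_u]
      if (log_scale) y_obs <- log10(y_obs)
      keep_col <- apply(X_all[obs_u, , drop = FALSE], 2,
                        function(col) stats::var(col) > 0)
      keep_col[1] <- TRUE # intercept
      X_obs <- X_all[obs_u, keep_col, drop = FALSE]
      X_mis <- X_all[mis_u, keep_col, drop = FALSE]
      for (j in seq_len(m)) {
        imp <- .pmm_draw(X_obs, y_obs, X_mis, donors = donors)
        if (log_scale) imp <- 10^imp
        draws[match(mis_u, miss_pos), j] <- imp
      }
    }
    completed$dose_value[miss] <- apply(draws, 1, stats::median)
  }
  completed$imputed <- miss
  completed$dose_category <- dose_to_category(completed$dose_value,
                                              completed$dose_unit)
  structure(list(completed = completed, draws = draws, m = m,
                 imputed_flag = miss),
            class = "dose_imputation")
}

#' Convert a dose to the categorical label used as a random effect
#'
#' Doses enter the hierarchical model as a random-effect factor, so they are
#' rounded to 2 significant figures and prefixed with their unit class;
#' equal numeric doses in different unit classes map to distinct labels.
#'
#' @param dose Positive dose value(s).
#' @param unit Dose unit label(s), recycled.
#' @param sig_figs Significant figures to round to, default 2.
#' @return Character label(s) of the form `"g/L:0.46"`.
#' @export
dose_to_category <- function(dose, unit, sig_figs = 2) {
  if (any(!is.na(dose) & dose <= 0)) stop("dose must be positive")
  unit <- as.character(unit)
  unit[is.na(unit)] <- "(none)"
  ifelse(is.na(dose), NA_character_,
         paste0(unit, ":", format(signif(dose, sig_figs),
                                  trim = TRUE, scientific = FALSE)))
}
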