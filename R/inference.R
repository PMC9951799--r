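#' Directional posterior hypothesis test
#'
#' Evaluates a linear combination of model parameters on every posterior
#' draw and summarizes it: posterior mean, equal-tailed credible interval at
#' `level`, the directional probability `p_direction` (fraction of draws
#' with the a-priori predicted sign), and a support decision. The test is
#' supported when the interval bound on the predicted side excludes zero:
#' for a predicted negative contrast, the upper bound must be below 0.
#'
#' The package's three standing contrasts are the Novel Weapons Hypothesis
#' (`beta_grass`, predicted negative), the Biotic Resistance Hypothesis
#' (`beta_recipient`, predicted negative), and the Phylogenetic Distance
#' Hypothesis (the linear smooth coefficient `beta_pd`, predicted negative);
#' see [test_hypotheses()].
#'
#' @param fit A `"meta_fit"` from [fit_meta_model()].
#' @param contrast Either a single parameter name, or a named numeric vector
#'   of coefficients over parameter names.
#' @param direction Predicted sign, `"negative"` (default) or `"positive"`.
#' @param level Credible level, default 0.95.
#' @param name Label for the result.
#' @return A one-row data frame of class `"hypothesis_result"` with columns
#'   `name`, `estimate`, `ci_low`, `ci_high`, `level`, `p_direction`,
#'   `supported`.
#' @export
hypothesis_test <- function(fit, contrast, direction = c("negative", "positive"),
                            level = 0.95, name = NULL) {
  direction <- match.arg(direction)
  stopifnot(level > 0, level < 1)
  if (is.character(contrast)) {
    cn <- contrast
    contrast <- rep(1, length(cn))
    names(contrast) <- cn
  }
  vals <- drop(posterior_draws(fit, names(contrast)) %*% contrast)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(vals, c(alpha, 1 - alpha)))
  p_dir <- if (direction == "negative") mean(vals < 0) else mean(vals > 0)
  supported <- if (direction == "negative") ci[2] < 0 else ci[1] > 0
  out <- data.frame(
    name = if (is.null(name)) paste(names(contrast), collapse = "+") else name,
    estimate = mean(vals), ci_low = ci[1], ci_high = ci[2],
    level = level, p_direction = p_dir, supported = supported,
    stringsAsFactors = FALSE)
  class(out) <- c("hypothesis_result", class(out))
  out
}

#' Test the three invasion-biology hypotheses
#'
#' Runs the three standing directional contrasts on a full-model fit:
#' Novel Weapons (non-native grasses suppress native recipients more than
#' native grasses do; `beta_grass < 0`), Biotic Resistance (native grasses
#' suppress non-native recipients more than native ones; `beta_recipient <
#' 0`), and Phylogenetic Distance (suppression strengthens with distance;
#' linear smooth coefficient `< 0`). Negative differences were the a-priori
#' prediction for all three.
#'
#' @param fit A full-model `"meta_fit"`.
#' @param level Credible level, default 0.95.
#' @return Data frame with one row per hypothesis.
#' @export
test_hypotheses <- function(fit, level = 0.95) {
  stopifnot(fit$model == "full")
  rbind(
    hypothesis_test(fit, "beta_grass", "negative", level,
                    name = "Novel Weapons Hypothesis"),
    hypothesis_test(fit, "beta_recipient", "negative", level,
                    name = "Biotic Resistance Hypothesis"),
    hypothesis_test(fit, "beta_pd", "negative", level,
                    name = "Phylogenetic Distance Hypothesis"))
}

#' Posterior of an origin-cell mean effect
#'
#' Predicted average effect size for a grass-origin x recipient-origin cell:
#' the sum of the two component intercepts, the origin fixed effects, and
#' the distance smooth evaluated at the mean log-scaled phylogenetic
#' distance of that cell's rows (the overall mean, with a warning, when the
#' cell has no data).
#'
#' @param fit A full-model `"meta_fit"`.
#' @param grass_origin,recipient_origin `"native"` or `"nonnative"`.
#' @return List with `draws`, `mean`, `ci` (95\% equal-tailed),
#'   `p_negative`, and the `logpd` value used.
#' @export
predict_cell <- function(fit, grass_origin, recipient_origin) {
  stopifnot(fit$model == "full")
  grass_origin <- match.arg(grass_origin, c("native", "nonnative"))
  recipient_origin <- match.arg(recipient_origin, c("native", "nonnative"))
  eff <- fit$design$effects
  rows <- eff$grass_origin == grass_origin &
    eff$recipient_origin == recipient_origin
  if (!any(rows)) {
    warning("no data rows in cell ", grass_origin, " x ", recipient_origin,
            "; using overall mean distance")
    logpd <- mean(fit$design$logpd)
  } else {
    logpd <- mean(fit$design$logpd[rows])
  }
  bs <- predict_spline_basis(fit$design$basis, logpd)
  dr <- fit$draws
  vals <- dr[, "b0_study"] + dr[, "b0_species"] +
    (grass_origin == "nonnative") * dr[, "beta_grass"] +
    (recipient_origin == "nonnative") * dr[, "beta_recipient"] +
    dr[, "beta_pd"] * bs$linear
  wcols <- grep("^bw\\[", fit$params, value = TRUE)
  if (length(wcols) > 0) {
    vals <- vals + drop(dr[, wcols, drop = FALSE] %*% drop(bs$wiggly))
  }
  list(draws = vals, mean = mean(vals),
       ci = unname(stats::quantile(vals, c(0.025, 0.975))),
       p_negative = mean(vals < 0), logpd = logpd)
}

#' Variance decomposition of the intercept model
#'
#' Shares of total variance attributed to each random-effect factor and the
#' residual: per draw, `tau_r^2 / (sum_r tau_r^2 + sigma^2)`, summarized by
#' the posterior mean of each share (the canonical output) and, for
#' reference, by the share of posterior-mean variances. Shares sum to 1 by
#' construction. `sigma` is the regression noise scale; optionally the
#' residual variance can be inflated by the Student-t factor
#' `nu / (nu - 2)`.
#'
#' @param fit A `"meta_fit"`, normally of the intercept model.
#' @param inflate_t Inflate `sigma^2` by `nu/(nu-2)` (draws with `nu <= 2.1`
#'   clamped), default FALSE.
#' @return Data frame with `component`, `proportion` (posterior mean of the
#'   per-draw share), `percent` (rounded), `proportion_of_means`.
#' @export
variance_decomposition <- function(fit, inflate_t = FALSE) {
  stopifnot(inherits(fit, "meta_fit"))
  tau_cols <- paste0("tau_", names(fit$design$groups),
                     recycle0 = TRUE)
  tau_cols <- intersect(tau_cols, fit$params)
  tau2 <- fit$draws[, tau_cols, drop = FALSE]^2
  sigma2 <- fit$draws[, "sigma"]^2
  if (inflate_t) {
    nu <- pmax(fit$draws[, "nu"], 2.1)
    sigma2 <- sigma2 * nu / (nu - 2)
  }
  var_mat <- cbind(tau2, residual = sigma2)
  total <- rowSums(var_mat)
  shares <- var_mat / total
  prop <- colMeans(shares)
  prop_of_means <- colMeans(var_mat) / sum(colMeans(var_mat))
  data.frame(
    component = c(sub("^tau_", "", tau_cols), "residual"),
    proportion = unname(prop),
    percent = unname(round(100 * prop)),
    proportion_of_means = unname(prop_of_means),
    stringsAsFactors = FALSE)
}

#' PSIS-LOO and WAIC from a fitted model
#'
#' Computes pointwise log likelihoods from the posterior draws of the linear
#' predictor (the fit must have been run with `monitor_mu = TRUE`), then
#' Pareto-smoothed importance-sampling leave-one-out cross-validation and
#' WAIC with their standard errors.
#'
#' @param fit A `"meta_fit"`.
#' @return List of class `"loo_result"`: `elpd_loo`, `se_elpd_loo`, `p_loo`,
#'   `elpd_waic`, `se_elpd_waic`, `p_waic`, `waic` (`-2 * elpd_waic`),
#'   `pointwise` (matrix with per-observation contributions), `pareto_k`,
#'   `n_high_k`.
#' @export
loo_waic <- function(fit) {
  ll <- .pointwise_loglik(fit)
  s <- nrow(ll)
  n <- ncol(ll)

  lppd_i <- apply(ll, 2, .logsumexp) - log(s)
  p_waic_i <- apply(ll, 2, stats::var)
  elpd_waic_i <- lppd_i - p_waic_i

  elpd_loo_i <- numeric(n)
  pareto_k <- numeric(n)
  for (j in seq_len(n)) {
    ps <- .psis_smooth(-ll[, j])
    elpd_loo_i[j] <- .logsumexp(ps$log_weights + ll[, j])
    pareto_k[j] <- ps$pareto_k
  }
  n_high <- sum(is.finite(pareto_k) & pareto_k > 0.7)
  if (n_high > 0.1 * n) {
    warning(sprintf("%d of %d Pareto-k values exceed 0.7; LOO may be unreliable",
                    n_high, n))
  }
  structure(list(
    elpd_loo = sum(elpd_loo_i),
    se_elpd_loo = sqrt(n * stats::var(elpd_loo_i)),
    p_loo = sum(lppd_i - elpd_loo_i),
    elpd_waic = sum(elpd_waic_i),
    se_elpd_waic = sqrt(n * stats::var(elpd_waic_i)),
    p_waic = sum(p_waic_i),
    waic = -2 * sum(elpd_waic_i),
    pointwise = cbind(lppd = lppd_i, elpd_loo = elpd_loo_i,
                      elpd_waic = elpd_waic_i),
    pareto_k = pareto_k,
    n_high_k = n_high), class = "loo_result")
}

.pointwise_loglik <- function(fit) {
  mu_cols <- grep("^mu\\[", fit$params, value = TRUE)
  if (length(mu_cols) == 0) {
    stop("fit has no draws of mu; rerun fit_meta_model(monitor_mu = TRUE)")
  }
  ord <- order(as.integer(sub("^mu\\[(\\d+)\\]$", "\\1", mu_cols)))
  mu <- fit$draws[, mu_cols[ord], drop = FALSE]
  sigma <- fit$draws[, "sigma"]
  nu <- fit$draws[, "nu"]
  y <- fit$design$y
  se <- fit$design$se
  ll <- matrix(NA_real_, nrow = nrow(mu), ncol = ncol(mu))
  for (j in seq_len(ncol(mu))) {
    ll[, j] <- log_likelihood_point(y[j], mu[, j], sigma, nu, se[j])
  }
  ll
}

#' Compare two fitted models by expected log predictive density
#'
#' Pointwise elpd difference (model A minus model B) with its standard
#' error, for both PSIS-LOO and WAIC, in the style of a two-model
#' `loo_compare`.
#'
#' @param fit_a,fit_b Two `"meta_fit"` objects on the same data.
#' @param loo_a,loo_b Optional precomputed [loo_waic()] results.
#' @return Data frame with rows `loo` and `waic`: `elpd_a`, `elpd_b`,
#'   `elpd_diff` (A - B), `se_diff`.
#' @export
compare_models <- function(fit_a, fit_b, loo_a = NULL, loo_b = NULL) {
  if (is.null(loo_a)) loo_a <- loo_waic(fit_a)
  if (is.null(loo_b)) loo_b <- loo_waic(fit_b)
  stopifnot(nrow(loo_a$pointwise) == nrow(loo_b$pointwise))
  n <- nrow(loo_a$pointwise)
  d_loo <- loo_a$pointwise[, "elpd_loo"] - loo_b$pointwise[, "elpd_loo"]
  d_waic <- loo_a$pointwise[, "elpd_waic"] - loo_b$pointwise[, "elpd_waic"]
  data.frame(
    criterion = c("loo", "waic"),
    elpd_a = c(loo_a$elpd_loo, loo_a$elpd_waic),
    elpd_b = c(loo_b$elpd_loo, loo_b$elpd_waic),
    elpd_diff = c(sum(d_loo), sum(d_waic)),
    se_diff = c(sqrt(n * stats::var(d_loo)), sqrt(n * stats::var(d_waic))),
    stringsAsFactors = FALSE)
}
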