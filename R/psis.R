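# Pareto-smoothed importance sampling (PSIS) internals.
#
# Generalized Pareto tail fit by the Zhang & Stephens (2009) profile
# posterior-mean estimator, with the weakly-informative shrinkage toward
# k = 0.5 used by modern PSIS implementations; then the largest importance
# weights are replaced by expected order statistics of the fitted tail.

# Fit GPD(k, sigma) to exceedances x > 0 (location 0). Returns c(k, sigma).
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jhalf <- seq_len(m) - 0.5
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / jhalf)) / (prior_bs * xstar)
  profile_loglik <- vapply(theta, function(b) {
    k <- -mean(log1p(-b * x))
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- exp(profile_loglik - max(profile_loglik))
  w <- w / sum(w)
  b_hat <- sum(theta * w)
  k_hat <- -mean(log1p(-b_hat * x))
  sigma_hat <- k_hat / b_hat
  # weakly-informative shrinkage of k toward 0.5
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  c(k = k_hat, sigma = sigma_hat)
}

.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of log importance ratios. Returns list(log_weights
# normalized to logsumexp 0, pareto_k).
.psis_smooth <- function(log_ratios) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  tail_len <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  k_hat <- Inf
  if (tail_len >= 5) {
    ord <- order(lw)
    tail_ids <- ord[(s - tail_len + 1):s]
    cutoff <- exp(lw[ord[s - tail_len]])
    exceed <- exp(lw[tail_ids]) - cutoff
    if (all(exceed >= 0) && stats::sd(exceed) > 0) {
      fit <- .gpd_fit(exceed[exceed > 0])
      k_hat <- fit["k"]
      if (is.finite(k_hat)) {
        p <- (seq_len(tail_len) - 0.5) / tail_len
        smoothed <- cutoff + vapply(p, .gpd_quantile, numeric(1),
                                    k = fit["k"], sigma = fit["sigma"])
        smoothed <- pmin(smoothed, exp(max(lw))) # never exceed max raw weight
        lw[tail_ids[order(exp(lw[tail_ids]))]] <- log(sort(smoothed))
      }
    } else {
      k_hat <- NA_real_
    }
  }
  lse <- .logsumexp(lw)
  list(log_weights = lw - lse, pareto_k = unname(k_hat))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
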