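#' Low-rank penalized spline basis for the phylogenetic-distance smooth
#'
#' Builds a thin-plate-type low-rank smooth basis for the log-scaled
#' phylogenetic distance and eigen-decomposes its penalty so that the
#' penalty null space is a single linear column (whose coefficient is the
#' reportable "coefficient of smoothed phylogenetic distance") and the
#' penalized range space becomes "wiggly" columns with an i.i.d. normal
#' prior under a shared smoothing SD. All columns are centered.
#'
#' @param x Covariate vector (log-scaled distances).
#' @param k Basis dimension before decomposition, default 10; reduced (with
#'   a message) when `x` has fewer distinct values.
#' @return An object of class `"pd_smooth"` with elements `linear` (n
#'   vector), `wiggly` (n x (k-2) matrix, possibly 0 columns), `k_used`, and
#'   the projection information needed by [predict_spline_basis()].
#' @export
spline_basis <- function(x, k = 10) {
  stopifnot(is.numeric(x), k >= 3)
  nd <- length(unique(x))
  if (nd < 2) stop("smooth covariate is constant; basis degenerates to an intercept")
  if (nd < 4) {
    # too few distinct values for a wiggly component: linear column only
    message("smooth covariate has ", nd,
            " distinct values; basis reduced to the linear column")
    lin <- x - mean(x)
    return(structure(list(linear = lin, wiggly = matrix(0, length(x), 0),
                          k_used = 2, center = mean(x), sm = NULL),
                     class = "pd_smooth"))
  }
  k_use <- min(k, nd)
  if (k_use < k) message("smooth basis dimension reduced to k = ", k_use)
  sm <- mgcv::smoothCon(mgcv::s(x, k = k_use, bs = "tp"),
                        data = data.frame(x = x), absorb.cons = TRUE)[[1]]
  X <- sm$X
  S <- sm$S[[1]]
  eg <- eigen(S, symmetric = TRUE)
  tol <- max(eg$values) * 1e-8
  pen <- eg$values > tol
  # range space, scaled so penalized coefficients are i.i.d. standard normal
  Zw <- X %*% eg$vectors[, pen, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pen]), sum(pen))
  Zl <- X %*% eg$vectors[, !pen, drop = FALSE]
  if (ncol(Zl) != 1) stop("unexpected penalty null-space dimension: ", ncol(Zl))
  lin <- drop(Zl)
  # orient and scale the null-space column to the covariate so its
  # coefficient reads as a per-unit slope in x
  fitc <- stats::coef(stats::lm(lin ~ x))[2]
  lin <- lin / fitc
  center <- mean(lin)
  lin <- lin - center
  # residualize the wiggly columns against {1, linear} so the linear
  # coefficient is the unambiguous per-unit trend of the smooth
  Xl <- cbind(1, lin)
  G <- qr.solve(Xl, Zw)
  wig <- Zw - Xl %*% G
  structure(list(linear = lin, wiggly = wig, k_used = k_use,
                 center = center, lin_scale = fitc,
                 sm = sm, U = eg$vectors, pen = pen,
                 d_pen = eg$values[pen], G = G),
            class = "pd_smooth")
}

#' Evaluate a fitted spline basis at new covariate values
#'
#' @param basis A `"pd_smooth"` object from [spline_basis()].
#' @param xnew New covariate values.
#' @return List with `linear` and `wiggly` evaluated at `xnew`, on the same
#'   centering as the training basis.
#' @export
predict_spline_basis <- function(basis, xnew) {
  stopifnot(inherits(basis, "pd_smooth"))
  if (is.null(basis$sm)) {
    return(list(linear = xnew - basis$center,
                wiggly = matrix(0, length(xnew), 0)))
  }
  Xp <- mgcv::PredictMat(basis$sm, data.frame(x = xnew))
  Zw <- Xp %*% basis$U[, basis$pen, drop = FALSE] %*%
    diag(1 / sqrt(basis$d_pen), length(basis$d_pen))
  lin <- drop(Xp %*% basis$U[, !basis$pen, drop = FALSE]) / basis$lin_scale -
    basis$center
  list(linear = lin, wiggly = Zw - cbind(1, lin) %*% basis$G)
}

# Factor inventory of the two model components. Nested factors are realized
# by interaction coding (each nested level is unique within its parent).
.study_side <- c("study", "substudy", "trait_in_substudy",
                 "method", "duration_in_method", "dose_category")
.species_side_iid <- c("grass_species", "recipient_species")
.species_side_tree <- c("grass_species_tree", "recipient_species_tree")

#' Assemble the design of the two-component hierarchical model
#'
#' Translates a completed effect table and a phylogeny into everything the
#' sampler needs: the response and its sampling SEs, dummy-coded origin
#' fixed effects (native is the reference level), the penalized smooth of
#' log-scaled phylogenetic distance, index vectors for every random-effect
#' factor of the "study" component (study, nested sub-study, nested trait;
#' method, nested duration; dose category) and the "species" component
#' (grass and recipient species, plain and tree-linked), and the
#' phylogenetic correlation matrices constraining the tree-linked effects.
#'
#' @param effects Completed effect table (post [impute_dose()]), with
#'   `d`, `se`, moderators and `dose_category`.
#' @param tree An [ape::phylo] covering all grass and recipient species.
#' @param model `"full"` (fixed effects + smooth) or `"intercept"` (random
#'   effects only).
#' @param k Smooth basis dimension, default 10.
#' @param pd_offset Offset of the log distance scale, default 1.
#' @param year_smooth Add a smooth of log-scaled publication year to the
#'   study component (publication-bias variant), default FALSE.
#' @return An object of class `"meta_design"`.
#' @export
build_design <- function(effects, tree, model = c("full", "intercept"),
                         k = 10, pd_offset = 1, year_smooth = FALSE) {
  model <- match.arg(model)
  stopifnot(is.data.frame(effects), nrow(effects) > 0,
            all(c("d", "se") %in% names(effects)))
  if (anyNA(effects$dose_category)) {
    stop("dose_category has missing values; run impute_dose() first")
  }

  fac <- list(
    study = factor(effects$study_id),
    substudy = interaction(effects$study_id, effects$substudy_id, drop = TRUE),
    trait_in_substudy = interaction(effects$study_id, effects$substudy_id,
                                    effects$trait, drop = TRUE),
    method = factor(effects$method_category),
    duration_in_method = interaction(effects$method_category,
                                     effects$duration_days, drop = TRUE),
    dose_category = factor(effects$dose_category),
    grass_species = factor(effects$grass_species),
    recipient_species = factor(effects$recipient_species)
  )
  fac$grass_species_tree <- fac$grass_species
  fac$recipient_species_tree <- fac$recipient_species

  single <- vapply(fac, nlevels, integer(1)) < 2
  if (any(single)) {
    warning("dropping single-level random effect(s): ",
            paste(names(fac)[single], collapse = ", "))
    fac <- fac[!single]
  }

  A <- phylo_correlation(tree)
  missing_sp <- setdiff(
    unique(c(effects$grass_species, effects$recipient_species)),
    rownames(A))
  if (length(missing_sp) > 0) {
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
  }
  A_list <- list()
  for (f in intersect(.species_side_tree, names(fac))) {
    lv <- levels(fac[[f]])
    A_list[[f]] <- A[lv, lv, drop = FALSE]
  }

  pdist <- .pair_log_distance(effects, tree, offset = pd_offset)
  basis <- NULL
  if (model == "full") basis <- spline_basis(pdist$logpd, k = k)

  ybasis <- NULL
  if (year_smooth) {
    logyear <- log(effects$year_published -
                     min(effects$year_published) + 1)
    ybasis <- spline_basis(logyear, k = k)
  }

  structure(list(
    y = effects$d,
    se = effects$se,
    n = nrow(effects),
    model = model,
    nng = as.numeric(effects$grass_origin == "nonnative"),
    nnr = as.numeric(effects$recipient_origin == "nonnative"),
    groups = lapply(fac, as.integer),
    levels = lapply(fac, levels),
    A = A_list,
    logpd = pdist$logpd,
    pd = pdist$pd,
    pd_offset = pd_offset,
    basis = basis,
    year_basis = ybasis,
    effects = effects
  ), class = "meta_design")
}

#' Pointwise Student-t measurement-error log likelihood
#'
#' Log density of the observation model: a Student-t with `nu` degrees of
#' freedom, location `mu`, and scale `sqrt(sigma^2 + se^2)` combining the
#' estimated residual scale with the known sampling error of each effect
#' size. All arguments vectorized.
#'
#' @param y Observed effect size(s).
#' @param mu Linear-predictor value(s).
#' @param sigma Residual scale, `> 0`.
#' @param nu Degrees of freedom, `> 1`.
#' @param se Known sampling SE(s), default 0.
#' @return Log density value(s).
#' @export
log_likelihood_point <- function(y, mu, sigma, nu, se = 0) {
  stopifnot(all(sigma > 0), all(nu > 1), all(se >= 0))
  scale <- sqrt(sigma^2 + se^2)
  stats::dt((y - mu) / scale, df = nu, log = TRUE) - log(scale)
}

#' Default weakly-informative priors
#'
#' Intercepts and fixed effects normal(0, 1); every random-effect SD and the
#' residual scale half-Student-t(3, 0, 2.5); Student-t degrees of freedom
#' gamma(2, 0.1) truncated at 1.
#'
#' @return Named list of prior settings used by [fit_meta_model()].
#' @export
default_priors <- function() {
  list(b_sd = 1, tau_scale = 2.5, tau_df = 3,
       sigma_scale = 2.5, sigma_df = 3,
       nu_shape = 2, nu_rate = 0.1)
}

# Assemble the JAGS model string for a given design.
.jags_model_string <- function(design, priors, fix_nu = NULL,
                               fix_sigma = NULL) {
  g <- names(design$groups)
  iid <- setdiff(g, .species_side_tree)
  tree_f <- intersect(g, .species_side_tree)
  full <- design$model == "full"
  kw <- if (full) ncol(design$basis$wiggly) else 0L
  ykw <- if (!is.null(design$year_basis)) ncol(design$year_basis$wiggly) else 0L

  study_terms <- c("b0_study",
    sprintf("u_%s[idx_%s[i]]", intersect(.study_side, g),
            intersect(.study_side, g)))
  if (!is.null(design$year_basis)) {
    study_terms <- c(study_terms, "beta_year * Xyear[i]")
    if (ykw > 0) study_terms <- c(study_terms,
      "inprod(Xyw[i,], bw_year)")
  }
  sp_iid <- intersect(.species_side_iid, g)
  species_terms <- c("b0_species",
    sprintf("u_%s[idx_%s[i]]", sp_iid, sp_iid),
    sprintf("w_%s[idx_%s[i]]", tree_f, tree_f))
  if (full) {
    species_terms <- c(species_terms,
                       "beta_grass * NNg[i]", "beta_recipient * NNr[i]",
                       "beta_pd * Xpd[i]")
    if (kw > 0) species_terms <- c(species_terms, "inprod(Xw[i,], bw)")
  }

  lines <- c(
    "model {",
    "  for (i in 1:N) {",
    # Student-t as a scale mixture of normals: marginally
    # y_i ~ t_nu(mu_i, sqrt(sigma^2 + se_i^2)); the conditionally Gaussian
    # form lets the sampler block-update all location parameters.
    "    y[i] ~ dnorm(mu[i], lam[i] / (pow(sigma, 2) + se2[i]))",
    "    lam[i] ~ dgamma(nu / 2, nu / 2)",
    "    mu[i] <- study_comp[i] + species_comp[i]",
    paste0("    study_comp[i] <- ", paste(study_terms, collapse = " + ")),
    paste0("    species_comp[i] <- ", paste(species_terms, collapse = " + ")),
    "  }",
    sprintf("  b0_study ~ dnorm(0, %g)", 1 / priors$b_sd^2),
    sprintf("  b0_species ~ dnorm(0, %g)", 1 / priors$b_sd^2),
    "  b0_sum <- b0_study + b0_species")
  for (f in iid) {
    lines <- c(lines,
      sprintf("  for (j in 1:L_%s) { u_%s[j] ~ dnorm(0, pow(tau_%s, -2)) }",
              f, f, f),
      sprintf("  tau_%s ~ dt(0, %g, %d) T(0,)", f,
              1 / priors$tau_scale^2, priors$tau_df))
  }
  for (f in tree_f) {
    lines <- c(lines,
      sprintf("  w_%s[1:L_%s] ~ dmnorm(zero_%s, P_%s * pow(tau_%s, -2))",
              f, f, f, f, f),
      sprintf("  tau_%s ~ dt(0, %g, %d) T(0,)", f,
              1 / priors$tau_scale^2, priors$tau_df))
  }
  if (full) {
    lines <- c(lines,
      sprintf("  beta_grass ~ dnorm(0, %g)", 1 / priors$b_sd^2),
      sprintf("  beta_recipient ~ dnorm(0, %g)", 1 / priors$b_sd^2),
      sprintf("  beta_pd ~ dnorm(0, %g)", 1 / priors$b_sd^2))
    if (kw > 0) {
      lines <- c(lines,
        "  for (j in 1:KW) { bw[j] ~ dnorm(0, pow(tau_smooth, -2)) }",
        sprintf("  tau_smooth ~ dt(0, %g, %d) T(0,)",
                1 / priors$tau_scale^2, priors$tau_df))
    }
  }
  if (!is.null(design$year_basis)) {
    lines <- c(lines,
      sprintf("  beta_year ~ dnorm(0, %g)", 1 / priors$b_sd^2))
    if (ykw > 0) {
      lines <- c(lines,
        "  for (j in 1:KWY) { bw_year[j] ~ dnorm(0, pow(tau_smooth_year, -2)) }",
        sprintf("  tau_smooth_year ~ dt(0, %g, %d) T(0,)",
                1 / priors$tau_scale^2, priors$tau_df))
    }
  }
  lines <- c(lines,
    if (is.null(fix_sigma)) {
      sprintf("  sigma ~ dt(0, %g, %d) T(0,)",
              1 / priors$sigma_scale^2, priors$sigma_df)
    } else "  sigma <- sigma_fixed",
    if (is.null(fix_nu)) {
      sprintf("  nu ~ dgamma(%g, %g) T(1,)", priors$nu_shape, priors$nu_rate)
    } else "  nu <- nu_fixed",
    "}")
  paste(lines, collapse = "\n")
}

# JAGS data list for a design.
.jags_data <- function(design, jitter = 1e-8) {
  dat <- list(N = design$n, y = design$y, se2 = design$se^2)
  for (f in names(design$groups)) {
    dat[[paste0("idx_", f)]] <- design$groups[[f]]
    dat[[paste0("L_", f)]] <- length(design$levels[[f]])
  }
  for (f in names(design$A)) {
    Af <- design$A[[f]]
    diag(Af) <- diag(Af) + jitter
    dat[[paste0("P_", f)]] <- solve(Af)
    dat[[paste0("zero_", f)]] <- rep(0, nrow(Af))
  }
  if (design$model == "full") {
    dat$NNg <- design$nng
    dat$NNr <- design$nnr
    dat$Xpd <- design$basis$linear
    if (ncol(design$basis$wiggly) > 0) {
      dat$Xw <- design$basis$wiggly
      dat$KW <- ncol(design$basis$wiggly)
    }
  }
  if (!is.null(design$year_basis)) {
    dat$Xyear <- design$year_basis$linear
    if (ncol(design$year_basis$wiggly) > 0) {
      dat$Xyw <- design$year_basis$wiggly
      dat$KWY <- ncol(design$year_basis$wiggly)
    }
  }
  dat
}

#' Fit the hierarchical meta-analytic model by MCMC
#'
#' Samples the posterior of the two-component ("study" + "species")
#' non-linear hierarchical model with a Student-t measurement-error
#' likelihood: each observed delta LRR `y_i` is modelled as
#' `Student-t(nu, mu_i, sqrt(sigma^2 + se_i^2))` with
#' `mu_i = study_component_i + species_component_i`. Tree-linked species
#' effects are multivariate normal with covariance `tau^2 * A` (A the
#' phylogenetic correlation matrix). Only the *sum* of the two component
#' intercepts is identified by the data; each addend is identified through
#' its prior alone, so the fitted object always reports the sum (`b0_sum`)
#' alongside the addends.
#'
#' @param design A `"meta_design"` from [build_design()].
#' @param chains Number of chains, default 4.
#' @param iter Total iterations per chain (including warmup), default 2000.
#' @param warmup Warmup (adaptation + burn-in) iterations, default 1000.
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @param priors Prior settings, see [default_priors()].
#' @param thin Thinning interval, default 1.
#' @param quiet Suppress JAGS progress output, default TRUE.
#' @param monitor_mu Keep draws of every `mu_i` (needed for LOO/WAIC and
#'   residuals), default TRUE.
#' @param fix_nu,fix_sigma Optionally fix the Student-t degrees of freedom
#'   and/or the residual scale at a known constant instead of estimating
#'   them; used for validation against conjugate closed forms.
#' @return An object of class `"meta_fit"`: `draws` (matrix, one column per
#'   parameter), `chain` (chain index per row), `params`, `design`,
#'   `diagnostics` (R-hat, effective size, per-parameter), `mcmc` settings.
#' @export
fit_meta_model <- function(design, chains = 4, iter = 2000, warmup = 1000,
                           seed = 1, priors = default_priors(), thin = 1,
                           quiet = TRUE, monitor_mu = TRUE,
                           fix_nu = NULL, fix_sigma = NULL) {
  stopifnot(inherits(design, "meta_design"), iter > warmup, warmup >= 2)
  model_string <- .jags_model_string(design, priors, fix_nu = fix_nu,
                                     fix_sigma = fix_sigma)
  dat <- .jags_data(design)
  if (!is.null(fix_nu)) dat$nu_fixed <- fix_nu
  if (!is.null(fix_sigma)) dat$sigma_fixed <- fix_sigma

  monitors <- c("b0_study", "b0_species", "b0_sum", "sigma", "nu",
                paste0("tau_", names(design$groups), recycle0 = TRUE))
  if (design$model == "full") {
    monitors <- c(monitors, "beta_grass", "beta_recipient", "beta_pd")
    if (!is.null(dat$KW)) monitors <- c(monitors, "bw", "tau_smooth")
  }
  if (!is.null(design$year_basis)) {
    monitors <- c(monitors, "beta_year")
    if (!is.null(dat$KWY)) monitors <- c(monitors, "tau_smooth_year")
  }
  group_monitors <- c(paste0("u_", setdiff(names(design$groups),
                                           .species_side_tree),
                             recycle0 = TRUE),
                      paste0("w_", intersect(names(design$groups),
                                             .species_side_tree),
                             recycle0 = TRUE))
  monitors <- c(monitors, group_monitors)
  if (monitor_mu) monitors <- c(monitors, "mu")

  # start every variance component away from zero: the conditional Gibbs
  # update cannot escape a tau that collapses to 0 during adaptation
  group_names <- names(design$groups)
  if (is.null(group_names)) group_names <- character(0)
  tau_inits <- stats::setNames(
    as.list(rep(0.2, length(group_names))),
    paste0("tau_", group_names, recycle0 = TRUE))
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- c(list(.RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = as.integer(seed + ch)),
             tau_inits)
    if (is.null(fix_sigma)) ini$sigma <- 0.2
    if (is.null(fix_nu)) ini$nu <- 5
    if (design$model == "full" && !is.null(dat$KW)) ini$tau_smooth <- 0.2
    if (!is.null(design$year_basis) && !is.null(dat$KWY)) {
      ini$tau_smooth_year <- 0.2
    }
    ini
  })
  n_adapt <- min(500, max(100, warmup %/% 2))
  n_burn <- max(warmup - n_adapt, 0)
  run <- function() {
    rjags::load.module("glm", quiet = TRUE)
    jm <- rjags::jags.model(textConnection(model_string), data = dat,
                            inits = inits, n.chains = chains,
                            n.adapt = n_adapt, quiet = quiet)
    if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, variable.names = monitors,
                        n.iter = iter - warmup, thin = thin,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  draws <- do.call(rbind, lapply(samples, as.matrix))
  per_chain <- nrow(samples[[1]])
  chain_id <- rep(seq_len(chains), each = per_chain)

  scalar_pars <- intersect(
    c("b0_study", "b0_species", "b0_sum",
      if (is.null(fix_sigma)) "sigma", if (is.null(fix_nu)) "nu",
      "beta_grass", "beta_recipient", "beta_pd", "beta_year",
      "tau_smooth", "tau_smooth_year",
      paste0("tau_", names(design$groups), recycle0 = TRUE)),
    colnames(draws))
  diagnostics <- .mcmc_diagnostics(samples, scalar_pars)

  structure(list(draws = draws, chain = chain_id, params = colnames(draws),
                 design = design, model = design$model,
                 diagnostics = diagnostics,
                 mcmc = list(chains = chains, iter = iter, warmup = warmup,
                             thin = thin, seed = seed),
                 priors = priors),
            class = "meta_fit")
}

.mcmc_diagnostics <- function(samples, pars) {
  sub <- samples[, pars, drop = FALSE]
  rhat <- rep(NA_real_, length(pars))
  names(rhat) <- pars
  if (coda::nchain(samples) >= 2) {
    gd <- try(coda::gelman.diag(sub, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1]
  }
  ess <- coda::effectiveSize(sub)
  bad <- names(rhat)[!is.na(rhat) & rhat > 1.05]
  if (length(bad) > 0) {
    warning("R-hat > 1.05 for: ", paste(bad, collapse = ", "),
            " - consider longer chains")
  }
  list(rhat = rhat, ess = ess, flagged = bad)
}

#' Extract a named parameter's posterior draws
#'
#' @param fit A `"meta_fit"`.
#' @param pars Parameter names (columns of the draws matrix).
#' @return Matrix of draws (rows = iterations, columns = `pars`).
#' @export
posterior_draws <- function(fit, pars) {
  stopifnot(inherits(fit, "meta_fit"))
  missing <- setdiff(pars, fit$params)
  if (length(missing) > 0) {
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  }
  fit$draws[, pars, drop = FALSE]
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Hierarchical allelopathy meta-analysis fit (", x$model,
      " model)\n", sep = "")
  cat(sprintf("  %d effect sizes, %d chains x %d iterations (%d warmup)\n",
              x$design$n, x$mcmc$chains, x$mcmc$iter, x$mcmc$warmup))
  key <- intersect(c("b0_study", "b0_species", "b0_sum", "beta_grass",
                     "beta_recipient", "beta_pd", "sigma", "nu"), x$params)
  sm <- t(apply(x$draws[, key, drop = FALSE], 2, function(d) {
    c(mean = mean(d), stats::quantile(d, c(0.025, 0.975)))
  }))
  print(round(sm, 3))
  if (length(x$diagnostics$flagged) > 0) {
    cat("  warning: R-hat > 1.05 for",
        paste(x$diagnostics$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
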