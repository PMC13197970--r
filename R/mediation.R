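#' Sampler and prior settings for the Bayesian mediation models
#'
#' Both linked models are Bernoulli regressions with logit link: the mediator
#' model (30-day first-contact PCP follow-up on hospital type and covariates)
#' and the outcome model (90-day readmission on hospital type, PCP follow-up,
#' their interaction, and covariates), each with facility random intercepts.
#' Coefficients get normal(0, 2.5) priors on standardized covariates
#' (intercepts normal(0, 5)); the facility intercept SD gets a half-normal(1)
#' prior. Because the two likelihoods share no parameters, their joint
#' posterior factorizes and they are sampled as two Gibbs chains.
#'
#' @param chains Number of MCMC chains.
#' @param warmup,draws Warmup and retained iterations per chain.
#' @param prior_sd Prior SD for standardized coefficients.
#' @param prior_sd_intercept Prior SD for the intercept.
#' @param sigma_scale Half-normal scale for the facility intercept SD.
#' @param interaction Include the hospital-type-by-PCP interaction.
#' @param covariates Covariates entering both models.
#' @param rhat_max,ess_min Convergence thresholds; exceeding them raises a
#'   warning, not an error.
#' @return A list of class `posticu_mspec`.
#' @export
mediation_spec <- function(chains = 4, warmup = 1000, draws = 1000,
                           prior_sd = 2.5, prior_sd_intercept = 5,
                           sigma_scale = 1, interaction = TRUE,
                           covariates = default_covariates(),
                           rhat_max = 1.01, ess_min = 400) {
  structure(list(chains = chains, warmup = warmup, draws = draws,
                 prior_sd = prior_sd, prior_sd_intercept = prior_sd_intercept,
                 sigma_scale = sigma_scale, interaction = interaction,
                 covariates = covariates, rhat_max = rhat_max,
                 ess_min = ess_min),
            class = "posticu_mspec")
}

# standardized (center/scale continuous, dummy-code categorical) design for
# the Bayesian models; returns the matrix without exposure/mediator columns
bayes_design <- function(patients, covariates) {
  fml <- as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- model.matrix(fml, data = patients)[, -1, drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  sweep(sweep(X, 2, ctr), 2, scl, "/")
}

# split-half potential scale reduction factor
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via initial-positive-sequence autocorrelation
ess_basic <- function(draws_by_chain) {
  per_chain <- vapply(draws_by_chain, function(x) {
    n <- length(x)
    if (sd(x) < 1e-12) return(n)
    rho <- stats::acf(x, lag.max = min(200, n - 2), plot = FALSE)$acf[-1]
    s <- 0
    for (l in seq(1, length(rho) - 1, by = 2)) {
      pair <- rho[l] + rho[l + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }, numeric(1))
  sum(per_chain)
}

# Polya-Gamma Gibbs fit of one Bernoulli-logit model with facility intercepts
fit_bayes_logit <- function(y, X, fac, spec, seed) {
  fac_f <- factor(fac)
  n_fac <- nlevels(fac_f)
  fac_i <- as.integer(fac_f) - 1L
  p <- ncol(X)
  prior_sd <- c(spec$prior_sd_intercept, rep(spec$prior_sd, p - 1))
  n_iter <- spec$warmup + spec$draws
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(seed * 1000L + ch)
    init <- rnorm(p, 0, 0.1)
    chains[[ch]] <- pg_gibbs_cpp(X, as.integer(y), fac_i, n_fac, prior_sd,
                                 spec$sigma_scale, n_iter, spec$warmup, init)
  }
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- colnames(X)
  u <- do.call(rbind, lapply(chains, `[[`, "u"))
  colnames(u) <- levels(fac_f)
  sigma <- unlist(lapply(chains, `[[`, "sigma"))

  par_chains <- function(j) lapply(chains, function(c) c$beta[, j])
  diag <- tibble(
    parameter = colnames(X),
    rhat = vapply(seq_len(p), function(j) split_rhat(par_chains(j)), numeric(1)),
    ess = vapply(seq_len(p), function(j) ess_basic(par_chains(j)), numeric(1))
  )
  if (any(diag$rhat > spec$rhat_max, na.rm = TRUE) ||
      any(diag$ess < spec$ess_min, na.rm = TRUE))
    warning("MCMC convergence diagnostics outside thresholds (see $diagnostics)",
            call. = FALSE)
  structure(list(beta = beta, u = u, sigma = sigma, diagnostics = diag,
                 fac_levels = levels(fac_f), n = length(y),
                 observed_rate = mean(y)),
            class = "posticu_blogit")
}

#' Fit the mediator model (30-day PCP first-contact follow-up)
#'
#' @param patients Patient tibble.
#' @param mediator Logical/0-1 vector: PCP visit as strictly first contact
#'   within 30 days (see [patient_outcomes()]).
#' @param spec A [mediation_spec()].
#' @param seed Seed (chains use `seed * 1000 + chain`).
#' @return A `posticu_blogit` posterior.
#' @export
fit_mediator_model <- function(patients, mediator, spec = mediation_spec(),
                               seed = 1L) {
  Z <- bayes_design(patients, spec$covariates)
  X <- cbind(`(Intercept)` = 1, va = patients$hospital_type, Z)
  fit_bayes_logit(as.integer(mediator), X, patients$facility_id, spec, seed)
}

#' Fit the outcome model (90-day readmission)
#'
#' Includes hospital type, the mediator, their interaction (unless disabled in
#' the sampler settings) and covariates, with facility random intercepts.
#'
#' @param patients Patient tibble.
#' @param outcome Logical/0-1 readmission-by-90-days indicator.
#' @param mediator Logical/0-1 mediator vector.
#' @inheritParams fit_mediator_model
#' @return A `posticu_blogit` posterior.
#' @export
fit_outcome_model <- function(patients, outcome, mediator,
                              spec = mediation_spec(), seed = 2L) {
  Z <- bayes_design(patients, spec$covariates)
  A <- patients$hospital_type
  M <- as.integer(mediator)
  X <- if (spec$interaction) {
    cbind(`(Intercept)` = 1, va = A, pcp = M, va_pcp = A * M, Z)
  } else {
    cbind(`(Intercept)` = 1, va = A, pcp = M, Z)
  }
  fit_bayes_logit(as.integer(outcome), X, patients$facility_id, spec, seed)
}

#' Counterfactual natural direct and indirect effects
#'
#' Applies posterior draws to the four counterfactual exposure-mediator
#' scenarios. For draw s and patient i, `m_i(a')` is the mediator probability
#' with exposure set to a', `y_i(a, m)` the outcome probability with exposure
#' a and mediator m (each using the patient's own facility intercept draw),
#' and `p(a, a') = mean_i[m_i(a') y_i(a,1) + (1 - m_i(a')) y_i(a,0)]`.
#' Reported effects (percentage points): pure natural direct effect
#' PNDE = p(1,0) - p(0,0); total natural direct effect TNDE = p(1,1) - p(0,1);
#' community- and VA-indexed natural indirect effects
#' NIE_CCN = p(0,1) - p(0,0), NIE_VA = p(1,1) - p(1,0); total effect
#' TE = p(1,1) - p(0,0); mediator-setting contrasts Delta_a (risk change from
#' setting M=1 vs M=0 under exposure a) and their interaction contrast
#' Delta_0 - Delta_1. The decompositions TE = PNDE + NIE_VA and
#' TE = TNDE + NIE_CCN hold exactly per draw.
#'
#' @param mediator_fit,outcome_fit `posticu_blogit` posteriors with matched
#'   draw counts.
#' @param patients Patient tibble the models were fit on.
#' @param spec The [mediation_spec()] used.
#' @return An object of class `posticu_mediation`: `effects` summary tibble,
#'   per-draw effect matrix, diagnostics and posterior-predictive checks.
#' @export
natural_effects <- function(mediator_fit, outcome_fit, patients,
                            spec = mediation_spec()) {
  S <- nrow(mediator_fit$beta)
  if (S != nrow(outcome_fit$beta))
    stop("mediator and outcome posteriors must have matched draw counts",
         call. = FALSE)
  Z <- bayes_design(patients, spec$covariates)
  fac_m <- match(as.character(patients$facility_id), mediator_fit$fac_levels)
  fac_y <- match(as.character(patients$facility_id), outcome_fit$fac_levels)

  bm <- mediator_fit$beta
  by <- outcome_fit$beta
  zcols_m <- setdiff(colnames(bm), c("(Intercept)", "va"))
  zcols_y <- setdiff(colnames(by), c("(Intercept)", "va", "pcp", "va_pcp"))
  has_int <- "va_pcp" %in% colnames(by)

  eff_names <- c("pnde", "tnde", "nie_ccn", "nie_va", "te",
                 "delta_ccn", "delta_va", "interaction_contrast")
  draws <- matrix(NA_real_, S, length(eff_names),
                  dimnames = list(NULL, eff_names))
  ppc_m <- numeric(S); ppc_y <- numeric(S)

  chunk <- 100L
  for (lo in seq(1L, S, by = chunk)) {
    hi <- min(lo + chunk - 1L, S)
    idx <- lo:hi
    # n x s linear predictor bases with exposure/mediator at 0
    base_m <- Z[, zcols_m, drop = FALSE] %*% t(bm[idx, zcols_m, drop = FALSE])
    base_m <- base_m + rep(bm[idx, "(Intercept)"], each = nrow(Z)) +
      t(mediator_fit$u[idx, , drop = FALSE][, fac_m, drop = FALSE])
    base_y <- Z[, zcols_y, drop = FALSE] %*% t(by[idx, zcols_y, drop = FALSE])
    base_y <- base_y + rep(by[idx, "(Intercept)"], each = nrow(Z)) +
      t(outcome_fit$u[idx, , drop = FALSE][, fac_y, drop = FALSE])

    gA <- rep(bm[idx, "va"], each = nrow(Z))
    tA <- rep(by[idx, "va"], each = nrow(Z))
    tM <- rep(by[idx, "pcp"], each = nrow(Z))
    tAM <- if (has_int) rep(by[idx, "va_pcp"], each = nrow(Z)) else 0

    pm0 <- plogis(base_m); pm1 <- plogis(base_m + gA)
    y00 <- plogis(base_y); y01 <- plogis(base_y + tM)
    y10 <- plogis(base_y + tA); y11 <- plogis(base_y + tA + tM + tAM)

    # mixture written as y(a,0) + m * (y(a,1) - y(a,0)) so that structural
    # zeros of the mediator pathway propagate exactly
    p00 <- colMeans(y00 + pm0 * (y01 - y00))
    p01 <- colMeans(y00 + pm1 * (y01 - y00))
    p10 <- colMeans(y10 + pm0 * (y11 - y10))
    p11 <- colMeans(y10 + pm1 * (y11 - y10))
    d0 <- colMeans(y01 - y00)
    d1 <- colMeans(y11 - y10)

    draws[idx, ] <- 100 * cbind(p10 - p00, p11 - p01, p01 - p00, p11 - p10,
                                p11 - p00, d0, d1, d0 - d1)
    # posterior predictive mean event rates at observed exposure/mediator
    A <- patients$hospital_type
    Mv <- attr(outcome_fit, "mediator_observed")
    ppc_m[idx] <- colMeans(plogis(base_m + outer(A, bm[idx, "va"])))
    if (!is.null(Mv)) {
      eta_obs <- base_y + outer(A, by[idx, "va"]) + outer(Mv, by[idx, "pcp"]) +
        if (has_int) outer(A * Mv, by[idx, "va_pcp"]) else 0
      ppc_y[idx] <- colMeans(plogis(eta_obs))
    }
  }

  qs <- function(v) c(mean = mean(v), lo = unname(quantile(v, 0.025)),
                      hi = unname(quantile(v, 0.975)))
  summ <- as_tibble(t(apply(draws, 2, qs)), rownames = "effect")
  structure(list(
    effects = summ, draws = draws,
    diagnostics = bind_rows(mediator = mediator_fit$diagnostics,
                            outcome = outcome_fit$diagnostics, .id = "model"),
    ppc = tibble(model = c("mediator", "outcome"),
                 posterior_mean_rate = c(mean(ppc_m),
                                         if (any(ppc_y != 0)) mean(ppc_y) else NA_real_),
                 observed_rate = c(mediator_fit$observed_rate,
                                   outcome_fit$observed_rate))
  ), class = "posticu_mediation")
}

#' One-call Bayesian mediation analysis
#'
#' Derives the mediator (30-day PCP first contact) and outcome (90-day
#' readmission) from the event table, fits both models and returns the
#' natural-effect decomposition.
#'
#' @param events,patients Cohort tibbles.
#' @param spec A [mediation_spec()].
#' @param seed Seed.
#' @return A `posticu_mediation` object.
#' @export
fit_mediation <- function(events, patients, spec = mediation_spec(), seed = 1L) {
  out <- patient_outcomes(events, patients)
  med <- fit_mediator_model(patients, out$pcp30_first, spec, seed)
  ofit <- fit_outcome_model(patients, out$readmit90, out$pcp30_first, spec,
                            seed + 1L)
  attr(ofit, "mediator_observed") <- as.numeric(out$pcp30_first)
  natural_effects(med, ofit, patients, spec)
}

#' Mediation sensitivity analyses
#'
#' Re-runs the natural-effect decomposition under three variants: no
#' hospital-type-by-PCP interaction, excluding ICU/hospital length of stay
#' from the covariates, and widened coefficient priors (normal(0, 10)); and
#' reports the resulting effect shifts against the main analysis.
#'
#' @param events,patients Cohort tibbles.
#' @param spec Baseline [mediation_spec()].
#' @param seed Seed.
#' @return A tibble of effect means per analysis variant.
#' @export
sensitivity_suite <- function(events, patients, spec = mediation_spec(),
                              seed = 1L) {
  variants <- list(
    main = spec,
    no_interaction = modifyList(spec, list(interaction = FALSE)),
    drop_los = modifyList(spec, list(covariates = default_covariates(FALSE))),
    wide_priors = modifyList(spec, list(prior_sd = 10, prior_sd_intercept = 10))
  )
  res <- imap(variants, function(sp, nm) {
    class(sp) <- "posticu_mspec"
    fit <- fit_mediation(events, patients, sp, seed)
    mutate(fit$effects, variant = nm)
  })
  list_rbind(res) |> relocate("variant")
}
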