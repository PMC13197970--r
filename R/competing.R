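#' Default adjustment covariate set
#'
#' The discharge covariates the adjusted models condition on: demographics,
#' social context, comorbidity and severity proxies, and lengths of stay. The
#' LOS variables can be dropped (`include_los = FALSE`) as a sensitivity
#' analysis, since post-ICU lengths of stay may lie on the causal pathway.
#'
#' @param include_los Include ICU and hospital length of stay.
#' @return Character vector of covariate names.
#' @export
default_covariates <- function(include_los = TRUE) {
  base <- c("age", "sex", "race", "ethnicity", "marital", "rural",
            "adi", "cci", "drg_weight")
  if (include_los) c(base, "icu_los", "hosp_los") else base
}

#' Prepare a competing-risk dataset for one outcome
#'
#' Codes follow-up time and status per patient under outcome-specific
#' competing events. `pcp_first` uses the first-contact rule: the event is a
#' PCP visit as the strictly first post-discharge contact; a first contact
#' that is an ED visit or readmission, or death before any contact, is the
#' competing event. For `ed` and `readmission` the event is the first
#' occurrence of that type and prior death is the competing event. For
#' `death` there is no competing event. Everyone else is administratively
#' censored at the horizon.
#'
#' @param events,patients Cohort tibbles.
#' @param outcome One of `"pcp_first"`, `"ed"`, `"readmission"`, `"death"`.
#' @param horizon Days of follow-up.
#' @return The patient tibble augmented with `time` (0 < time <= horizon) and
#'   `status` (0 censored, 1 event, 2 competing).
#' @export
prepare_competing_data <- function(events, patients, outcome, horizon = 90) {
  outcome <- match.arg(outcome, c("pcp_first", "ed", "readmission", "death"))
  ids <- patients$patient_id
  ev <- filter(events, .data$day >= 1, .data$day <= horizon)
  fd <- function(types) {
    out <- rep(NA_integer_, length(ids))
    x <- filter(ev, .data$event_type %in% types)
    if (nrow(x) == 0) return(out)
    x <- summarise(group_by(x, .data$patient_id), d = min(.data$day),
                   .groups = "drop")
    out[match(x$patient_id, ids)] <- x$d
    out
  }
  death <- fd("DEATH")
  time <- rep(as.integer(horizon), length(ids))
  status <- rep(0L, length(ids))
  if (outcome == "death") {
    has <- !is.na(death)
    time[has] <- death[has]
    status[has] <- 1L
  } else if (outcome == "pcp_first") {
    pcp <- fd("PCP")
    acute <- fd(c("ED", "READMIT"))
    fc <- pmin(pcp, acute, death, na.rm = TRUE)
    has <- is.finite(fc) & !is.na(fc)
    is_ev <- has & !is.na(pcp) & pcp == fc &
      (is.na(acute) | pcp < acute) & (is.na(death) | pcp < death)
    time[has] <- fc[has]
    status[has] <- ifelse(is_ev[has], 1L, 2L)
  } else {
    type <- if (outcome == "ed") "ED" else "READMIT"
    first <- fd(type)
    is_ev <- !is.na(first) & (is.na(death) | first <= death)
    is_comp <- !is.na(death) & (is.na(first) | death < first)
    time[is_ev] <- first[is_ev]; status[is_ev] <- 1L
    time[is_comp] <- death[is_comp]; status[is_comp] <- 2L
  }
  bind_cols(patients, tibble(time = as.numeric(time), status = status))
}

#' Kaplan-Meier of the censoring distribution
#'
#' Estimates the censoring survivor curve G(t) by treating censoring as the
#' event (events and competing events are censored observations for G); the
#' inverse-probability-of-censoring ingredient of Fine-Gray estimation.
#'
#' @param data Output of [prepare_competing_data()].
#' @return A list of class `posticu_km` with step-function knots `time`,
#'   `surv`, and an evaluator usable through [km_left()].
#' @export
censoring_km <- function(data) {
  fit <- survival::survfit(survival::Surv(data$time, data$status == 0) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "posticu_km")
}

#' Left-limit evaluation of a censoring survivor curve
#'
#' @param km A [censoring_km()] object.
#' @param t Times at which to evaluate G(t-).
#' @return Numeric vector of G(t-) values (1 before the first knot).
#' @export
km_left <- function(km, t) {
  idx <- findInterval(t - 1e-9, km$time)
  c(1, km$surv)[idx + 1L]
}

fg_design <- function(data, covariates, exposure) {
  vars <- c(exposure, covariates)
  fml <- as.formula(paste("~", paste(vars, collapse = " + ")))
  mf <- stats::model.frame(fml, data = data, na.action = stats::na.fail)
  X <- model.matrix(fml, mf)[, -1, drop = FALSE]
  list(X = X, terms = stats::terms(mf), xlev = stats::.getXlevels(stats::terms(mf), mf))
}

#' Fit a Fine-Gray subdistribution-hazard model
#'
#' Maximizes the weighted Fine-Gray partial likelihood: subjects with a
#' competing event remain in the risk set after their event time with
#' inverse-probability-of-censoring weight `G(t-) / G(T_i-)`, where G is the
#' censoring Kaplan-Meier. Ties are handled by Breslow's method. Newton-
#' Raphson with step-halving iterates until the gradient max-norm falls below
#' `tol`; the log-likelihood is non-decreasing across accepted steps. Standard
#' errors are model-based (inverse information) and facility-clustered
#' sandwich. The Breslow baseline cumulative subdistribution hazard is
#' returned so cumulative incidence can be predicted.
#'
#' @param data Output of [prepare_competing_data()] (must contain the
#'   exposure, covariates and `facility_id`).
#' @param covariates Adjustment covariates; see [default_covariates()].
#' @param exposure Name of the exposure column (kept first in the design).
#' @param cluster Column for the sandwich clustering (NULL for independence).
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return An object of class `posticu_fg`.
#' @export
fine_gray_fit <- function(data, covariates = default_covariates(),
                          exposure = "hospital_type",
                          cluster = "facility_id",
                          tol = 1e-8, max_iter = 50) {
  if (!any(data$status == 1L)) stop("no events of interest", call. = FALSE)
  km <- censoring_km(data)
  des <- fg_design(data, covariates, exposure)
  X <- des$X
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) stop("collinear covariates in the design", call. = FALSE)

  ord <- order(data$time)
  tt <- data$time[ord]
  ss <- data$status[ord]
  Xo <- Xc[ord, , drop = FALSE]
  ginv <- 1 / km_left(km, tt)
  tev <- unique(tt[ss == 1L])
  gtev <- km_left(km, tev)

  p <- ncol(Xo)
  beta <- rep(0, p)
  q0 <- fg_quantities_cpp(tt, ss, Xo, beta, ginv, tev, gtev)
  nll <- q0$nll; grad <- as.numeric(q0$grad); hess <- q0$hess
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    step <- solve(hess, grad)
    lambda <- 1
    repeat {
      bnew <- beta - lambda * step
      qn <- fg_quantities_cpp(tt, ss, Xo, bnew, ginv, tev, gtev)
      if (qn$nll <= nll + 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    no_progress <- max(abs(lambda * step)) < 1e-10
    beta <- as.numeric(bnew); nll <- qn$nll
    grad <- as.numeric(qn$grad); hess <- qn$hess
    if (no_progress) { # at the numerical floor of the likelihood surface
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(grad)) < tol) converged <- TRUE
  if (!converged)
    warning("Fine-Gray Newton-Raphson did not converge; returning last iterate",
            call. = FALSE)

  qf <- fg_quantities_cpp(tt, ss, Xo, beta, ginv, tev, gtev, resid = TRUE)
  vcov_model <- solve(qf$hess)
  U <- qf$resid
  vcov_cluster <- NULL
  if (!is.null(cluster)) {
    cl <- data[[cluster]][ord]
    Ucl <- rowsum(U, cl)
    meat <- crossprod(Ucl)
    vcov_cluster <- vcov_model %*% meat %*% vcov_model
  }
  names(beta) <- colnames(X)
  baseline <- tibble(time = tev, haz = qf$dk / qf$s0,
                     cumhaz = cumsum(qf$dk / qf$s0))
  structure(list(
    coef = beta, vcov_model = vcov_model, vcov_cluster = vcov_cluster,
    baseline = baseline, censoring = km, centers = centers,
    terms = des$terms, xlev = des$xlev, exposure = exposure,
    covariates = covariates, cluster = cluster,
    n = nrow(data), n_event = sum(data$status == 1L),
    loglik = -nll, iter = iter, converged = converged,
    data = data
  ), class = "posticu_fg")
}

#' Fit a cause-specific Cox model
#'
#' Competing events are treated as censored; Breslow tie handling and
#' facility-clustered robust standard errors, via the survival package.
#'
#' @inheritParams fine_gray_fit
#' @return A `coxph` fit.
#' @export
cause_specific_cox_fit <- function(data, covariates = default_covariates(),
                                   exposure = "hospital_type",
                                   cluster = "facility_id") {
  vars <- c(exposure, covariates)
  fml <- as.formula(paste("survival::Surv(time, status == 1) ~",
                          paste(vars, collapse = " + "),
                          if (!is.null(cluster)) paste0("+ cluster(", cluster, ")")))
  survival::coxph(fml, data = data, ties = "breslow")
}

#' Predict cumulative incidence from a Fine-Gray fit
#'
#' `F1(t | x) = 1 - exp(-H10(t) * exp(x'beta))` with the Breslow baseline
#' cumulative subdistribution hazard; non-decreasing in t and bounded in
#' \[0, 1\].
#'
#' @param fit A `posticu_fg` object.
#' @param newdata Tibble of covariate rows.
#' @param t Evaluation times (vector allowed).
#' @return A matrix (rows = newdata, columns = t) of probabilities, dropped to
#'   a vector for scalar `t`.
#' @export
predict_cif <- function(fit, newdata, t) {
  mf <- stats::model.frame(stats::delete.response(fit$terms), data = newdata,
                           xlev = fit$xlev, na.action = stats::na.fail)
  X <- model.matrix(stats::delete.response(fit$terms), mf)[, -1, drop = FALSE]
  eta <- as.numeric(sweep(X, 2, fit$centers) %*% fit$coef)
  H <- vapply(t, function(tt) {
    idx <- findInterval(tt, fit$baseline$time)
    if (idx == 0) 0 else fit$baseline$cumhaz[idx]
  }, numeric(1))
  out <- 1 - exp(-outer(exp(eta), H))
  if (length(t) == 1L) drop(out) else out
}

#' Marginally standardized absolute risks, risk differences and ratios
#'
#' g-computation over the study population: each patient's cumulative
#' incidence is predicted under exposure set to VA and to community, and
#' averaged; reported as percentages with percentile bootstrap confidence
#' intervals (patient resampling by default, facility cluster bootstrap as an
#' option). The model is refit on every bootstrap resample.
#'
#' @param fit A `posticu_fg` fit (carries its data and design).
#' @param t_set Horizons in days.
#' @param n_boot Bootstrap replicates (at least 2).
#' @param seed Seed for resampling.
#' @param cluster_boot Resample facilities instead of patients.
#' @return A tibble of class `posticu_stdrisks`: per horizon, `risk_va`,
#'   `risk_ccn` (in percent), `rd` (percentage points), `rr`, and 95% CIs.
#' @export
marginal_standardization <- function(fit, t_set = c(30, 90), n_boot = 200,
                                     seed = 1L, cluster_boot = FALSE) {
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  data <- fit$data
  point <- std_risks_once(fit, data, t_set)
  set.seed(seed)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    db <- if (cluster_boot) {
      fids <- unique(data$facility_id)
      take <- sample(fids, length(fids), replace = TRUE)
      bind_rows(lapply(take, function(f) filter(data, .data$facility_id == f)))
    } else {
      slice_sample(data, n = nrow(data), replace = TRUE)
    }
    fb <- try(fine_gray_fit(db, covariates = fit$covariates,
                            exposure = fit$exposure, cluster = NULL),
              silent = TRUE)
    boots[[b]] <- if (inherits(fb, "try-error")) NULL else std_risks_once(fb, db, t_set)
  }
  bt <- bind_rows(boots)
  ci <- bt |>
    group_by(.data$t) |>
    summarise(across(c("risk_va", "risk_ccn", "rd", "rr"),
                     list(lo = ~ quantile(.x, 0.025, na.rm = TRUE),
                          hi = ~ quantile(.x, 0.975, na.rm = TRUE))),
              .groups = "drop")
  out <- left_join(point, ci, by = "t")
  class(out) <- c("posticu_stdrisks", class(out))
  out
}

std_risks_once <- function(fit, data, t_set) {
  d_va <- mutate(data, "{fit$exposure}" := 1L)
  d_ccn <- mutate(data, "{fit$exposure}" := 0L)
  cif_va <- predict_cif(fit, d_va, t_set)
  cif_ccn <- predict_cif(fit, d_ccn, t_set)
  if (length(t_set) == 1L) {
    cif_va <- matrix(cif_va, ncol = 1)
    cif_ccn <- matrix(cif_ccn, ncol = 1)
  }
  tibble(t = t_set,
         risk_va = 100 * colMeans(cif_va),
         risk_ccn = 100 * colMeans(cif_ccn)) |>
    mutate(rd = .data$risk_va - .data$risk_ccn,
           rr = .data$risk_va / .data$risk_ccn)
}

#' Unadjusted cumulative outcome rates by hospital type
#'
#' Raw 30- and 90-day proportions per outcome and hospital type (first-contact
#' PCP follow-up, any ED visit, any readmission, death), plus the share of
#' readmissions flagged as ambulatory care-sensitive.
#'
#' @param events,patients Cohort tibbles.
#' @return A tibble with one row per outcome, horizon and hospital type, and
#'   an `acsc_share` attribute-free extra row set (`outcome == "acsc_share"`)
#'   giving the ACSC proportion among readmissions.
#' @export
unadjusted_rates <- function(events, patients) {
  ids <- patients$patient_id
  grp <- ifelse(patients$hospital_type == 1, "VA", "CCN")
  rates <- list()
  for (h in c(30, 90)) {
    out30 <- patient_outcomes(events, patients, horizon = h)
    pcp_first <- prepare_competing_data(events, patients, "pcp_first", h)
    tab <- tibble(
      hospital_type = grp,
      pcp_first = pcp_first$status == 1L,
      ed = out30$ed90, readmission = out30$readmit90, death = out30$death90
    ) |>
      group_by(.data$hospital_type) |>
      summarise(across(c("pcp_first", "ed", "readmission", "death"),
                       ~ 100 * mean(.x)), .groups = "drop") |>
      pivot_longer(-"hospital_type", names_to = "outcome", values_to = "rate") |>
      mutate(horizon = h)
    rates[[as.character(h)]] <- tab
  }
  re <- filter(events, .data$event_type == "READMIT", .data$day <= 90)
  re$grp <- grp[match(re$patient_id, ids)]
  acsc <- re |>
    group_by(hospital_type = .data$grp) |>
    summarise(rate = 100 * mean(.data$acsc_flag), .groups = "drop") |>
    mutate(outcome = "acsc_share", horizon = 90)
  bind_rows(rates) |> bind_rows(acsc) |>
    select("outcome", "horizon", "hospital_type", "rate") |>
    arrange(.data$outcome, .data$horizon, .data$hospital_type)
}

#' Simulate from a Fine-Gray subdistribution model
#'
#' Direct simulation under the subdistribution-hazard model with a binary
#' covariate: `P(cause 1 | x) = 1 - (1 - p)^exp(x b)` with unit-exponential
#' mixture timing for cause 1, exponential cause-2 times, and administrative
#' censoring, so the cause-1 subdistribution hazard ratio for x is exactly
#' `exp(b)`. Used for parameter-recovery checks.
#'
#' @param n Sample size.
#' @param beta True log subdistribution hazard ratio.
#' @param p Baseline cause-1 mass `P(cause 1 | x = 0)`.
#' @param time_scale Multiplies the latent times onto a day-like scale.
#' @param admin_censor Administrative censoring time (after scaling).
#' @param censor_rate Optional rate of an additional independent exponential
#'   censoring time (on the latent scale); 0 for administrative only.
#' @param seed Seed.
#' @return A tibble with `time`, `status`, `x`, `facility_id`.
#' @export
sim_finegray_data <- function(n, beta = log(1.2), p = 0.35, time_scale = 25,
                              admin_censor = 90, censor_rate = 0, seed = 1L) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  eb <- exp(beta * x)
  p1 <- 1 - (1 - p)^eb
  cause1 <- rbinom(n, 1, p1) == 1L
  t <- numeric(n)
  u <- runif(n)
  # invert F1(t|x)/P1(x) = u
  inner <- (1 - u[cause1] * p1[cause1])^(1 / eb[cause1])
  t[cause1] <- -log(1 - (1 - inner) / p)
  t[!cause1] <- stats::rexp(sum(!cause1), rate = 0.8)
  t <- t * time_scale
  status <- ifelse(cause1, 1L, 2L)
  ctime <- rep(admin_censor, n)
  if (censor_rate > 0)
    ctime <- pmin(ctime, stats::rexp(n, censor_rate) * time_scale)
  cens <- t > ctime
  t[cens] <- ctime[cens]
  status[cens] <- 0L
  tibble(time = t, status = status, x = x,
         facility_id = sprintf("F%02d", sample.int(20, n, TRUE)))
}
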