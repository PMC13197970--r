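#' Configuration for the synthetic post-ICU cohort generator
#'
#' Builds the full parameter set driving [generate_cohort()]. Defaults emulate
#' the published cohort this package is designed around: a predominantly male
#' veteran population (median age 70), about 36.9% discharged from VA medical
#' centers, five latent trajectory archetypes with marginal shares of roughly
#' 5.9 / 5.0 / 7.8 / 7.9 / 73.4 percent, and an embedded mediation structure in
#' which VA discharge raises the probability of primary-care (PCP) first-contact
#' follow-up within 30 days, and that follow-up in turn lowers the odds of
#' 90-day readmission (more strongly for community-discharged patients).
#'
#' The generator has two layers. The mediation layer draws, per patient,
#' three linked Bernoulli outcomes on the logit scale with facility random
#' intercepts: the mediator M (PCP as first post-discharge contact within 30
#' days), the outcome Y (any readmission within 90 days), and death within 90
#' days. The trajectory layer then draws a latent class (delta, omicron, gamma,
#' epsilon, sigma) from a multinomial logit on covariates, hospital type and the
#' realized (death, Y, M) indicators, and the class shapes event timing and
#' counts: emergency-department (ED) visits, repeat readmission episodes, death
#' timing and additional PCP visits. Event placement always honours the drawn
#' M, Y and death indicators, so the downstream outcome codings recover them
#' exactly.
#'
#' @param n_patients Number of patients.
#' @param n_facilities Number of facilities (split between VA and community in
#'   proportion to `va_share`).
#' @param va_share Probability that a patient is discharged from a VA facility.
#' @param mediator_model,outcome_model,death_model Named lists of log-odds
#'   coefficients on standardized covariates. `outcome_model$pcp` and
#'   `outcome_model$pcp + outcome_model$va_pcp` are the mediator effects:
#'   the log-odds shift in 90-day readmission conferred by 30-day PCP
#'   follow-up for community and VA patients respectively.
#' @param death_model As above, for 90-day mortality.
#' @param class_model Named list of per-class coefficient vectors for the
#'   multinomial trajectory-class logit (reference class `sigma`). Features are
#'   `intercept, death, readmit, pcp30, va, age_s, cci_s, drg_s`. The `delta`
#'   class is structurally restricted to decedents.
#' @param class_events Per-class event-shape parameters. `ed`, `pcp` and
#'   `readmit_extra` are count distributions `c(base, extra, p)`: the number
#'   of events is `base + Binomial(extra, p)` (low dispersion keeps the
#'   archetypes distinguishable); `readmit_extra` counts repeat readmission
#'   episodes beyond the one implied by the readmission outcome. `duration`
#'   is the mean readmission episode length in days and `death_week_q` (delta
#'   only) the weekly geometric parameter of the early-death timing.
#' @param ed_type_factor Multiplies the ED rate for VA (`va`) and community
#'   (`ccn`) patients; community reliance on ED care is the default.
#' @param facility_sd Standard deviations of the facility random intercepts in
#'   the mediator and outcome models.
#' @param readmit_duration_mean Mean length (days) of a readmission episode.
#' @param acsc_prob Probability a readmission is flagged as an ambulatory
#'   care-sensitive condition.
#' @param horizon Follow-up horizon in days (administrative censoring).
#'
#' @return A list of class `posticu_config`.
#' @export
sim_config <- function(n_patients = 5000,
                       n_facilities = 40,
                       va_share = 0.369,
                       mediator_model = list(
                         intercept = -1.70, va = 0.36, age_s = -0.05,
                         cci_s = -0.05, adi_s = -0.05, rural = -0.10
                       ),
                       outcome_model = list(
                         intercept = -1.15, va = 0.18, pcp = -0.25,
                         va_pcp = 0.07, age_s = 0.05, cci_s = 0.18,
                         drg_s = 0.10, icu_s = 0.06
                       ),
                       death_model = list(
                         intercept = -2.73, va = 0.24, age_s = 0.45,
                         cci_s = 0.35
                       ),
                       class_model = list(
                         delta   = c(intercept = 1.09, death = 0, readmit = 0.3,
                                     pcp30 = -0.3, va = 0.2, age_s = 0.3,
                                     cci_s = 0.2, drg_s = 0.2),
                         omicron = c(intercept = -5.55, death = 0.5, readmit = 4.5,
                                     pcp30 = 0, va = 0.2, age_s = 0,
                                     cci_s = 0.1, drg_s = 0.05),
                         gamma   = c(intercept = -5.04, death = -0.5, readmit = 4.5,
                                     pcp30 = 0, va = 0.15, age_s = 0,
                                     cci_s = 0.1, drg_s = 0.05),
                         epsilon = c(intercept = -2.99, death = -0.8, readmit = -1.5,
                                     pcp30 = 2.5, va = 0.1, age_s = -0.05,
                                     cci_s = 0, drg_s = 0)
                       ),
                       class_events = list(
                         delta   = list(ed = c(1, 2, 0.50), pcp = c(0, 1, 0.10),
                                        readmit_extra = c(0, 1, 0.15),
                                        duration = 4, death_week_q = 0.28),
                         omicron = list(ed = c(0, 1, 0.10), pcp = c(0, 1, 0.10),
                                        readmit_extra = c(4, 1, 0.50),
                                        duration = 8),
                         gamma   = list(ed = c(7, 2, 0.50), pcp = c(0, 1, 0.10),
                                        readmit_extra = c(0, 1, 0.50),
                                        duration = 4),
                         epsilon = list(ed = c(0, 1, 0.10), pcp = c(8, 2, 0.50),
                                        readmit_extra = c(0, 1, 0.20),
                                        duration = 4),
                         sigma   = list(ed = c(0, 1, 0.16), pcp = c(0, 1, 0.08),
                                        readmit_extra = c(0, 1, 0.10),
                                        duration = 4)
                       ),
                       ed_type_factor = c(va = 0.82, ccn = 1.10),
                       facility_sd = c(mediator = 0.15, outcome = 0.15),
                       readmit_duration_mean = 4,
                       acsc_prob = 0.19,
                       horizon = 90) {
  stopifnot(n_patients >= 1, n_facilities >= 2,
            va_share > 0, va_share < 1, horizon == 90)
  cfg <- list(
    n_patients = n_patients, n_facilities = n_facilities, va_share = va_share,
    mediator_model = mediator_model, outcome_model = outcome_model,
    death_model = death_model, class_model = class_model,
    class_events = class_events, ed_type_factor = ed_type_factor,
    facility_sd = facility_sd, readmit_duration_mean = readmit_duration_mean,
    acsc_prob = acsc_prob, horizon = horizon
  )
  for (cl in names(cfg$class_model)) {
    if (length(cfg$class_model[[cl]]) != 8L)
      stop("class_model coefficients must have 8 entries (class ", cl, ")",
           call. = FALSE)
  }
  if (!setequal(names(cfg$class_events),
                c("delta", "omicron", "gamma", "epsilon", "sigma")))
    stop("class_events must name all five trajectory classes", call. = FALSE)
  structure(cfg, class = "posticu_config")
}

# standardized covariates used by the true simulation models; the same
# transformations are applied when fitting, so linear predictors agree.
std_covariates <- function(patients) {
  tibble(
    age_s = (patients$age - 70) / 10,
    cci_s = (patients$cci - 3.5) / 2.7,
    adi_s = (patients$adi - 61) / 27,
    drg_s = (log(patients$drg_weight) - log(1.12)) / 0.45,
    icu_s = (patients$icu_los - 2.2) / 2,
    rural = as.numeric(patients$rural == "rural")
  )
}

# truncated-normal helper via inverse cdf
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

draw_covariates <- function(n, hospital_type) {
  va <- hospital_type == 1L
  age <- round(rtnorm(n, 70, 10, 30, 100))
  sex <- rbinom(n, 1, ifelse(va, 0.950, 0.942))
  race_p <- list(
    va = c(White = 0.692, Black = 0.241, Asian = 0.004, Other = 0.016, Unknown = 0.047),
    ccn = c(White = 0.747, Black = 0.165, Asian = 0.005, Other = 0.022, Unknown = 0.061)
  )
  sample_cat <- function(p_va, p_ccn) {
    lv <- names(p_va)
    out <- character(n)
    out[va] <- sample(lv, sum(va), TRUE, p_va)
    out[!va] <- sample(lv, sum(!va), TRUE, p_ccn)
    out
  }
  race <- sample_cat(race_p$va, race_p$ccn)
  eth <- sample_cat(c(Hispanic = 0.062, NonHispanic = 0.905, Unknown = 0.033),
                    c(Hispanic = 0.045, NonHispanic = 0.912, Unknown = 0.043))
  marital <- ifelse(rbinom(n, 1, ifelse(va, 0.460, 0.507)) == 1, "married", "other")
  rural <- ifelse(rbinom(n, 1, ifelse(va, 0.295, 0.399)) == 1, "rural", "urban")
  adi <- pmin(100L, pmax(1L, round(rtnorm(n, 61, 27, 1, 100))))
  cci <- rnbinom_int(n, mu = 3.6, size = 1.8)
  drg_weight <- exp(rnorm(n, ifelse(va, log(1.06), log(1.17)), 0.45))
  icu_los <- 1L + rnbinom_int(n, mu = 1.6, size = 1.2)
  extra <- rnbinom_int(n, mu = ifelse(va, 3.2, 1.4), size = 1.5)
  hosp_los <- icu_los + extra
  drg_group <- sample(c("sepsis", "resp_failure", "ami", "other"), n, TRUE,
                      c(0.30, 0.25, 0.12, 0.33))
  tibble(age = age, sex = sex, race = race, ethnicity = eth, marital = marital,
         rural = rural, adi = as.integer(adi), cci = cci,
         drg_weight = drg_weight, icu_los = icu_los, hosp_los = hosp_los,
         drg_group = drg_group)
}

rnbinom_int <- function(n, mu, size) as.integer(stats::rnbinom(n, mu = mu, size = size))

# weighted early-skewed day draw within 1..ub
draw_day <- function(ub, rate) {
  if (ub == 1L) return(1L)
  sample.int(ub, 1L, prob = (1 - rate)^(0:(ub - 1L)))
}

#' Generate a synthetic post-ICU cohort
#'
#' Draws a seeded cohort of discharged ICU survivors (one row per patient) and
#' the dated post-discharge care events the downstream analyses consume. Day 0
#' is the discharge day; events occur on days 1 to `horizon`. Death is
#' absorbing: no event is placed after a patient's death day.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; the same `config` and `seed` reproduce the cohort
#'   byte-identically.
#' @return A list with `patients` (tibble, one row per patient, including the
#'   simulator-only `latent_class` ground truth) and `events` (tibble with
#'   `patient_id`, `event_type` in PCP/ED/READMIT/DEATH, `day`, `end_day` and
#'   `acsc_flag` for readmissions).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "posticu_config"))
  set.seed(seed)
  n <- config$n_patients

  # facilities and hospital type
  n_va_fac <- max(1L, round(config$n_facilities * 0.4))
  n_ccn_fac <- max(1L, config$n_facilities - n_va_fac)
  hospital_type <- rbinom(n, 1, config$va_share)
  fac_idx <- ifelse(hospital_type == 1L,
                    sample.int(n_va_fac, n, TRUE),
                    n_va_fac + sample.int(n_ccn_fac, n, TRUE))
  facility_id <- sprintf("F%03d", fac_idx)

  cov <- draw_covariates(n, hospital_type)
  patients <- bind_cols(
    tibble(patient_id = sprintf("P%06d", seq_len(n)),
           facility_id = facility_id, hospital_type = hospital_type),
    cov
  )
  z <- std_covariates(patients)
  A <- hospital_type

  # facility random intercepts
  u_m <- rnorm(config$n_facilities, 0, config$facility_sd[["mediator"]])
  u_y <- rnorm(config$n_facilities, 0, config$facility_sd[["outcome"]])

  # mediation layer: M (30-day PCP first contact), Y (90-day readmission), death
  mm <- config$mediator_model
  eta_m <- mm$intercept + mm$va * A + mm$age_s * z$age_s + mm$cci_s * z$cci_s +
    mm$adi_s * z$adi_s + mm$rural * z$rural + u_m[fac_idx]
  M <- rbinom(n, 1, plogis(eta_m))

  om <- config$outcome_model
  eta_y <- om$intercept + om$va * A + om$pcp * M + om$va_pcp * A * M +
    om$age_s * z$age_s + om$cci_s * z$cci_s + om$drg_s * z$drg_s +
    om$icu_s * z$icu_s + u_y[fac_idx]
  Y <- rbinom(n, 1, plogis(eta_y))

  dm <- config$death_model
  eta_d <- dm$intercept + dm$va * A + dm$age_s * z$age_s + dm$cci_s * z$cci_s
  D <- rbinom(n, 1, plogis(eta_d))

  # trajectory layer: latent class from multinomial logit on covariates,
  # hospital type and realized indicators; delta restricted to decedents
  feats <- cbind(1, D, Y, M, A, z$age_s, z$cci_s, z$drg_s)
  cm <- config$class_model
  scores <- vapply(c("delta", "omicron", "gamma", "epsilon"),
                   function(cl) as.numeric(feats %*% cm[[cl]]),
                   numeric(n))
  if (n == 1L) scores <- matrix(scores, nrow = 1, dimnames = list(NULL, names(scores)))
  scores <- cbind(scores, sigma = 0)
  scores[D == 0L, "delta"] <- -Inf
  pr <- exp(scores - apply(scores, 1, max))
  pr <- pr / rowSums(pr)
  cum <- t(apply(pr, 1, cumsum))
  latent_class <- colnames(scores)[max.col(cum >= runif(n), ties.method = "first")]
  patients$latent_class <- latent_class

  # death timing: delta deaths early (truncated-geometric week), others late
  death_day <- rep(NA_integer_, n)
  is_delta <- latent_class == "delta"
  if (any(is_delta)) {
    qd <- config$class_events$delta$death_week_q %||% 0.25
    wk <- 1L + (rgeom(sum(is_delta), qd) %% 13L)
    dd <- 7L * (wk - 1L) + sample.int(7L, sum(is_delta), TRUE)
    death_day[is_delta] <- pmin(90L, pmax(3L, dd))
  }
  other_d <- which(D == 1L & !is_delta)
  if (length(other_d)) {
    dd <- round(8 + 82 * rbeta(length(other_d), 3.5, 0.9))
    death_day[other_d] <- pmin(90L, pmax(8L, as.integer(dd)))
  }

  ev_cfg <- config$class_events
  draw_count <- function(field, p_mult = NULL) {
    out <- integer(n)
    for (cl in names(ev_cfg)) {
      idx <- which(latent_class == cl)
      par <- ev_cfg[[cl]][[field]]
      pp <- if (is.null(p_mult)) par[3] else pmin(1, par[3] * p_mult[idx])
      out[idx] <- par[1] + rbinom(length(idx), par[2], pp)
    }
    out
  }
  ed_factor <- ifelse(A == 1L, config$ed_type_factor[["va"]],
                      config$ed_type_factor[["ccn"]])
  life_end <- ifelse(is.na(death_day), 90L, death_day)
  # thin visit counts for patients who die early
  expo <- pmin(1, life_end / 60)
  n_ed <- rbinom(n, draw_count("ed", p_mult = ed_factor), expo)
  n_pcp_extra <- rbinom(n, draw_count("pcp"), expo)
  n_rex <- draw_count("readmit_extra")
  dur_mean <- vapply(ev_cfg, function(e) e$duration %||% config$readmit_duration_mean,
                     numeric(1))[latent_class]

  # mediator PCP day (first contact, strictly before any acute contact)
  pcp1_day <- rep(NA_integer_, n)
  idx_m <- which(M == 1L)
  for (i in idx_m) {
    ub <- min(29L, life_end[i] - 1L)
    pcp1_day[i] <- draw_day(max(1L, ub), 0.08)
  }

  # per-patient event assembly
  has_any <- which(Y == 1L | M == 1L | n_ed > 0L | n_pcp_extra > 0L | D == 1L)
  ev_pid <- vector("list", length(has_any))
  ev_type <- vector("list", length(has_any))
  ev_day <- vector("list", length(has_any))
  ev_end <- vector("list", length(has_any))
  for (j in seq_along(has_any)) {
    i <- has_any[j]
    le <- life_end[i]
    in_hosp <- logical(90L)
    re_start <- integer(0)
    re_end <- integer(0)
    if (Y[i] == 1L) {
      lb <- if (M[i] == 1L) pcp1_day[i] + 1L else 1L
      win <- lb:le
      r1 <- win[draw_day(length(win), 0.03)]
      dur <- max(1L, as.integer(round(dur_mean[i])) - 1L + rbinom(1L, 2L, 0.5))
      e1 <- min(r1 + dur - 1L, le, 90L)
      re_start <- r1; re_end <- e1
      prev_end <- e1
      for (k in seq_len(n_rex[i])) {
        lo <- prev_end + 2L
        if (lo > le) break
        r <- lo + draw_day(le - lo + 1L, 0.03) - 1L
        dur <- max(1L, as.integer(round(dur_mean[i])) - 1L + rbinom(1L, 2L, 0.5))
        e <- min(r + dur - 1L, le, 90L)
        re_start <- c(re_start, r); re_end <- c(re_end, e)
        prev_end <- e
      }
      for (k in seq_along(re_start)) in_hosp[re_start[k]:re_end[k]] <- TRUE
    }
    first_acute <- if (length(re_start)) min(re_start) else Inf

    days_free <- which(!in_hosp[seq_len(le)])
    # ED visits
    ed_days <- integer(0)
    if (n_ed[i] > 0L) {
      ok <- days_free
      if (M[i] == 1L) ok <- ok[ok > pcp1_day[i]]
      if (length(ok)) {
        ed_days <- sort(ok[sample.int(length(ok), min(n_ed[i], length(ok)))])
        first_acute <- min(first_acute, ed_days[1])
      }
    }
    # additional PCP visits (never creating a spurious 30-day first contact)
    pcp_days <- if (M[i] == 1L) pcp1_day[i] else integer(0)
    if (n_pcp_extra[i] > 0L) {
      ok <- days_free
      ok <- if (M[i] == 1L) ok[ok > pcp1_day[i]] else ok[ok > min(30, first_acute)]
      ok <- setdiff(ok, ed_days)
      if (length(ok))
        pcp_days <- c(pcp_days,
                      sort(ok[sample.int(length(ok), min(n_pcp_extra[i], length(ok)))]))
    }
    types <- c(rep("PCP", length(pcp_days)), rep("ED", length(ed_days)),
               rep("READMIT", length(re_start)),
               if (D[i] == 1L) "DEATH")
    days <- c(pcp_days, ed_days, re_start, if (D[i] == 1L) death_day[i])
    ends <- c(rep(NA_integer_, length(pcp_days) + length(ed_days)), re_end,
              if (D[i] == 1L) NA_integer_)
    ev_pid[[j]] <- rep(patients$patient_id[i], length(days))
    ev_type[[j]] <- types
    ev_day[[j]] <- as.integer(days)
    ev_end[[j]] <- as.integer(ends)
  }

  events <- tibble(
    patient_id = unlist(ev_pid, use.names = FALSE),
    event_type = unlist(ev_type, use.names = FALSE),
    day = unlist(ev_day, use.names = FALSE),
    end_day = unlist(ev_end, use.names = FALSE)
  )
  events$acsc_flag <- ifelse(events$event_type == "READMIT",
                             runif(nrow(events)) < config$acsc_prob, NA)
  events <- arrange(events, .data$patient_id, .data$day)

  list(patients = patients, events = events,
       truth = tibble(patient_id = patients$patient_id, pcp30 = M,
                      readmit90 = Y, death90 = D))
}

#' Monte-Carlo ground-truth mediation effects of the generator
#'
#' Computes the generator's own counterfactual natural effects by averaging the
#' true mediator and outcome probabilities over a fresh draw of covariates and
#' facility intercepts: `p(a, a')` is the mean over patients of
#' `P(M=1|a') P(Y=1|a, M=1) + P(M=0|a') P(Y=1|a, M=0)`. Because the generator
#' draws its mediator and outcome from exactly these models, the quantities are
#' exact up to Monte-Carlo error in the covariate average. Used as the oracle
#' for mediation recovery tests.
#'
#' @param config A [sim_config()].
#' @param n_mc Monte-Carlo sample size (at least 1e5).
#' @param seed Seed for the covariate draw.
#' @return A tibble with one row per effect (`pnde`, `tnde`, `nie_ccn`,
#'   `nie_va`, `te`, `interaction_contrast`, `mediator_rd`), in percentage
#'   points.
#' @export
true_mediation_effects <- function(config = sim_config(), n_mc = 1e5, seed = 1L) {
  stopifnot(n_mc >= 1e5)
  set.seed(seed)
  n <- as.integer(n_mc)
  hospital_type <- rbinom(n, 1, config$va_share)
  cov <- draw_covariates(n, hospital_type)
  cov$patient_id <- sprintf("M%07d", seq_len(n))
  z <- std_covariates(cov)
  u_m <- rnorm(n, 0, config$facility_sd[["mediator"]])
  u_y <- rnorm(n, 0, config$facility_sd[["outcome"]])

  mm <- config$mediator_model
  om <- config$outcome_model
  eta_m0 <- mm$intercept + mm$age_s * z$age_s + mm$cci_s * z$cci_s +
    mm$adi_s * z$adi_s + mm$rural * z$rural + u_m
  pm <- function(a) plogis(eta_m0 + mm$va * a)
  eta_y0 <- om$intercept + om$age_s * z$age_s + om$cci_s * z$cci_s +
    om$drg_s * z$drg_s + om$icu_s * z$icu_s + u_y
  py <- function(a, m) plogis(eta_y0 + om$va * a + om$pcp * m + om$va_pcp * a * m)
  p_cf <- function(a, ap) mean(pm(ap) * py(a, 1) + (1 - pm(ap)) * py(a, 0))

  p00 <- p_cf(0, 0); p10 <- p_cf(1, 0); p01 <- p_cf(0, 1); p11 <- p_cf(1, 1)
  delta0 <- mean(py(0, 1) - py(0, 0))
  delta1 <- mean(py(1, 1) - py(1, 0))
  tibble(
    effect = c("pnde", "tnde", "nie_ccn", "nie_va", "te",
               "interaction_contrast", "mediator_rd"),
    value = 100 * c(p10 - p00, p11 - p01, p01 - p00, p11 - p10, p11 - p00,
                    delta0 - delta1, mean(pm(1) - pm(0)))
  )
}

#' Write / read a cohort as CSV files
#'
#' `write_cohort()` writes `patients.csv` and `events.csv` (plus
#' `latent_class.csv` holding the simulator-only ground truth) into `dir`;
#' `read_cohort()` reads them back with stable column types so the round trip
#' is lossless.
#'
#' @param cohort A list with `patients` and `events` tibbles.
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   list with `patients` and `events`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pat <- select(cohort$patients, -any_of("latent_class"))
  readr::write_csv(pat, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$events, file.path(dir, "events.csv"))
  if ("latent_class" %in% names(cohort$patients)) {
    readr::write_csv(select(cohort$patients, "patient_id", "latent_class"),
                     file.path(dir, "latent_class.csv"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pat <- readr::read_csv(
    file.path(dir, "patients.csv"),
    col_types = readr::cols(
      patient_id = "c", facility_id = "c", hospital_type = "i", age = "i",
      sex = "i", race = "c", ethnicity = "c", marital = "c", rural = "c",
      adi = "i", cci = "i", drg_weight = "d", icu_los = "i", hosp_los = "i",
      drg_group = "c"
    )
  )
  ev <- readr::read_csv(
    file.path(dir, "events.csv"),
    col_types = readr::cols(patient_id = "c", event_type = "c", day = "i",
                            end_day = "i", acsc_flag = "l")
  )
  lc <- file.path(dir, "latent_class.csv")
  if (file.exists(lc)) {
    truth <- readr::read_csv(lc, col_types = readr::cols(patient_id = "c",
                                                         latent_class = "c"))
    pat <- left_join(pat, truth, by = "patient_id")
  }
  list(patients = pat, events = ev)
}
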