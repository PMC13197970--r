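test_that("competing-risk status coding follows the outcome-specific rules", {
  p <- pat(c("A", "B", "C", "D"))
  e <- dplyr::bind_rows(
    ev("A", "ED", 4), ev("A", "PCP", 10),
    ev("C", "DEATH", 12),
    ev("D", "READMIT", 20, end_day = 22), ev("D", "DEATH", 20)
  )
  d <- prepare_competing_data(e, p, "pcp_first")
  expect_equal(d$status, c(2L, 0L, 2L, 2L))
  expect_equal(d$time, c(4, 90, 12, 20))

  d2 <- prepare_competing_data(e, p, "readmission")
  # death on the same day as readmission counts as the event
  expect_equal(d2$status, c(0L, 0L, 2L, 1L))
  expect_equal(d2$time, c(90, 90, 12, 20))

  d3 <- prepare_competing_data(e, p, "death")
  expect_equal(d3$status, c(0L, 0L, 1L, 1L))
  expect_error(prepare_competing_data(e, p, "nonsense"))
})

test_that("censoring Kaplan-Meier matches a hand computation", {
  d <- tibble::tibble(time = c(2, 3, 5, 7), status = c(0L, 1L, 0L, 0L))
  km <- censoring_km(d)
  # censoring events at 2, 5, 7; at-risk 4, 2, 1
  expect_equal(km_left(km, 2), 1)
  expect_equal(km_left(km, 3), 3 / 4)
  expect_equal(km_left(km, 6), (3 / 4) * (1 / 2))
  expect_true(all(diff(km$surv) <= 1e-12))
  # administrative-only censoring keeps G at 1 before the horizon
  d2 <- tibble::tibble(time = c(10, 20, 90, 90), status = c(1L, 2L, 0L, 0L))
  km2 <- censoring_km(d2)
  expect_equal(km_left(km2, 90), 1)
})

test_that("Fine-Gray reduces to a Cox fit when no competing events exist", {
  set.seed(1)
  n <- 2000
  d <- tibble::tibble(
    time = round(stats::rexp(n, 0.03), 3) + 0.001,
    x = stats::rbinom(n, 1, 0.5),
    facility_id = sample(sprintf("F%02d", 1:15), n, TRUE)
  )
  d$time <- pmin(d$time, 90)
  d$status <- ifelse(d$time < 90, 1L, 0L)
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "x")
  cx <- survival::coxph(survival::Surv(time, status == 1) ~ x, data = d,
                        ties = "breslow")
  expect_lt(abs(fg$coef - unname(stats::coef(cx))), 1e-6)
})

test_that("Fine-Gray coefficients agree with the cmprsk reference on censored data", {
  skip_if_not_installed("cmprsk")
  d <- sim_finegray_data(3000, beta = log(1.4), censor_rate = 0.3, seed = 9)
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "x")
  cr <- cmprsk::crr(d$time, d$status, cbind(x = d$x))
  expect_lt(abs(unname(fg$coef) - unname(cr$coef)), 1e-4)
})

test_that("null data give small coefficients and clustered SEs behave sanely", {
  d <- sim_finegray_data(5000, beta = 0, seed = 123)
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "x")
  expect_lt(abs(fg$coef), 3 * sqrt(fg$vcov_model[1, 1]))
  expect_gt(sqrt(fg$vcov_cluster[1, 1]), 0)
  # invariance to facility relabelling and row order
  d2 <- d[sample.int(nrow(d)), ]
  d2$facility_id <- paste0("X_", d2$facility_id)
  fg2 <- fine_gray_fit(d2, covariates = character(0), exposure = "x")
  expect_equal(unname(fg$coef), unname(fg2$coef), tolerance = 1e-10)
  expect_equal(fg$vcov_cluster, fg2$vcov_cluster, tolerance = 1e-8)
})

test_that("cause-specific Cox fit is directionally consistent with Fine-Gray", {
  # low competing-event share so the two hazard scales agree in direction
  d <- sim_finegray_data(4000, beta = log(1.5), p = 0.75, seed = 31)
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "x")
  cs <- cause_specific_cox_fit(d, covariates = character(0), exposure = "x")
  expect_equal(sign(unname(fg$coef)), sign(unname(stats::coef(cs))[1]))
})

test_that("predicted cumulative incidence is a proper distribution function", {
  d <- sim_finegray_data(3000, seed = 6)
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "x")
  grid <- c(0, 5, 10, 20, 40, 60, 80, 90)
  cif <- predict_cif(fg, d[1:5, ], grid)
  expect_equal(unname(cif[, 1]), rep(0, 5))
  expect_true(all(cif >= 0 & cif <= 1))
  expect_true(all(apply(cif, 1, function(r) all(diff(r) >= -1e-12))))
})

test_that("null-exposure standardized CIF matches the Aalen-Johansen estimator", {
  d <- sim_finegray_data(10000, beta = 0, seed = 4)
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "x", cluster = NULL)
  sr <- posticu:::std_risks_once(fg, d, c(30, 90))
  aj <- survival::survfit(survival::Surv(time, factor(status, levels = 0:2)) ~ 1,
                          data = d)
  aj_at <- vapply(c(30, 90),
                  function(t) aj$pstate[max(which(aj$time <= t)), 2],
                  numeric(1))
  expect_lt(max(abs(sr$risk_va / 100 - aj_at)), 0.005)
})

test_that("standardization is exactly null when the exposure coefficient is zero", {
  d <- sim_finegray_data(2000, beta = log(1.3), seed = 15)
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "x")
  fg$coef[] <- 0
  sr <- posticu:::std_risks_once(fg, d, c(30, 90))
  expect_equal(sr$rd, c(0, 0))
  expect_equal(sr$rr, c(1, 1))
})

test_that("standardized risks carry percentile bootstrap intervals", {
  d <- sim_finegray_data(1500, beta = log(1.4), seed = 8)
  d$hospital_type <- d$x
  fg <- fine_gray_fit(d, covariates = character(0), exposure = "hospital_type")
  sr <- marginal_standardization(fg, t_set = 90, n_boot = 40, seed = 2)
  expect_true(sr$rd_lo <= sr$rd & sr$rd <= sr$rd_hi)
  expect_true(sr$risk_va > sr$risk_ccn)   # SHR > 1 must raise the risk
  expect_error(marginal_standardization(fg, n_boot = 1), "n_boot")
})

test_that("unadjusted rates reproduce hand counts and are monotone in horizon", {
  p1 <- pat("A")
  e1 <- ev("A", "PCP", 10)
  r1 <- unadjusted_rates(e1, p1)
  expect_equal(r1$rate[r1$outcome == "pcp_first" & r1$horizon == 30], 100)

  p <- pat(sprintf("P%d", 1:10), hospital_type = rep(c(1L, 0L), each = 5))
  e <- dplyr::bind_rows(
    ev("P1", "PCP", 3), ev("P2", "ED", 40), ev("P3", "READMIT", 10, end_day = 12),
    ev("P6", "PCP", 50), ev("P7", "DEATH", 25)
  )
  r <- unadjusted_rates(e, p)
  g <- function(o, h, t) r$rate[r$outcome == o & r$horizon == h & r$hospital_type == t]
  expect_equal(g("pcp_first", 30, "VA"), 20)   # 1 of 5
  expect_equal(g("pcp_first", 90, "CCN"), 20)  # PCP at day 50 counts at 90 days
  expect_equal(g("ed", 30, "VA"), 0)
  expect_equal(g("ed", 90, "VA"), 20)
  expect_equal(g("death", 90, "CCN"), 20)
  wide <- tidyr::pivot_wider(dplyr::filter(r, outcome != "acsc_share"),
                             names_from = horizon, values_from = rate)
  expect_true(all(wide$`90` >= wide$`30`))
})
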