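test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 400)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  c <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$events, c$events))
})

test_that("degenerate class mixture puts every patient in one class", {
  cfg <- sim_config(n_patients = 300)
  for (cl in c("delta", "omicron", "gamma", "epsilon"))
    cfg$class_model[[cl]]["intercept"] <- -1e6
  co <- generate_cohort(cfg, seed = 2)
  expect_true(all(co$patients$latent_class == "sigma"))
})

test_that("default class shares match the target trajectory-mixture shares", {
  target <- c(delta = 18376, omicron = 15576, gamma = 24214,
              epsilon = 24498, sigma = 228560) / 311224
  co <- generate_cohort(sim_config(n_patients = 50000), seed = 31)
  shares <- prop.table(table(factor(co$patients$latent_class,
                                    levels = names(target))))
  expect_lt(max(abs(as.numeric(shares) - as.numeric(target))), 0.01)
})

test_that("generated records satisfy the schema invariants", {
  co <- generate_cohort(sim_config(n_patients = 3000), seed = 8)
  p <- co$patients; e <- co$events
  expect_true(all(p$icu_los <= p$hosp_los))
  expect_true(all(p$adi >= 1 & p$adi <= 100))
  expect_true(all(p$hospital_type %in% 0:1))
  expect_true(all(e$day >= 1 & e$day <= 90))
  re <- dplyr::filter(e, event_type == "READMIT")
  expect_true(all(re$end_day >= re$day))
  expect_true(all(!is.na(re$acsc_flag)))
  deaths <- dplyr::filter(e, event_type == "DEATH")
  expect_false(any(duplicated(deaths$patient_id)))
  # absorbing death: no event after the death day, cohort-wide
  chk <- dplyr::left_join(e, dplyr::select(deaths, patient_id, dday = day),
                          by = "patient_id")
  chk <- dplyr::filter(chk, !is.na(dday))
  expect_true(all(chk$day <= chk$dday))
  expect_true(all(is.na(chk$end_day) | chk$end_day <= chk$dday))
})

test_that("outcome proportions are monotone in their configured hazards", {
  n <- 20000
  bump <- function(field, delta) {
    cfg <- sim_config(n_patients = n)
    cfg[[field]]$intercept <- cfg[[field]]$intercept + delta
    co <- generate_cohort(cfg, seed = 12)
    posticu::patient_outcomes(co$events, co$patients)
  }
  lo <- bump("death_model", 0); hi <- bump("death_model", 0.7)
  expect_gt(mean(hi$death90), mean(lo$death90))
  lo <- bump("outcome_model", 0); hi <- bump("outcome_model", 0.7)
  expect_gt(mean(hi$readmit90), mean(lo$readmit90))
  lo <- bump("mediator_model", 0); hi <- bump("mediator_model", 0.7)
  expect_gt(mean(hi$pcp30_first), mean(lo$pcp30_first))
  # ED visit probability knob
  cfg <- sim_config(n_patients = n)
  co_lo <- generate_cohort(cfg, seed = 12)
  cfg$class_events$sigma$ed <- c(0, 1, 0.60)
  co_hi <- generate_cohort(cfg, seed = 12)
  expect_gt(mean(patient_outcomes(co_hi$events, co_hi$patients)$ed90),
            mean(patient_outcomes(co_lo$events, co_lo$patients)$ed90))
})

test_that("cohorts round-trip losslessly through the CSV writer/reader", {
  co <- generate_cohort(sim_config(n_patients = 250), seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$patients), as.data.frame(co$patients))
  expect_equal(as.data.frame(back$events), as.data.frame(co$events))
})

test_that("generator oracle effects vanish when their pathways are switched off", {
  cfg <- sim_config()
  cfg$outcome_model$pcp <- 0
  cfg$outcome_model$va_pcp <- 0
  eff <- true_mediation_effects(cfg, n_mc = 1e5, seed = 2)
  nies <- eff$value[eff$effect %in% c("nie_ccn", "nie_va")]
  expect_true(all(abs(nies) < 1e-10))

  cfg2 <- sim_config()
  cfg2$mediator_model$va <- 0
  cfg2$outcome_model$va <- 0
  cfg2$outcome_model$va_pcp <- 0
  cfg2$death_model$va <- 0
  eff2 <- true_mediation_effects(cfg2, n_mc = 2e5, seed = 3)
  expect_lt(abs(eff2$value[eff2$effect == "te"]), 0.15)
})
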