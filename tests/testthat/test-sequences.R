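test_that("weekly state assignment follows the highest-acuity rule", {
  p <- pat(c("A", "B", "C", "D"))
  e <- dplyr::bind_rows(
    ev("B", "PCP", 3), ev("B", "ED", 5),        # same week: ED wins
    ev("C", "DEATH", 10),                        # day 10 is week 2
    ev("D", "READMIT", 12, end_day = 24)         # spans weeks 2-4
  )
  sq <- build_state_sequences(e, p)
  m <- as.matrix(sq[, -1])
  expect_equal(unname(m[1, ]), rep(0L, 13))                 # no events -> HOME
  expect_equal(unname(m[2, ]), c(2L, rep(0L, 12)))
  expect_equal(unname(m[3, ]), c(0L, rep(4L, 12)))          # death absorbing
  expect_equal(unname(m[4, ]), c(0L, 3L, 3L, 3L, rep(0L, 9)))
})

test_that("readmission overlapped weeks are READMIT and death dominates", {
  p <- pat("A")
  e <- dplyr::bind_rows(ev("A", "READMIT", 8, end_day = 20),
                        ev("A", "DEATH", 20))
  m <- as.matrix(build_state_sequences(e, p)[, -1])
  # weeks 2-3 readmission, but death in week 3 takes precedence from there on
  expect_equal(unname(m[1, ]), c(0L, 3L, rep(4L, 11)))
})

test_that("events beyond the 13-week horizon are truncated", {
  p <- pat("A")
  e <- ev("A", "ED", 95)
  m <- as.matrix(build_state_sequences(e, p)[, -1])
  expect_equal(unname(m[1, ]), rep(0L, 13))
  e2 <- ev("A", "ED", 91)   # day 91 belongs to week 13
  m2 <- as.matrix(build_state_sequences(e2, p)[, -1])
  expect_equal(unname(m2[1, 13]), 2L)
})

test_that("lcs length matches spec examples and brute-force enumeration", {
  s <- sample(0:4, 13, TRUE)
  expect_equal(lcs_length(s, s), 13L)
  expect_equal(lcs_length(c(0, 1, 2, 0), c(0, 2, 0)), 3L)
  expect_equal(lcs_length(rep(0L, 5), rep(1L, 7)), 0L)
  set.seed(42)
  for (r in 1:50) {
    a <- sample(0:4, sample(2:8, 1), TRUE)
    b <- sample(0:4, sample(2:8, 1), TRUE)
    expect_equal(lcs_length(a, b), lcs_bruteforce(a, b))
  }
})

test_that("lcs distance satisfies the stated examples and is a metric", {
  a <- c(0, 1, 2, 0); b <- c(0, 2, 0)
  expect_equal(lcs_distance(a, a), 0)
  expect_equal(lcs_distance(a, b), 1)
  expect_equal(lcs_distance(rep(0L, 13), rep(1L, 13)), 26)
  set.seed(7)
  for (r in 1:1000) {
    x <- sample(0:4, 13, TRUE); y <- sample(0:4, 13, TRUE); z <- sample(0:4, 13, TRUE)
    dxy <- lcs_distance(x, y); dyz <- lcs_distance(y, z); dxz <- lcs_distance(x, z)
    expect_lte(dxz, dxy + dyz)
    expect_equal(dxy, lcs_distance(y, x))
    expect_equal(dxy == 0, identical(x, y))
  }
})

test_that("deduplication weights are multiset multiplicities", {
  m <- matrix(rep(c(0L, 1L, 0L, 2L, 0L), each = 6), nrow = 6)  # identical rows
  dw <- dedup_weight(seq_tibble(m))
  expect_equal(nrow(dw$seqs), 1L)
  expect_equal(dw$weights, 6)

  m2 <- rbind(c(0L, 1L), c(0L, 2L), c(0L, 1L), c(3L, 3L), c(0L, 1L))
  dw2 <- dedup_weight(seq_tibble(m2))
  expect_equal(sum(dw2$weights), 5)
  expect_equal(sort(dw2$weights), c(1, 1, 3))
  # all distinct
  m3 <- rbind(c(0L, 1L), c(1L, 0L), c(2L, 2L))
  expect_equal(dedup_weight(seq_tibble(m3))$weights, rep(1, 3))
})

test_that("hospital-free days count alive out-of-hospital days", {
  p <- pat(c("A", "B", "C", "D"))
  e <- dplyr::bind_rows(
    ev("B", "DEATH", 23),
    ev("C", "READMIT", 5, end_day = 9),
    ev("D", "READMIT", 85, end_day = 100)   # truncated at the horizon
  )
  hfd <- hospital_free_days(e, p)
  expect_equal(hfd$hospital_free_days, c(90L, 22L, 85L, 84L))
})

test_that("state density proportions sum to one per week", {
  co <- generate_cohort(sim_config(n_patients = 400), seed = 3)
  sq <- build_state_sequences(co$events, co$patients)
  den <- state_density(sq)
  sums <- den |>
    dplyr::group_by(week) |>
    dplyr::summarise(s = sum(proportion))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # absorbing death: weekly DEAD proportion is non-decreasing
  dead <- dplyr::filter(den, state == "DEAD")$proportion
  expect_true(all(diff(dead) >= -1e-12))
})
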