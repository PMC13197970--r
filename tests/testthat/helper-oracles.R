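# independent oracles used across the suite; deliberately naive implementations

# longest common subsequence by exhaustive subsequence enumeration (len <= ~10)
lcs_bruteforce <- function(a, b) {
  subseqs <- function(x) {
    n <- length(x)
    out <- new.env(hash = TRUE, parent = emptyenv())
    for (mask in 0:(2^n - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      key <- paste0("s:", paste(x[sel], collapse = ","))
      assign(key, length(sel), envir = out)
    }
    out
  }
  sa <- subseqs(a)
  best <- 0
  n <- length(b)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    key <- paste0("s:", paste(b[sel], collapse = ","))
    if (!is.null(sa[[key]])) best <- length(sel)
  }
  best
}

# exhaustive-search optimum of the weighted k-medoids objective
pam_bruteforce <- function(D, w, k) {
  m <- nrow(D)
  best <- Inf
  best_set <- NULL
  sets <- combn(m, k)
  for (j in seq_len(ncol(sets))) {
    med <- sets[, j]
    cost <- sum(w * apply(D[, med, drop = FALSE], 1, min))
    if (cost < best - 1e-12) { best <- cost; best_set <- med }
  }
  list(objective = best, medoids = best_set)
}

# random valid state-sequence matrix (absorbing death respected)
random_sequences <- function(n, len = 13, seed = 1) {
  set.seed(seed)
  t(replicate(n, {
    s <- sample(0:3, len, TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    if (runif(1) < 0.2) {
      dw <- sample(len, 1)
      s[dw:len] <- 4L
    }
    s
  }))
}

seq_tibble <- function(mat) {
  dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("S%04d", seq_len(nrow(mat)))),
    tibble::as_tibble(mat, .name_repair = ~ sprintf("w%02d", seq_len(ncol(mat))))
  )
}

# small event-table constructor
ev <- function(patient_id, event_type, day, end_day = NA_integer_,
               acsc_flag = NA) {
  tibble::tibble(patient_id = patient_id, event_type = event_type,
                 day = as.integer(day), end_day = as.integer(end_day),
                 acsc_flag = acsc_flag)
}

pat <- function(ids, hospital_type = 0L, facility_id = "F01") {
  n <- length(ids)
  tibble::tibble(
    patient_id = ids,
    facility_id = rep_len(facility_id, n),
    hospital_type = rep_len(as.integer(hospital_type), n),
    age = rep_len(70L, n), sex = rep_len(1L, n),
    race = rep_len("White", n), ethnicity = rep_len("NonHispanic", n),
    marital = rep_len("married", n), rural = rep_len("urban", n),
    adi = rep_len(60L, n), cci = rep_len(3L, n),
    drg_weight = rep_len(1.1, n), icu_los = rep_len(2L, n),
    hosp_los = rep_len(5L, n), drg_group = rep_len("sepsis", n)
  )
}
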