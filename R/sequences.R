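#' Ordered care-state alphabet
#'
#' Weekly states ranked by increasing acuity; death is absorbing.
#' @export
state_levels <- c("HOME", "PCP", "ED", "READMIT", "DEAD")

#' Build weekly acuity-ranked state sequences
#'
#' Converts dated post-discharge events into one 13-week state sequence per
#' patient over the ordered alphabet HOME < PCP < ED < READMIT < DEAD. Week w
#' covers days 7(w-1)+1 to 7w (day 0, the discharge day, belongs to no week).
#' A week's state is the highest-acuity event in it; weeks overlapped by a
#' readmission inpatient interval are READMIT even without a new admission;
#' the week of death and all later weeks are DEAD; event-free weeks are HOME.
#' Events after day `7 * horizon_weeks` are truncated.
#'
#' @param events Event tibble (`patient_id`, `event_type`, `day`, `end_day`).
#' @param patients Patient tibble (or a character vector of patient ids);
#'   patients without events get all-HOME sequences.
#' @param horizon_weeks Number of weekly bins (13 weeks covers the 90-day
#'   window).
#' @return A tibble with `patient_id` and integer state columns `w01` ... ;
#'   codes 0-4 index [state_levels].
#' @export
build_state_sequences <- function(events, patients, horizon_weeks = 13) {
  ids <- if (is.character(patients)) patients else patients$patient_id
  W <- as.integer(horizon_weeks)
  max_day <- 7L * W
  mat <- matrix(0L, nrow = length(ids), ncol = W)
  pid <- match(events$patient_id, ids)
  if (anyNA(pid)) stop("events reference unknown patient ids", call. = FALSE)
  ev <- tibble(pid = pid, type = events$event_type,
               day = events$day, end_day = events$end_day)
  ev <- filter(ev, .data$day >= 1L, .data$day <= max_day)

  wk <- (ev$day + 6L) %/% 7L
  put <- function(sel, code) {
    cells <- cbind(ev$pid[sel], wk[sel])
    mat[cells] <<- pmax(mat[cells], code)
  }
  put(ev$type == "PCP", 1L)
  put(ev$type == "ED", 2L)
  re <- which(ev$type == "READMIT")
  for (i in re) {
    w1 <- wk[i]
    e <- ev$end_day[i]
    if (is.na(e)) e <- ev$day[i]
    w2 <- (min(e, max_day) + 6L) %/% 7L
    ww <- w1:max(w1, w2)
    mat[ev$pid[i], ww] <- pmax(mat[ev$pid[i], ww], 3L)
  }
  de <- which(ev$type == "DEATH")
  for (i in de) mat[ev$pid[i], wk[i]:W] <- 4L

  out <- as_tibble(mat, .name_repair = ~ sprintf("w%02d", seq_len(W)))
  bind_cols(tibble(patient_id = ids), out)
}

seq_matrix <- function(sequences) {
  as.matrix(select(sequences, starts_with("w")))
}

#' Longest common subsequence length and distance
#'
#' `lcs_length()` is the length of the longest (not necessarily contiguous)
#' common subsequence of two state vectors; `lcs_distance()` is the standard
#' LCS metric `|a| + |b| - 2 * LCS(a, b)`, which is symmetric, zero only for
#' identical equal-length sequences, and satisfies the triangle inequality.
#'
#' @param a,b Integer (or factor-coded) state vectors.
#' @return An integer length / a non-negative numeric distance.
#' @export
lcs_length <- function(a, b) {
  lcs_length_cpp(as.integer(a), as.integer(b))
}

#' @rdname lcs_length
#' @export
lcs_distance <- function(a, b) {
  length(a) + length(b) - 2 * lcs_length(a, b)
}

#' Deduplicate sequences with frequency weights
#'
#' Collapses identical state sequences, attaching their multiplicity as a
#' weight, so clustering is not biased by duplicates. Weights sum to the
#' cohort size.
#'
#' @param sequences Output of [build_state_sequences()].
#' @return A list with `seqs` (unique-sequence integer matrix), `weights`
#'   (multiplicities), and `map` (index of each patient's unique sequence).
#' @export
dedup_weight <- function(sequences) {
  m <- seq_matrix(sequences)
  key <- apply(m, 1, paste0, collapse = "")
  first <- !duplicated(key)
  ukey <- key[first]
  map <- match(key, ukey)
  list(seqs = m[first, , drop = FALSE],
       weights = as.numeric(tabulate(map, nbins = length(ukey))),
       map = map)
}

#' Pairwise LCS distance matrix over unique sequences
#'
#' @param sequences Output of [build_state_sequences()].
#' @return A list of class `posticu_distmatrix` with the unique sequences,
#'   their frequency weights, the patient-to-unique map, and the symmetric
#'   zero-diagonal LCS distance matrix `D`.
#' @export
sequence_distance_matrix <- function(sequences) {
  dw <- dedup_weight(sequences)
  D <- lcs_dist_matrix_cpp(dw$seqs)
  structure(list(seqs = dw$seqs, weights = dw$weights, map = dw$map, D = D),
            class = "posticu_distmatrix")
}

#' Hospital-free days over the follow-up window
#'
#' Counts the days in 1..`horizon` on which a patient is alive at day's end
#' and not in hospital: the day of death and all later days do not count, nor
#' does any day inside a readmission interval.
#'
#' @param events Event tibble.
#' @param patients Patient tibble or id vector.
#' @param horizon Window length in days.
#' @return Tibble with `patient_id` and `hospital_free_days`.
#' @export
hospital_free_days <- function(events, patients, horizon = 90) {
  ids <- if (is.character(patients)) patients else patients$patient_id
  death <- events |>
    filter(.data$event_type == "DEATH") |>
    select("patient_id", death_day = "day")
  alive_end <- rep(as.integer(horizon), length(ids))
  dmatch <- match(ids, death$patient_id)
  alive_end[!is.na(dmatch)] <-
    pmin(alive_end[!is.na(dmatch)], death$death_day[dmatch[!is.na(dmatch)]] - 1L)

  inp <- rep(0L, length(ids))
  re <- filter(events, .data$event_type == "READMIT")
  if (nrow(re)) {
    pidx <- match(re$patient_id, ids)
    len <- pmax(0L, pmin(re$end_day, alive_end[pidx]) - re$day + 1L)
    agg <- tapply(len, pidx, sum)
    inp[as.integer(names(agg))] <- as.integer(agg)
  }
  tibble(patient_id = ids,
         hospital_free_days = pmax(0L, alive_end - inp))
}

#' Weekly state-density table
#'
#' Proportion of patients in each state per week, overall or by cluster; the
#' tabular analogue of a state-density plot.
#'
#' @param sequences Output of [build_state_sequences()].
#' @param cluster Optional per-patient cluster labels (same order).
#' @return Tibble with `cluster` (if given), `week`, `state`, `proportion`.
#' @export
state_density <- function(sequences, cluster = NULL) {
  long <- sequences |>
    pivot_longer(starts_with("w"), names_to = "week", values_to = "code") |>
    mutate(week = as.integer(sub("^w", "", .data$week)),
           state = factor(state_levels[.data$code + 1L], levels = state_levels))
  if (!is.null(cluster)) {
    long$cluster <- rep(cluster, each = sum(startsWith(names(sequences), "w")))
    grp <- c("cluster", "week", "state")
  } else grp <- c("week", "state")
  long |>
    count(across(all_of(grp)), .drop = FALSE) |>
    group_by(across(all_of(setdiff(grp, "state")))) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()
}
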