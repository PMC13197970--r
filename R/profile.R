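#' Per-patient 90-day outcome summaries
#'
#' Derives, per patient: first-contact PCP follow-up within 30 days (the
#' mediator), 90-day indicators and counts for PCP visits, ED visits and
#' readmissions, death and its day, and hospital-free days.
#'
#' @param events Event tibble.
#' @param patients Patient tibble.
#' @param horizon Follow-up window in days.
#' @return Tibble with one row per patient.
#' @export
patient_outcomes <- function(events, patients, horizon = 90) {
  ids <- patients$patient_id
  ev <- filter(events, .data$day >= 1, .data$day <= horizon)

  cnt <- function(type, cutoff = horizon) {
    x <- ev |>
      filter(.data$event_type == type, .data$day <= cutoff) |>
      count(.data$patient_id)
    out <- rep(0L, length(ids))
    out[match(x$patient_id, ids)] <- x$n
    out
  }
  first_day <- function(types, cutoff = horizon) {
    out <- rep(NA_integer_, length(ids))
    x <- filter(ev, .data$event_type %in% types, .data$day <= cutoff)
    if (nrow(x) == 0) return(out)
    x <- summarise(group_by(x, .data$patient_id), d = min(.data$day),
                   .groups = "drop")
    out[match(x$patient_id, ids)] <- x$d
    out
  }

  n_pcp <- cnt("PCP"); n_ed <- cnt("ED"); n_readmit <- cnt("READMIT")
  death_day <- first_day("DEATH")
  first_contact <- first_day(c("PCP", "ED", "READMIT"), cutoff = 30)
  first_pcp30 <- first_day("PCP", cutoff = 30)
  first_acute30 <- first_day(c("ED", "READMIT"), cutoff = 30)
  # first-contact rule: PCP strictly before any acute contact (and any death)
  pcp30_first <- !is.na(first_pcp30) &
    (is.na(first_acute30) | first_pcp30 < first_acute30) &
    (is.na(death_day) | first_pcp30 < death_day)

  hfd <- hospital_free_days(events, patients, horizon)
  tibble(
    patient_id = ids,
    pcp30_first = pcp30_first,
    first_contact_day = first_contact,
    pcp90 = n_pcp > 0L, n_pcp = n_pcp,
    ed90 = n_ed > 0L, n_ed = n_ed,
    readmit90 = n_readmit > 0L, n_readmit = n_readmit,
    death90 = !is.na(death_day), death_day = death_day,
    hospital_free_days = hfd$hospital_free_days
  )
}

#' Overrepresentation index by cluster
#'
#' For a patient group g and cluster c, the global overrepresentation index is
#' `OI(g, c) = (n_gc / n_c) / (n_g / N)`: the group's share within the cluster
#' relative to its cohort prevalence; 1 means proportional representation.
#' With a `stratum` (e.g. a DRG category), all counts are restricted to the
#' stratum before forming the same ratio. For every group the cluster-share-
#' weighted mean of the global OI equals 1 exactly. Empty clusters yield `NA`.
#'
#' @param data Tibble with one row per patient.
#' @param cluster,group Column names (strings) holding cluster labels and the
#'   group variable (logical or factor; every level is reported).
#' @param stratum Optional column name of a stratifying variable.
#' @return Tibble with counts and `oi` per (group level, cluster) and, when
#'   `stratum` is given, per stratum.
#' @export
overrepresentation_index <- function(data, cluster, group, stratum = NULL) {
  if (anyNA(data[[group]])) stop("group must be defined for all patients", call. = FALSE)
  oi_one <- function(df) {
    g <- df[[group]]
    lv <- if (is.logical(g)) c(TRUE, FALSE) else levels(factor(g))
    N <- nrow(df)
    cl_tab <- count(df, cluster = .data[[cluster]], name = "n_cluster")
    out <- list()
    for (l in lv) {
      n_g <- sum(g == l)
      both <- df |>
        filter(.data[[group]] == l) |>
        count(cluster = .data[[cluster]], name = "n_both")
      tab <- left_join(cl_tab, both, by = "cluster") |>
        mutate(n_both = tidyr::replace_na(.data$n_both, 0L),
               group = as.character(l), n_group = n_g, n_total = N,
               oi = if (n_g > 0)
                 (.data$n_both / .data$n_cluster) / (n_g / N)
               else NA_real_)
      out[[as.character(l)]] <- tab
    }
    bind_rows(out)
  }
  if (is.null(stratum)) {
    oi_one(data) |> relocate("group")
  } else {
    data |>
      group_by(.data[[stratum]]) |>
      group_modify(~ oi_one(.x)) |>
      ungroup() |>
      relocate(all_of(stratum), "group")
  }
}

#' Cluster profile table
#'
#' Per-cluster patient characteristics and 90-day outcomes: size, median age,
#' VA share, comorbidity and severity summaries, lengths of stay, outcome
#' proportions and counts, median time to death among decedents, and median
#' hospital-free days.
#'
#' @param cluster Per-patient cluster labels.
#' @param patients Patient tibble.
#' @param events Event tibble.
#' @return One row per cluster.
#' @export
cluster_profile <- function(cluster, patients, events) {
  out <- patient_outcomes(events, patients)
  df <- bind_cols(patients, select(out, -"patient_id"))
  df$cluster <- cluster
  df |>
    group_by(.data$cluster) |>
    summarise(
      n = n(),
      median_age = median(.data$age),
      va_share = mean(.data$hospital_type == 1),
      median_cci = median(.data$cci),
      median_drg_weight = median(.data$drg_weight),
      median_hosp_los = median(.data$hosp_los),
      median_icu_los = median(.data$icu_los),
      pcp90 = mean(.data$pcp90),
      median_n_pcp = median(.data$n_pcp),
      ed90 = mean(.data$ed90),
      median_n_ed = median(.data$n_ed),
      readmit90 = mean(.data$readmit90),
      median_n_readmit = median(.data$n_readmit),
      death90 = mean(.data$death90),
      median_time_to_death = median(.data$death_day[.data$death90]),
      median_hospital_free_days = median(.data$hospital_free_days),
      .groups = "drop"
    )
}
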