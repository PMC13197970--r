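#' Silhouette profile plot for cluster-number selection
#'
#' @param object A `posticu_kselect` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posticu_kselect <- function(object, ...) {
  ggplot(object$silhouette, aes(x = .data$k, y = .data$avg_silhouette)) +
    geom_line() +
    geom_point() +
    geom_point(data = filter(object$silhouette, .data$k == object$best_k),
               colour = "red", size = 3) +
    labs(x = "number of clusters k", y = "weighted average silhouette width",
         title = "Cluster-number selection") +
    theme_minimal()
}

#' Weekly state-density plot
#'
#' Stacked proportions of patients in each care state per week, optionally
#' facetted by trajectory cluster; the plot analogue of [state_density()].
#'
#' @param density Output of [state_density()].
#' @return A ggplot.
#' @export
plot_state_density <- function(density) {
  p <- ggplot(density, aes(x = .data$week, y = .data$proportion,
                           fill = .data$state)) +
    geom_area(position = "stack") +
    scale_fill_manual(values = c(HOME = "grey85", PCP = "#2c7fb8",
                                 ED = "#fec44f", READMIT = "#d95f0e",
                                 DEAD = "grey25")) +
    labs(x = "week after discharge", y = "proportion of patients") +
    theme_minimal()
  if ("cluster" %in% names(density)) p <- p + facet_wrap(~cluster)
  p
}

#' Forest-style plot of standardized risks
#'
#' @param object A `posticu_stdrisks` tibble.
#' @param ... Unused.
#' @return A ggplot of VA and community absolute risks with bootstrap CIs.
#' @export
autoplot.posticu_stdrisks <- function(object, ...) {
  long <- object |>
    pivot_longer(c("risk_va", "risk_ccn"), names_to = "group",
                 values_to = "risk") |>
    mutate(lo = ifelse(.data$group == "risk_va", .data$risk_va_lo, .data$risk_ccn_lo),
           hi = ifelse(.data$group == "risk_va", .data$risk_va_hi, .data$risk_ccn_hi),
           group = ifelse(.data$group == "risk_va", "VA", "Community"))
  ggplot(long, aes(x = factor(.data$t), y = .data$risk, colour = .data$group)) +
    geom_pointrange(aes(ymin = .data$lo, ymax = .data$hi),
                    position = position_dodge(width = 0.4)) +
    labs(x = "days after discharge", y = "standardized absolute risk (%)") +
    theme_minimal()
}

#' Posterior interval plot of mediation effects
#'
#' @param object A `posticu_mediation` object.
#' @param ... Unused.
#' @return A ggplot of posterior means and 95% credible intervals.
#' @export
autoplot.posticu_mediation <- function(object, ...) {
  ggplot(object$effects,
         aes(x = .data$mean, y = stats::reorder(.data$effect, .data$mean))) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_pointrange(aes(xmin = .data$lo, xmax = .data$hi)) +
    labs(x = "effect on 90-day readmission risk (percentage points)",
         y = NULL) +
    theme_minimal()
}
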