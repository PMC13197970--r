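#' Tidy a Fine-Gray fit
#'
#' One row per coefficient with the subdistribution hazard ratio and a 95%
#' confidence interval from the facility-clustered sandwich standard errors
#' (model-based when no clustering was requested).
#'
#' @param x A `posticu_fg` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (log SHR), `std.error`, `shr`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.posticu_fg <- function(x, ...) {
  V <- x$vcov_cluster %||% x$vcov_model
  se <- sqrt(diag(V))
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = se, shr = exp(unname(x$coef)),
         conf.low = exp(unname(x$coef) - 1.96 * se),
         conf.high = exp(unname(x$coef) + 1.96 * se))
}

#' @rdname tidy.posticu_fg
#' @export
glance.posticu_fg <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
         iter = x$iter, converged = x$converged)
}

#' Tidy a Bayesian logistic posterior
#'
#' @param x A `posticu_blogit` object.
#' @param ... Unused.
#' @return Posterior mean, SD, 95% credible interval and diagnostics per
#'   parameter (plus the facility intercept SD).
#' @export
tidy.posticu_blogit <- function(x, ...) {
  qs <- apply(x$beta, 2, quantile, c(0.025, 0.975))
  out <- tibble(parameter = colnames(x$beta),
                mean = colMeans(x$beta), sd = apply(x$beta, 2, sd),
                conf.low = qs[1, ], conf.high = qs[2, ]) |>
    left_join(x$diagnostics, by = "parameter")
  bind_rows(out, tibble(parameter = "facility_sd", mean = mean(x$sigma),
                        sd = sd(x$sigma),
                        conf.low = unname(quantile(x$sigma, 0.025)),
                        conf.high = unname(quantile(x$sigma, 0.975)),
                        rhat = NA_real_, ess = NA_real_))
}

#' Tidy / glance a mediation result
#'
#' @param x A `posticu_mediation` object.
#' @param ... Unused.
#' @return `tidy()`: posterior mean and 95% credible interval per effect (in
#'   percentage points). `glance()`: worst-case convergence diagnostics and
#'   posterior-predictive rate gaps.
#' @export
tidy.posticu_mediation <- function(x, ...) x$effects

#' @rdname tidy.posticu_mediation
#' @export
glance.posticu_mediation <- function(x, ...) {
  tibble(max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         min_ess = min(x$diagnostics$ess, na.rm = TRUE),
         ppc_gap_mediator = abs(x$ppc$posterior_mean_rate[1] - x$ppc$observed_rate[1]),
         ppc_gap_outcome = abs(x$ppc$posterior_mean_rate[2] - x$ppc$observed_rate[2]))
}

#' Tidy a PAM clustering solution
#'
#' @param x A `posticu_pam` object.
#' @param ... Unused.
#' @return One row per cluster: medoid index, unique-sequence count and total
#'   frequency weight.
#' @export
tidy.posticu_pam <- function(x, ...) {
  tibble(cluster = seq_along(x$medoids), medoid = x$medoids) |>
    mutate(n_unique = map_dbl(.data$medoid, ~ sum(x$assignment == .x)),
           weight = map_dbl(.data$medoid,
                            ~ sum(x$weights[x$assignment == .x])))
}

#' @export
print.posticu_fg <- function(x, ...) {
  cat(sprintf("Fine-Gray subdistribution hazard fit: %d subjects, %d events, %s\n",
              x$n, x$n_event,
              if (x$converged) sprintf("converged in %d iterations", x$iter)
              else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' @export
print.posticu_mediation <- function(x, ...) {
  cat("Bayesian mediation natural-effect decomposition (percentage points)\n")
  print(x$effects)
  invisible(x)
}

#' @export
print.posticu_pam <- function(x, ...) {
  cat(sprintf("Weighted PAM: k = %d, objective = %.3f, avg silhouette = %.3f\n",
              x$k, x$objective, x$avg_silhouette))
  invisible(x)
}

#' @export
print.posticu_kselect <- function(x, ...) {
  cat(sprintf("Cluster-number selection: best k = %d by average silhouette\n",
              x$best_k))
  print(x$silhouette)
  invisible(x)
}
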