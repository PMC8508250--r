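#' Kaplan-Meier estimate per risk group
#'
#' Product-limit estimator with right censoring, via [survival::survfit()].
#'
#' @param data Tibble with time, event and group columns.
#' @param time,event,group Column names: follow-up time (months), event
#'   indicator (1 = distant recurrence observed), risk group label.
#' @return Object of class `edr_km`: tidy step-function tibble (`group`,
#'   `time`, `n_risk`, `n_event`, `survival`) plus the underlying `survfit`.
#' @export
km_estimate <- function(data, time = "time_months", event = "event",
                        group = "risk_group") {
  data <- as_tibble(data)
  groups <- unique(data[[group]])
  if (any(table(data[[group]]) < 1) || length(groups) < 1) {
    abort("each group needs at least one subject")
  }
  sf <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ data[[group]])
  if (length(groups) == 1) {
    strata_lab <- rep(groups, length(sf$time))
  } else {
    strata_lab <- rep(sub("^.*=", "", names(sf$strata)), sf$strata)
  }
  steps <- tibble(group = strata_lab, time = sf$time, n_risk = sf$n.risk,
                  n_event = sf$n.event, n_censor = sf$n.censor,
                  survival = sf$surv)
  structure(list(steps = steps, survfit = sf), class = "edr_km")
}

#' Survival probability at a time point
#'
#' Reads the KM curve at `t` with the right-continuous convention (the value
#' just after any event at exactly `t`).
#'
#' @param km An `edr_km` object.
#' @param t Time (months).
#' @return Tibble `group`, `survival`.
#' @export
km_survival_at <- function(km, t = 12) {
  km$steps |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      survival = if (any(.data$time <= t)) {
        .data$survival[max(which(.data$time <= t))]
      } else 1,
      .groups = "drop")
}

#' Log-rank test between risk groups
#'
#' Standard two-group log-rank chi-square (1 df), via
#' [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @return List `statistic`, `p_value`, `observed`, `expected`.
#' @export
log_rank <- function(data, time = "time_months", event = "event",
                     group = "risk_group") {
  data <- as_tibble(data)
  if (length(unique(data[[group]])) != 2) abort("exactly two groups required")
  if (sum(data[[event]]) == 0) {
    abort("log-rank undefined with zero events", class = "edrisk_degenerate_outcome")
  }
  sd_ <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ data[[group]])
  list(statistic = unname(sd_$chisq),
       p_value = pchisq(unname(sd_$chisq), df = 1, lower.tail = FALSE),
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Hazard ratio of the high-risk group
#'
#' Univariable Cox proportional-hazards fit on the binary risk-group
#' indicator (Efron tie handling); HR is `exp(coef)` for `high` vs `low`,
#' with a Wald 95% CI. When one group has no events (monotone likelihood),
#' the in-package Firth-type penalized logistic is not applicable, so the
#' Cox fit is rerun with a small ridge penalty and flagged.
#'
#' @inheritParams km_estimate
#' @return List `hr`, `ci_low`, `ci_high`, `p_value`, `penalized`.
#' @export
hazard_ratio <- function(data, time = "time_months", event = "event",
                         group = "risk_group") {
  data <- as_tibble(data)
  g <- factor(data[[group]], levels = c("low", "high"))
  if (any(is.na(g))) g <- factor(data[[group]])
  if (nlevels(droplevels(g)) != 2) abort("exactly two groups required")
  if (sum(data[[event]]) == 0) {
    abort("hazard ratio undefined with zero events",
          class = "edrisk_degenerate_outcome")
  }
  events_per_group <- tapply(data[[event]], g, sum)
  monotone <- any(events_per_group == 0)
  df <- data.frame(t = data[[time]], e = data[[event]], g = g)
  fit <- if (!monotone) {
    survival::coxph(survival::Surv(t, e) ~ g, data = df, ties = "efron")
  } else {
    warn("no events in one group; using ridge-penalized Cox fit")
    survival::coxph(survival::Surv(t, e) ~ survival::ridge(as.numeric(g == levels(g)[2]), theta = 1),
                    data = df, ties = "efron")
  }
  cf <- coef(fit)[1]
  se <- sqrt(diag(vcov(fit)))[1]
  z <- qnorm(0.975)
  list(hr = unname(exp(cf)),
       ci_low = unname(exp(cf - z * se)),
       ci_high = unname(exp(cf + z * se)),
       p_value = unname(2 * pnorm(-abs(cf / se))),
       penalized = monotone)
}

#' Stratified survival evaluation of a dichotomized prognostic index
#'
#' Bundles the KM curves, the log-rank test, the Cox hazard ratio and the
#' 12-month survival per group for a cohort already labelled by the frozen
#' model cutoff.
#'
#' @inheritParams km_estimate
#' @param horizon Months at which to read group survival (12 = the early
#'   distant recurrence horizon).
#' @return Object of class `edr_stratification`.
#' @export
evaluate_stratification <- function(data, time = "time_months",
                                    event = "event", group = "risk_group",
                                    horizon = 12) {
  km <- km_estimate(data, time, event, group)
  lr <- log_rank(data, time, event, group)
  hr <- hazard_ratio(data, time, event, group)
  s12 <- km_survival_at(km, horizon)
  structure(list(km = km, log_rank = lr, hazard_ratio = hr,
                 survival_at_horizon = s12, horizon = horizon,
                 n = nrow(as_tibble(data))),
            class = "edr_stratification")
}

#' @export
print.edr_stratification <- function(x, ...) {
  cat("<edr_stratification> n = ", x$n, "\n",
      "log-rank chi-sq = ", round(x$log_rank$statistic, 3), ", p = ",
      signif(x$log_rank$p_value, 3), "\n",
      "HR (high vs low) = ", round(x$hazard_ratio$hr, 3), " [",
      round(x$hazard_ratio$ci_low, 3), ", ",
      round(x$hazard_ratio$ci_high, 3), "]\n", sep = "")
  s <- x$survival_at_horizon
  for (i in seq_len(nrow(s))) {
    cat("  S(", x$horizon, "m | ", s$group[i], ") = ",
        round(s$survival[i], 3), "\n", sep = "")
  }
  invisible(x)
}
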