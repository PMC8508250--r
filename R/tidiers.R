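#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted prognostic logistic model
#'
#' @param x An `edr_logistic`.
#' @param ... Unused.
#' @return One row per term: estimate, std.error, p.value, odds ratio and CI.
#' @export
tidy.edr_logistic <- function(x, ...) {
  x$terms |>
    dplyr::rename(estimate = "coefficient", std.error = "se",
                  p.value = "p_value")
}

#' @rdname tidy.edr_logistic
#' @export
glance.edr_logistic <- function(x, ...) {
  tibble(n = x$n, n_variables = length(x$variables),
         overall_fit_p = x$overall_fit_p, training_auc = x$training_auc,
         logLik = x$loglik, method = x$method,
         cutoff = x$cutoff %||% NA_real_)
}

#' Tidy an ICC robustness report
#'
#' @param x An `edr_icc_report`.
#' @param ... Unused.
#' @export
tidy.edr_icc_report <- function(x, ...) as_tibble(x)

#' @rdname tidy.edr_icc_report
#' @export
glance.edr_icc_report <- function(x, ...) {
  tibble(n_features = nrow(x), n_pass = sum(x$pass),
         pass_rate = mean(x$pass), n_cases = attr(x, "n_cases"),
         n_readers = attr(x, "n_readers"), threshold = attr(x, "threshold"))
}

#' Tidy a bootstrap ranking
#'
#' @param x An `edr_bootstrap_ranking`.
#' @param ... Unused.
#' @export
tidy.edr_bootstrap_ranking <- function(x, ...) as_tibble(x)

#' @rdname tidy.edr_bootstrap_ranking
#' @export
glance.edr_bootstrap_ranking <- function(x, ...) {
  tibble(B = attr(x, "B"), alpha = attr(x, "alpha"),
         n_candidates = nrow(x), n_selected = sum(x$selected),
         n_redrawn = attr(x, "n_redrawn"),
         n_separated = attr(x, "n_separated"))
}

#' Tidy a stratified survival evaluation
#'
#' @param x An `edr_stratification`.
#' @param ... Unused.
#' @return The KM step table.
#' @export
tidy.edr_stratification <- function(x, ...) x$km$steps

#' @rdname tidy.edr_stratification
#' @export
glance.edr_stratification <- function(x, ...) {
  s <- tidyr::pivot_wider(x$survival_at_horizon, names_from = "group",
                          values_from = "survival",
                          names_prefix = "surv_horizon_")
  dplyr::bind_cols(
    tibble(n = x$n, logrank_chisq = x$log_rank$statistic,
           logrank_p = x$log_rank$p_value, hr = x$hazard_ratio$hr,
           hr_low = x$hazard_ratio$ci_low, hr_high = x$hazard_ratio$ci_high),
    s)
}
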