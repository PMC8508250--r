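#' Specify a simulated surgical cohort
#'
#' Patients carry a log-normal CA19.9 serum level (default median ~40 U/mL,
#' matching the cohort tables this pipeline is patterned on), a binary
#' radiological-necrosis flag (default prevalence 0.18), optional radiomic
#' feature values supplied at simulation time, and an early-distant-recurrence
#' (EDR) outcome drawn from a logistic model with the given coefficients.
#' Default coefficients are the combined-model values of the reference
#' analysis (CA19.9 0.000964 per U/mL, necrosis 0.86465, surface-to-volume
#' ratio -2.8972 per 1/mm); when `intercept` is `NULL` it is calibrated once,
#' by Monte Carlo over the covariate distribution, so the marginal EDR rate
#' equals `target_rate` (default 26.5%).
#'
#' Event times are exponential conditional on the EDR label: EDR cases recur
#' before 12 months (truncated exponential, mean 6), non-EDR cases have an
#' event or censoring time of at least 12 months, truncated at
#' `followup_max_months`.
#'
#' @param n_patients Cohort size.
#' @param true_coefficients Named vector of non-intercept logistic
#'   coefficients; names must be `ca199_u_ml`, `necrosis`, or columns of the
#'   feature table passed to [simulate_cohort()].
#' @param intercept Logistic intercept, or `NULL` to calibrate to
#'   `target_rate`.
#' @param target_rate Marginal EDR probability used when calibrating.
#' @param ca199_log_mean,ca199_log_sd Log-scale parameters of CA19.9.
#' @param necrosis_prevalence Probability of radiological necrosis.
#' @param followup_max_months Administrative censoring time.
#' @param censoring_rate Probability that a non-EDR patient is censored
#'   before any late event.
#' @param seed Integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 147,
                            true_coefficients = c(ca199_u_ml = 0.000964,
                                                  necrosis = 0.86465,
                                                  morph.surf_to_vol_ratio = -2.8972),
                            intercept = NULL,
                            target_rate = 0.265,
                            ca199_log_mean = 3.7,
                            ca199_log_sd = 1.3,
                            necrosis_prevalence = 0.18,
                            followup_max_months = 36,
                            censoring_rate = 0.15,
                            seed = 1L) {
  stopifnot(n_patients >= 1)
  if (necrosis_prevalence < 0 || necrosis_prevalence > 1) {
    abort("necrosis_prevalence must be in [0, 1]")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("censoring_rate must be in [0, 1)")
  }
  assert_scalar_pos(followup_max_months, "followup_max_months")
  structure(list(n_patients = as.integer(n_patients),
                 true_coefficients = true_coefficients,
                 intercept = intercept, target_rate = target_rate,
                 ca199_log_mean = ca199_log_mean, ca199_log_sd = ca199_log_sd,
                 necrosis_prevalence = necrosis_prevalence,
                 followup_max_months = followup_max_months,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# linear predictor without intercept for a covariate tibble
cohort_linear_predictor <- function(coefs, covars) {
  lp <- numeric(nrow(covars))
  for (v in names(coefs)) lp <- lp + coefs[[v]] * as.numeric(covars[[v]])
  lp
}

# Clinical covariates (CA19.9, necrosis) are generated unless the supplied
# feature table already carries them; any other coefficient name must resolve
# to a feature-table column.
draw_covariates <- function(spec, n, feature_values) {
  fv <- if (is.null(feature_values)) NULL else as_tibble(feature_values)
  rows <- NULL
  if (!is.null(fv)) {
    rows <- if (nrow(fv) == n) seq_len(n) else
      sample.int(nrow(fv), n, replace = TRUE)
  }
  vars <- union(names(spec$true_coefficients), c("ca199_u_ml", "necrosis"))
  cols <- list()
  for (v in vars) {
    cols[[v]] <- if (!is.null(fv) && v %in% names(fv)) {
      as.numeric(fv[[v]][rows])
    } else if (v == "ca199_u_ml") {
      rlnorm(n, spec$ca199_log_mean, spec$ca199_log_sd)
    } else if (v == "necrosis") {
      rbinom(n, 1, spec$necrosis_prevalence)
    } else {
      abort(paste("unknown variable in coefficients:", v),
            class = "edrisk_config_error")
    }
  }
  as_tibble(cols)
}

#' Calibrate the logistic intercept to a marginal event rate
#'
#' Finds `B0` such that the expected EDR probability over the covariate
#' distribution equals `target_rate`, by Monte Carlo integration (fixed
#' internal seed derived from the spec seed) and monotone root finding.
#'
#' @param spec A [cohort_sim_spec()].
#' @param feature_values Optional feature tibble used for radiomic
#'   covariates.
#' @param n_mc Monte Carlo sample size.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(spec, feature_values = NULL, n_mc = 20000) {
  set.seed(child_seed(spec$seed, "calibrate"))
  covars <- draw_covariates(spec, n_mc, feature_values)
  lp <- cohort_linear_predictor(spec$true_coefficients, covars)
  f <- function(b0) mean(plogis(b0 + lp)) - spec$target_rate
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-8)$root
}

#' Simulate a cohort from a specification
#'
#' @param spec A [cohort_sim_spec()].
#' @param feature_values Optional tibble supplying radiomic covariates named
#'   in the coefficients (one row per patient, or rows resampled when sizes
#'   differ).
#' @return Tibble with one row per patient: `patient_id`, covariates,
#'   `p_edr` (true event probability), `edr`, `time_months`, `event`.
#' @examples
#' spec <- cohort_sim_spec(n_patients = 50,
#'                         true_coefficients = c(ca199_u_ml = 0.001),
#'                         seed = 7)
#' cohort <- simulate_cohort(spec)
#' mean(cohort$edr)
#' @export
simulate_cohort <- function(spec, feature_values = NULL) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  b0 <- spec$intercept
  if (is.null(b0)) b0 <- calibrate_intercept(spec, feature_values)
  n <- spec$n_patients
  set.seed(child_seed(spec$seed, "cohort"))
  covars <- draw_covariates(spec, n, feature_values)
  lp <- b0 + cohort_linear_predictor(spec$true_coefficients, covars)
  p <- plogis(lp)
  edr <- rbinom(n, 1, p)

  # truncated-exponential event times conditional on the EDR label
  t_event <- numeric(n)
  event <- integer(n)
  u <- runif(n)
  rate_edr <- 1 / 6
  is_edr <- edr == 1
  t_event[is_edr] <- -log(1 - u[is_edr] * (1 - exp(-12 * rate_edr))) / rate_edr
  event[is_edr] <- 1L
  rate_late <- 1 / 12
  t_late <- 12 + rexp(sum(!is_edr), rate_late)
  censored <- runif(sum(!is_edr)) < spec$censoring_rate
  t_late_obs <- pmin(t_late, spec$followup_max_months)
  ev_late <- as.integer(!censored & t_late < spec$followup_max_months)
  t_late_obs[censored] <- 12 + (t_late_obs[censored] - 12) * runif(sum(censored))
  t_event[!is_edr] <- t_late_obs
  event[!is_edr] <- ev_late
  tibble(patient_id = sprintf("pt%03d", seq_len(n))) |>
    dplyr::bind_cols(covars) |>
    dplyr::mutate(p_edr = p, edr = edr, time_months = t_event,
                  event = event, intercept_used = b0)
}
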