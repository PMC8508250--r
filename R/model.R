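#' Backward multivariable logistic model with a variable cap
#'
#' Fits a logistic regression on the supplied candidates and removes, one at
#' a time, the variable with the worst Wald p-value until all remaining
#' p-values are below `p_retain`; if more than `max_vars` survive, removal
#' continues (worst p first) until the cap holds. The cap (3 by default)
#' mirrors the events-per-variable constraint of small surgical cohorts. If
#' no variable survives, an intercept-only model is returned with a warning.
#' Separated fits fall back to Firth-type penalization.
#'
#' @param data Tibble containing `outcome` and the candidate columns.
#' @param outcome Name of the binary outcome column (0/1).
#' @param candidates Character vector of candidate column names.
#' @param p_retain Wald p-value below which a variable is retained.
#' @param max_vars Maximum number of non-intercept variables.
#' @return An object of class `edr_logistic`: terms table (coefficient,
#'   Wald p, OR with 95% CI), intercept, overall-fit likelihood-ratio p
#'   against the intercept-only model, training AUC of the fitted index, and
#'   the fitting metadata.
#' @export
fit_backward_logistic <- function(data, outcome, candidates, p_retain = 0.20,
                                  max_vars = 3) {
  data <- as_tibble(data)
  y <- as.numeric(data[[outcome]])
  if (length(unique(y)) != 2) abort("outcome must contain both classes")
  missing_cand <- setdiff(candidates, names(data))
  if (length(missing_cand) > 0) {
    abort(paste("unknown candidates:", paste(missing_cand, collapse = ", ")),
          class = "edrisk_config_error")
  }
  current <- candidates
  fit <- NULL
  repeat {
    fit <- logistic_fit(data, y, current)
    if (length(current) == 0) break
    pv <- fit$p[-1]
    pv[!is.finite(pv)] <- 1
    worst <- which.max(pv)
    if (pv[worst] >= p_retain || length(current) > max_vars) {
      current <- current[-worst]
    } else {
      break
    }
  }
  if (length(current) == 0) {
    warn("no variable survived backward selection; returning intercept-only model")
    fit <- logistic_fit(data, y, character(0))
  }
  null_ll <- logistic_fit(data, y, character(0))$loglik
  lrt <- 2 * (fit$loglik - null_ll)
  overall_p <- if (length(current) > 0) {
    pchisq(max(lrt, 0), df = length(current), lower.tail = FALSE)
  } else {
    NA_real_
  }
  z <- qnorm(0.975)
  terms <- tibble(
    term = c("(Intercept)", current),
    coefficient = fit$coef,
    se = fit$se,
    p_value = fit$p,
    or = exp(fit$coef),
    or_low = exp(fit$coef - z * fit$se),
    or_high = exp(fit$coef + z * fit$se))
  p_train <- plogis(fit$eta)
  auc <- if (length(current) > 0) auc_mw(p_train, y) else 0.5
  structure(list(terms = terms, variables = current,
                 intercept = fit$coef[1],
                 coefficients = setNames(fit$coef[-1] %g0% numeric(0), current),
                 overall_fit_p = overall_p, loglik = fit$loglik,
                 training_auc = auc, n = length(y),
                 method = fit$method, p_retain = p_retain,
                 max_vars = max_vars, cutoff = NULL),
            class = "edr_logistic")
}

# single logistic fit (ML, Firth on separation) returning Wald stats.
# Covariates are standardized internally for numerical stability (features
# such as total energy span many orders of magnitude); estimates and
# standard errors are transformed back to the original scale, under which
# slope p-values are invariant.
logistic_fit <- function(data, y, vars) {
  Xraw <- cbind(`(Intercept)` = 1, as.matrix(as_tibble(data)[vars]))
  ctr <- c(0, if (length(vars) > 0) colMeans(Xraw[, -1, drop = FALSE]))
  scl <- c(1, if (length(vars) > 0) {
    pmax(apply(Xraw[, -1, drop = FALSE], 2, sd), 1e-300)
  })
  X <- sweep(sweep(Xraw, 2, ctr, "-"), 2, scl, "/")
  # linear map from standardized to raw parameterization: b_raw = Tmat b_std
  Tmat <- diag(1 / scl)
  Tmat[1, ] <- c(1, if (length(vars) > 0) -ctr[-1] / scl[-1])
  to_raw <- function(cf, Vi) {
    cf_raw <- drop(Tmat %*% cf)
    se_raw <- if (is.null(Vi)) rep(NA_real_, length(cf)) else
      sqrt(pmax(diag(Tmat %*% Vi %*% t(Tmat)), 0))
    list(coef = setNames(cf_raw, colnames(Xraw)), se = se_raw)
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  scale_ok <- TRUE
  if (!is.null(fit) && length(vars) > 0) {
    scale_ok <- all(abs(fit$coefficients[-1]) < 30)   # standardized scale
  }
  if (!is.null(fit) && fit$converged && !isTRUE(fit$boundary) &&
      fit$deviance > 1e-6 && scale_ok) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    Vi <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(Vi)) {
      cf <- fit$coefficients
      eta <- drop(X %*% cf)
      p <- plogis(eta)
      ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
      raw <- to_raw(cf, Vi)
      return(list(coef = raw$coef, se = raw$se,
                  p = 2 * pnorm(-abs(raw$coef / raw$se)),
                  eta = eta, loglik = ll, method = "ml"))
    }
  }
  ff <- firth_logistic(X, y)
  eta <- drop(X %*% ff$coef)
  pfit <- plogis(eta)
  w <- pmax(pfit * (1 - pfit), 1e-12)
  Vi <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  raw <- to_raw(ff$coef, Vi)
  list(coef = raw$coef, se = raw$se, p = 2 * pnorm(-abs(raw$coef / raw$se)),
       eta = eta, loglik = ff$loglik, method = "firth")
}

#' @export
print.edr_logistic <- function(x, ...) {
  cat("<edr_logistic> ", length(x$variables), " variable(s), n = ", x$n,
      ", training AUC = ", round(x$training_auc, 3), "\n", sep = "")
  print(as.data.frame(x$terms), digits = 4)
  if (!is.null(x$cutoff)) cat("risk cutoff (Youden):", signif(x$cutoff, 4), "\n")
  invisible(x)
}

#' Prognostic index of a fitted model
#'
#' The per-patient probability-scale index
#' `P = 1 / (1 + exp(-(B0 + sum(Bi * Xi))))` evaluated from the model's frozen
#' intercept and coefficients. Any missing model variable raises an error; no
#' silent imputation.
#'
#' @param model An `edr_logistic` fit.
#' @param newdata Tibble of covariates containing every model variable.
#' @return Numeric vector of P-index values in (0, 1).
#' @export
p_index <- function(model, newdata) {
  stopifnot(inherits(model, "edr_logistic"))
  newdata <- as_tibble(newdata)
  missing_vars <- setdiff(model$variables, names(newdata))
  if (length(missing_vars) > 0) {
    abort(paste("missing model variables:",
                paste(missing_vars, collapse = ", ")),
          class = "edrisk_missing_variable")
  }
  eta <- rep(model$intercept, nrow(newdata))
  for (v in model$variables) {
    eta <- eta + model$coefficients[[v]] * as.numeric(newdata[[v]])
  }
  plogis(eta)
}

#' Rank-based AUC (Mann-Whitney concordance)
#'
#' @param score Numeric risk scores.
#' @param outcome Binary outcomes (0/1).
#' @return AUC in `[0, 1]`; ties count 1/2.
#' @export
auc_mw <- function(score, outcome) {
  y <- as.numeric(outcome)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both outcome classes required")
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal cutoff and classification metrics
#'
#' Scans every threshold between consecutive distinct score values (plus the
#' two infinite extremes) and returns the cutoff maximizing the Youden index
#' `sensitivity + specificity - 1`. Ties are broken toward the cutoff with
#' higher specificity (fewer false high-risk labels). AUC comes from the
#' rank formulation ([auc_mw()]).
#'
#' @param p Numeric scores (e.g. P-index values).
#' @param outcome Binary outcomes (0/1); both classes must be present.
#' @return Object of class `edr_roc`: list with `cutoff`, `auc`, `youden`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, and the full `curve` tibble
#'   (one row per candidate threshold).
#' @export
youden_cutoff <- function(p, outcome) {
  y <- as.numeric(outcome)
  if (length(unique(y)) != 2) {
    abort("both outcome classes required", class = "edrisk_degenerate_outcome")
  }
  u <- sort(unique(p))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stats <- purrr::map(thr, function(t) {
    pred <- p > t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- n1 - tp; tn <- n0 - fp
    tibble(threshold = t, sensitivity = tp / n1, specificity = tn / n0,
           ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
           youden = tp / n1 + tn / n0 - 1)
  }) |> purrr::list_rbind()
  best <- stats |>
    dplyr::filter(.data$youden == max(.data$youden)) |>
    dplyr::arrange(dplyr::desc(.data$specificity)) |>
    dplyr::slice(1)
  structure(list(cutoff = best$threshold, auc = auc_mw(p, y),
                 youden = best$youden, sensitivity = best$sensitivity,
                 specificity = best$specificity, ppv = best$ppv,
                 npv = best$npv, curve = stats),
            class = "edr_roc")
}

#' @export
print.edr_roc <- function(x, ...) {
  cat("<edr_roc> AUC = ", round(x$auc, 3), ", cutoff = ",
      signif(x$cutoff, 4), " (Youden ", round(x$youden, 3), ")\n",
      "sens = ", round(x$sensitivity, 3), ", spec = ",
      round(x$specificity, 3), ", PPV = ", round(x$ppv, 3), ", NPV = ",
      round(x$npv, 3), "\n", sep = "")
  invisible(x)
}

#' Attach a Youden cutoff to a fitted model
#'
#' @param model An `edr_logistic` fit.
#' @param data Tibble with the model variables and the outcome (typically the
#'   training cohort).
#' @param outcome Name of the binary outcome column.
#' @return The model with `cutoff` and `roc` filled in.
#' @export
calibrate_cutoff <- function(model, data, outcome) {
  p <- p_index(model, data)
  roc <- youden_cutoff(p, as.numeric(as_tibble(data)[[outcome]]))
  model$cutoff <- roc$cutoff
  model$roc <- roc
  model
}

#' Dichotomize patients by the frozen model cutoff
#'
#' @param model An `edr_logistic` with a calibrated cutoff.
#' @param newdata Covariate tibble.
#' @return Tibble `p_index`, `risk_group` (`"high"` when P > cutoff).
#' @export
classify_risk <- function(model, newdata) {
  if (is.null(model$cutoff)) abort("model has no calibrated cutoff")
  p <- p_index(model, newdata)
  tibble(p_index = p,
         risk_group = dplyr::if_else(p > model$cutoff, "high", "low"))
}
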