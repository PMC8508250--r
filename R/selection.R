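#' Delineation-robustness ICC screen
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation — ICC(2,1) — per feature across readers' contours. Features
#' below `threshold` (default 0.80, the conventional high-agreement bar) are
#' flagged for exclusion; features whose between-case variance vanishes have
#' an undefined ICC and are excluded with a reason.
#'
#' @param reader_features Tibble in long-by-reader layout: columns `.case`,
#'   `.reader`, then one column per feature. Every reader must score every
#'   case.
#' @param threshold Minimum ICC to pass.
#' @return A tibble of class `edr_icc_report`: `feature`, `icc`, `pass`,
#'   `reason`, with attributes `n_cases`, `n_readers`, `threshold`.
#' @export
icc_screen <- function(reader_features, threshold = 0.80) {
  stopifnot(all(c(".case", ".reader") %in% names(reader_features)))
  feats <- setdiff(names(reader_features), c(".case", ".reader"))
  if (length(feats) == 0) abort("no feature columns")
  readers <- unique(reader_features$.reader)
  cases <- unique(reader_features$.case)
  if (length(readers) < 2 || length(cases) < 2) {
    abort("need >= 2 readers and >= 2 cases")
  }
  res <- purrr::map(feats, function(f) {
    m <- reader_features |>
      dplyr::select(dplyr::all_of(c(".case", ".reader", f))) |>
      tidyr::pivot_wider(names_from = ".reader", values_from = dplyr::all_of(f)) |>
      dplyr::select(-".case") |>
      as.matrix()
    if (anyNA(m)) abort(sprintf("incomplete reader grid for feature %s", f))
    icc <- icc21(m)
    tibble(feature = f, icc = icc,
           pass = !is.na(icc) && icc >= threshold,
           reason = if (is.na(icc)) "zero between-case variance" else
             if (icc >= threshold) NA_character_ else "icc below threshold")
  })
  out <- purrr::list_rbind(res)
  attr(out, "n_cases") <- length(cases)
  attr(out, "n_readers") <- length(readers)
  attr(out, "threshold") <- threshold
  class(out) <- c("edr_icc_report", class(out))
  out
}

# ICC(2,1) from two-way mean squares (cases x raters, single scores)
icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(den) || abs(den) < 1e-300 ||
      (msr < 1e-12 * max(abs(grand), 1)^2 + 1e-300 && mse < 1e-300 &&
       msc < 1e-300)) {
    return(NA_real_)
  }
  (msr - mse) / den
}

# univariate logistic Wald p (Firth fallback on separation); the covariate is
# standardized internally, under which the slope p-value is invariant
univariate_logistic_p <- function(x, y) {
  sx <- sd(x)
  if (!is.finite(sx) || sx == 0) {
    return(list(p = NA_real_, coef = NA_real_, method = "constant"))
  }
  z <- (x - mean(x)) / sx
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, z), y, family = binomial())),
    error = function(e) NULL)
  separated <- is.null(fit) || !fit$converged || isTRUE(fit$boundary) ||
    fit$deviance < 1e-6 || abs(fit$coefficients[2]) > 30
  if (!separated) {
    cf <- fit$coefficients[2]
    w <- fit$weights
    X <- cbind(1, z)
    XtWX <- crossprod(X * sqrt(w))
    se2 <- tryCatch(solve(XtWX)[2, 2], error = function(e) NA_real_)
    if (is.finite(se2) && se2 > 0) {
      return(list(p = 2 * pnorm(-abs(cf / sqrt(se2))), coef = cf / sx,
                  method = "wald"))
    }
  }
  ff <- firth_logistic(cbind(1, z), y)
  f0 <- firth_logistic(matrix(1, length(y), 1), y)
  lrt <- 2 * (ff$penalized_loglik - f0$penalized_loglik)
  list(p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
       coef = ff$coef[2] / sx, method = "firth_lrt")
}

# Firth-type penalized logistic regression (Jeffreys prior): Newton iteration
# on the modified score U*(b) = X'(y - p + h (1/2 - p))
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  b <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    XtWXinv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(XtWXinv)) break
    h <- rowSums((X %*% XtWXinv) * X) * w
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- XtWXinv %*% U
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  pll <- ll + 0.5 * determinant(crossprod(X * sqrt(w)))$modulus
  list(coef = b, loglik = ll, penalized_loglik = as.numeric(pll))
}

#' Spearman redundancy filter
#'
#' Clusters features whose absolute pairwise Spearman correlation exceeds
#' `threshold` (connected components of the redundancy graph; sign is
#' ignored, since anti-correlated duplicates carry the same information) and
#' keeps one representative per cluster: the feature with the smallest
#' univariate-logistic p against the outcome, ties broken by name. Constant
#' columns, for which rank correlation is undefined, are excluded with a
#' reason.
#'
#' @param features Tibble/data frame of numeric candidate columns (any
#'   `case` identifier column is ignored).
#' @param outcome Binary outcome vector (0/1), both classes present.
#' @param threshold Absolute Spearman correlation above which two features
#'   are redundant.
#' @return Tibble of class `edr_redundancy`: `feature`, `cluster`,
#'   `univariate_p`, `selected`, `reason`.
#' @export
redundancy_filter <- function(features, outcome, threshold = 0.70) {
  df <- dplyr::select(as_tibble(features), -dplyr::any_of("case"))
  y <- as.numeric(outcome)
  if (length(unique(y)) != 2) abort("outcome must contain both classes")
  if (nrow(df) != length(y)) abort("features/outcome length mismatch")
  feats <- names(df)
  is_const <- vapply(df, function(x) sd(x) == 0 || !all(is.finite(x)),
                     logical(1))
  active <- feats[!is_const]
  m <- as.matrix(df[active])
  rho <- suppressWarnings(cor(m, method = "spearman"))
  adj <- abs(rho) > threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  pvals <- vapply(active, function(f) univariate_logistic_p(df[[f]], y)$p,
                  numeric(1))
  out <- tibble(feature = active,
                cluster = as.integer(comp),
                univariate_p = pvals) |>
    dplyr::arrange(.data$cluster, .data$univariate_p, .data$feature) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(selected = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(reason = dplyr::if_else(.data$selected, NA_character_,
                                          "redundant with representative"))
  if (any(is_const)) {
    out <- dplyr::bind_rows(out, tibble(
      feature = feats[is_const], cluster = NA_integer_,
      univariate_p = NA_real_, selected = FALSE,
      reason = "constant column (correlation undefined)"))
  }
  out <- out[match(feats, out$feature), ]
  attr(out, "threshold") <- threshold
  class(out) <- c("edr_redundancy", class(out))
  out
}

#' Bootstrap-frequency variable ranking
#'
#' The training data are resampled with replacement `B` times; in each
#' resample every candidate is tested in its own univariate logistic
#' regression, and the candidate scores a hit when its Wald p-value is below
#' `alpha` (a Firth-penalized likelihood-ratio p is substituted when the
#' resample separates). Candidates are ranked by hit count; those significant
#' in more than half the resamples (`count > B/2`) are selected. Resamples in
#' which only one outcome class appears are redrawn (and counted in
#' `n_redrawn`).
#'
#' @param data Tibble with the candidate columns and the outcome.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate column names.
#' @param B Number of bootstrap resamples.
#' @param alpha Per-test significance level.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Tibble of class `edr_bootstrap_ranking`: `variable`, `count`,
#'   `frequency`, `median_p`, `selected`, ranked by count (ties: smaller
#'   median p, then name), with attributes `B`, `alpha`, `n_redrawn`,
#'   `n_separated`.
#' @export
bootstrap_rank <- function(data, outcome, candidates, B = 1000, alpha = 0.05,
                           seed = 1L) {
  data <- as_tibble(data)
  if (!outcome %in% names(data)) abort("outcome column not found")
  missing_cand <- setdiff(candidates, names(data))
  if (length(missing_cand) > 0) {
    abort(paste("unknown candidate variables:",
                paste(missing_cand, collapse = ", ")),
          class = "edrisk_config_error")
  }
  if (B < 1) abort("B must be >= 1")
  y <- as.numeric(data[[outcome]])
  X <- as.matrix(data[candidates])
  n <- length(y)
  set.seed(as.integer(seed))
  counts <- setNames(integer(length(candidates)), candidates)
  pmat <- matrix(NA_real_, B, length(candidates),
                 dimnames = list(NULL, candidates))
  n_redrawn <- 0L; n_separated <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    yb <- y[idx]
    for (j in seq_along(candidates)) {
      r <- univariate_logistic_p(X[idx, j], yb)
      if (r$method == "firth_lrt") n_separated <- n_separated + 1L
      pmat[b, j] <- r$p
      if (is.finite(r$p) && r$p < alpha) counts[j] <- counts[j] + 1L
    }
  }
  med_p <- apply(pmat, 2, median, na.rm = TRUE)
  out <- tibble(variable = candidates,
                count = as.integer(counts),
                frequency = counts / B,
                median_p = med_p,
                selected = counts > B / 2) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$median_p, .data$variable)
  attr(out, "B") <- B
  attr(out, "alpha") <- alpha
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "n_separated") <- n_separated
  class(out) <- c("edr_bootstrap_ranking", class(out))
  out
}
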