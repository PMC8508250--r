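#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_col geom_abline geom_hline labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Kaplan-Meier curves per risk group
#'
#' @param object An `edr_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edr_km <- function(object, ...) {
  steps <- object$steps |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, survival = 1), .x[c("time", "survival")])) |>
    dplyr::ungroup()
  ggplot(steps, aes(x = .data$time, y = .data$survival,
                    colour = .data$group)) +
    geom_step(linewidth = 0.8) +
    labs(x = "Months since surgery", y = "Distant-recurrence-free fraction",
         colour = "Risk group") +
    theme_minimal()
}

#' @export
autoplot.edr_stratification <- function(object, ...) {
  autoplot(object$km, ...) +
    labs(subtitle = sprintf("log-rank p = %.3g, HR = %.2f [%.2f, %.2f]",
                            object$log_rank$p_value, object$hazard_ratio$hr,
                            object$hazard_ratio$ci_low,
                            object$hazard_ratio$ci_high))
}

#' ROC curve with the Youden-optimal operating point
#'
#' @param object An `edr_roc` from [youden_cutoff()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edr_roc <- function(object, ...) {
  curve <- object$curve |> dplyr::arrange(dplyr::desc(.data$threshold))
  best <- curve[which.min(abs(curve$threshold - object$cutoff)), ]
  ggplot(curve, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    geom_point(data = best, colour = "red", size = 2) +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         subtitle = sprintf("AUC = %.3f, Youden cutoff = %.3g",
                            object$auc, object$cutoff)) +
    theme_minimal()
}

#' Bootstrap selection-frequency plot
#'
#' @param object An `edr_bootstrap_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edr_bootstrap_ranking <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(variable = factor(.data$variable,
                                    levels = rev(.data$variable)))
  ggplot(df, aes(x = .data$frequency, y = .data$variable,
                 fill = .data$selected)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    labs(x = sprintf("Fraction of %d bootstrap resamples with p < %.2g",
                     attr(object, "B"), attr(object, "alpha")),
         y = NULL, fill = "Selected") +
    theme_minimal()
}

#' ICC distribution plot
#'
#' @param object An `edr_icc_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edr_icc_report <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(family = sub("\\..*$", "", .data$feature))
  ggplot(df, aes(x = .data$icc, y = .data$family)) +
    geom_point(aes(colour = .data$pass), alpha = 0.6,
               position = ggplot2::position_jitter(height = 0.15, width = 0)) +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = 2) +
    labs(x = "ICC(2,1)", y = NULL, colour = "Robust") +
    theme_minimal()
}
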