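# ggplot2 visualisations of threshold searches, evaluation reports and
# score distributions.

#' Plot a threshold-search report
#'
#' C-statistic against the P-value threshold, with the feature count as the
#' secondary label.
#'
#' @param report Tibble with `threshold`, `n_features`, `cstat` (from
#'   [threshold_search()] or [select_best_ptrs()]; for the latter one line
#'   per tissue).
#' @return A ggplot object.
#' @export
plot_threshold_report <- function(report) {
  p <- ggplot2::ggplot(report,
                       ggplot2::aes(x = .data$threshold, y = .data$cstat)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "P-value threshold", y = "adjusted c-statistic") +
    ggplot2::theme_minimal()
  if ("tissue" %in% names(report)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$tissue)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$tissue))
  } else {
    p + ggplot2::geom_line() + ggplot2::geom_point()
  }
}

#' Forest plot of model c-statistics
#'
#' @param object A `risk_eval_report` from [evaluate_suite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_eval_report
#' @export
autoplot.risk_eval_report <- function(object, ...) {
  d <- object$cstats
  d$model <- stats::reorder(d$model, d$cstat)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cstat, y = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "c-statistic (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Score distribution by case status
#'
#' @param score A score vector.
#' @param cohort Cohort tibble with `case`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(score, cohort) {
  d <- dplyr::inner_join(cohort, score, by = "sample_id")
  d$value <- if ("standardized" %in% names(d)) d$standardized else d$raw
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  fill = factor(.data$case))) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "score", fill = "case") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
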