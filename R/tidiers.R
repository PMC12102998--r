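# broom-style tidiers for fitted objects and reports.

#' Tidy a fitted risk model
#'
#' @param x A `risk_model_fit`.
#' @param ... Unused.
#' @return Tibble of per-term estimates (log-odds for binary outcomes),
#'   standard errors, Wald statistics, P-values and 95% CIs.
#' @method tidy risk_model_fit
#' @export
tidy.risk_model_fit <- function(x, ...) {
  x$terms
}

#' @rdname tidy.risk_model_fit
#' @method glance risk_model_fit
#' @export
glance.risk_model_fit <- function(x, ...) {
  fit <- x$fit
  if (inherits(fit, "glm")) {
    tibble::tibble(n = length(fit$y), logLik = as.numeric(logLik(fit)),
                   aic = fit$aic, deviance = fit$deviance,
                   df_residual = fit$df.residual)
  } else {
    tibble::tibble(n = NA_integer_, logLik = NA_real_, aic = NA_real_,
                   deviance = NA_real_, df_residual = NA_real_)
  }
}

#' Tidy a c-statistic or a paired comparison
#'
#' @param x A `cstat` or `delta_cstat` row.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy cstat
#' @export
tidy.cstat <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.cstat
#' @method tidy delta_cstat
#' @export
tidy.delta_cstat <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy an evaluation report
#'
#' @param x A `risk_eval_report` from [evaluate_suite()].
#' @param ... Unused.
#' @return The per-model c-statistic tibble; the pairwise comparisons are
#'   available via `glance()`.
#' @method tidy risk_eval_report
#' @export
tidy.risk_eval_report <- function(x, ...) {
  x$cstats
}

#' @rdname tidy.risk_eval_report
#' @method glance risk_eval_report
#' @export
glance.risk_eval_report <- function(x, ...) {
  x$comparisons
}
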