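# Train/test splitting, covariate-adjusted c-statistics with DeLong or
# stratified-bootstrap confidence intervals, and paired ROC comparison.

#' Stratified train/test split
#'
#' Splits the cohort into train and test, stratified on case status, sex
#' and age quintile so the train fraction is maintained within each
#' stratum. Allocation uses largest-remainder rounding within each case
#' level, so the training case count deviates from its target only by
#' rounding. Strata smaller than 2 are merged with a neighbouring age bin
#' (same case/sex) and logged.
#'
#' @param cohort Cohort tibble with `case`, `sex`, `age`.
#' @param train_fraction Fraction assigned to train, in `(0, 1]`.
#' @param seed Integer seed for the within-stratum sampling.
#' @return The cohort with a `split` column (`"train"`/`"test"`).
#' @export
stratified_split <- function(cohort, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction > 1) {
    abort("stratified_split: train_fraction must be in (0, 1]")
  }
  if (train_fraction == 1) {
    warn("stratified_split: train_fraction = 1; test set is empty")
    cohort$split <- "train"
    return(cohort)
  }
  withr::local_seed(as.integer(seed))
  qs <- quantile(cohort$age, probs = seq(0.2, 0.8, 0.2), na.rm = TRUE)
  age_bin <- findInterval(cohort$age, qs) + 1L
  strat <- paste(cohort$case, cohort$sex, age_bin, sep = "|")
  # merge undersized strata into the nearest age bin of the same case/sex
  tab <- table(strat)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    inform(sprintf("stratified_split: merged %d undersized stratum(a)",
                   length(small)))
    for (s in small) {
      parts <- strsplit(s, "|", fixed = TRUE)[[1]]
      b <- as.integer(parts[3])
      nb <- if (b > 1) b - 1L else b + 1L
      strat[strat == s] <- paste(parts[1], parts[2], nb, sep = "|")
    }
  }
  split <- rep("test", nrow(cohort))
  for (cs in unique(cohort$case)) {
    rows_g <- which(cohort$case == cs)
    strata_g <- split(rows_g, strat[rows_g])
    targets <- vapply(strata_g, length, integer(1)) * train_fraction
    base <- floor(targets)
    total <- round(sum(targets))
    extra <- total - sum(base)
    frac <- targets - base
    bump <- order(frac, decreasing = TRUE)[seq_len(max(0, extra))]
    take <- base
    take[bump] <- take[bump] + 1L
    for (k in seq_along(strata_g)) {
      rows <- strata_g[[k]]
      split[sample(rows, min(take[k], length(rows)))] <- "train"
    }
  }
  cohort$split <- split
  cohort
}

# Mann-Whitney concordance (ties count 1/2) plus DeLong placement values,
# computed with midranks in O(n log n)
delong_placements <- function(pred, case) {
  x <- pred[case == 1]; y <- pred[case == 0]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) abort("concordance requires both classes")
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  theta <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(theta = theta, v10 = v10, v01 = v01, m = m, n = n)
}

# adjusted predictor shared by adjusted_cstat / delong_paired /
# evaluate_suite: fitted-probability convention (logistic model of the
# outcome on the score plus covariates), or residualisation of the score on
# the covariates. Coefficients are fitted on `train` rows when supplied
# (transport), else on the evaluation rows themselves.
adjusted_predictor <- function(score, cohort, covariates,
                               mode = c("fitted", "residual"),
                               train = NULL) {
  mode <- match.arg(mode)
  d <- dplyr::inner_join(cohort, score, by = "sample_id")
  if (nrow(d) == 0) abort("score and cohort share no samples")
  d$.score <- if ("standardized" %in% names(d)) d$standardized else d$raw
  covariates <- intersect(covariates, names(d))
  if (length(covariates) == 0) {
    return(list(data = d, pred = d$.score))
  }
  fit_data <- if (is.null(train)) d else {
    td <- dplyr::inner_join(train, score, by = "sample_id")
    td$.score <- if ("standardized" %in% names(td)) td$standardized else td$raw
    td
  }
  pred <- if (mode == "fitted") {
    fml <- as.formula(paste("case ~ .score +",
                            paste(covariates, collapse = " + ")))
    fit <- glm(fml, binomial(), fit_data)
    unname(predict(fit, newdata = d, type = "link"))
  } else {
    fml <- as.formula(paste(".score ~", paste(covariates, collapse = " + ")))
    fit <- lm(fml, fit_data)
    d$.score - unname(predict(fit, newdata = d))
  }
  list(data = d, pred = pred)
}

#' Covariate-adjusted c-statistic
#'
#' Computes the concordance (Mann-Whitney, ties count one half) of the
#' covariate-adjusted score against case status, with a 95% confidence
#' interval from DeLong's analytic variance (default) or a stratified
#' bootstrap. Adjustment follows the fitted-probability convention: the
#' predictor is the linear predictor of `case ~ score + covariates`
#' (equivalently its fitted probability); a residualisation mode is also
#' available. With `train` supplied, adjustment coefficients are fitted
#' there and transported.
#'
#' @param score A score vector (tibble with `sample_id` and `raw` or
#'   `standardized`).
#' @param cohort Cohort rows to evaluate on (must contain `case`).
#' @param covariates Covariate names; empty for unadjusted.
#' @param ci_method `"delong"`, `"bootstrap"`, or `"none"`.
#' @param mode Adjustment convention, `"fitted"` (default) or
#'   `"residual"`.
#' @param train Optional training rows for coefficient transport.
#' @param n_boot Stratified bootstrap resamples (default 10000).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row `cstat` tibble: estimate, ci_low, ci_high, method,
#'   n_cases, n_controls.
#' @export
#' @examples
#' sc <- new_score_vector(letters[1:4], c(2, 3, 1, 2.5), "PRS")
#' coh <- tibble::tibble(sample_id = letters[1:4], case = c(1, 1, 0, 0))
#' adjusted_cstat(sc, coh, character(0))$estimate # 0.75
adjusted_cstat <- function(score, cohort, covariates = default_covariates(),
                           ci_method = c("delong", "bootstrap", "none"),
                           mode = c("fitted", "residual"), train = NULL,
                           n_boot = 10000, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(unique(cohort$case)) < 2) {
    abort("adjusted_cstat: outcome must contain both classes")
  }
  ap <- adjusted_predictor(score, cohort, covariates, mode, train)
  pl <- delong_placements(ap$pred, ap$data$case)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(NA_real_, NA_real_)
  if (ci_method == "delong") {
    v <- var(pl$v10) / pl$m + var(pl$v01) / pl$n
    ci <- pl$theta + c(-1, 1) * zq * sqrt(v)
  } else if (ci_method == "bootstrap") {
    case_idx <- which(ap$data$case == 1)
    ctrl_idx <- which(ap$data$case == 0)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(case_idx, replace = TRUE),
               sample(ctrl_idx, replace = TRUE))
      delong_placements(ap$pred[idx], ap$data$case[idx])$theta
    }, numeric(1))
    ci <- unname(quantile(boots, c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2)))
  }
  out <- tibble::tibble(estimate = pl$theta,
                        ci_low = min(ci[1], pl$theta),
                        ci_high = max(ci[2], pl$theta),
                        method = ci_method,
                        n_cases = pl$m, n_controls = pl$n)
  class(out) <- c("cstat", class(out))
  out
}

#' Paired DeLong comparison of two (adjusted) scores
#'
#' Tests the difference of the two c-statistics on the same individuals,
#' with variance from the DeLong structural components (placement values)
#' accounting for the correlation of the scores. Swapping the scores
#' negates the difference and preserves the P-value.
#'
#' @param score1,score2 Score vectors over identical samples.
#' @param cohort Evaluation rows.
#' @param covariates Adjustment covariates.
#' @param mode,train As in [adjusted_cstat()].
#' @return A one-row `delta_cstat` tibble: c1, c2, delta, se, ci_low,
#'   ci_high, pvalue.
#' @export
delong_paired <- function(score1, score2, cohort,
                          covariates = default_covariates(),
                          mode = c("fitted", "residual"), train = NULL) {
  a1 <- adjusted_predictor(score1, cohort, covariates, mode, train)
  a2 <- adjusted_predictor(score2, cohort, covariates, mode, train)
  if (!identical(a1$data$sample_id, a2$data$sample_id)) {
    abort("delong_paired: scores must cover identical samples")
  }
  p1 <- delong_placements(a1$pred, a1$data$case)
  p2 <- delong_placements(a2$pred, a2$data$case)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / p1$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / p1$n
  delta <- p1$theta - p2$theta
  se <- sqrt(max(vd, 0))
  z <- if (se > 0) delta / se else 0
  out <- tibble::tibble(c1 = p1$theta, c2 = p2$theta, delta = delta, se = se,
                        ci_low = delta - 1.96 * se,
                        ci_high = delta + 1.96 * se,
                        pvalue = if (se > 0) 2 * pnorm(-abs(z)) else 1)
  class(out) <- c("delta_cstat", class(out))
  out
}

#' Evaluate a suite of risk models on the test set
#'
#' For each declared model family (a set of score names fitted jointly with
#' the covariates by logistic regression on the training rows), computes
#' the test-set c-statistic with a DeLong CI, and runs paired DeLong tests
#' among the requested comparisons.
#'
#' @param cohort Full cohort with `split`.
#' @param scores Named list of score vectors covering all samples.
#' @param families Named list; each element is a character vector of score
#'   names. Defaults to one family per single score.
#' @param covariates Adjustment covariates.
#' @param comparisons List of length-2 character vectors of family names to
#'   compare (default: all pairs).
#' @return A `risk_eval_report` list: `cstats` tibble (model, cstat,
#'   ci_low, ci_high, n_cases, n_controls) and `comparisons` tibble
#'   (model1, model2, delta, ci_low, ci_high, pvalue).
#' @export
evaluate_suite <- function(cohort, scores, families = NULL,
                           covariates = default_covariates(),
                           comparisons = NULL) {
  families <- families %||% setNames(as.list(names(scores)), names(scores))
  train <- dplyr::filter(cohort, .data$split == "train")
  test <- dplyr::filter(cohort, .data$split == "test")
  # family scores: linear predictor of the train-fit joint logistic model
  family_score <- function(members) {
    d_tr <- train; d_te <- test
    for (s in members) {
      val <- scores[[s]]
      col <- if ("standardized" %in% names(val)) val$standardized else val$raw
      v <- setNames(col, val$sample_id)
      d_tr[[paste0("s_", s)]] <- unname(v[d_tr$sample_id])
      d_te[[paste0("s_", s)]] <- unname(v[d_te$sample_id])
    }
    fml <- as.formula(paste("case ~",
                            paste(c(paste0("s_", members),
                                    intersect(covariates, names(d_tr))),
                                  collapse = " + ")))
    fit <- glm(fml, binomial(), d_tr)
    lp <- unname(predict(fit, newdata = d_te, type = "link"))
    new_score_vector(d_te$sample_id, lp, "family")
  }
  fam_scores <- lapply(families, family_score)
  cstats <- purrr::map_dfr(names(fam_scores), function(f) {
    cs <- adjusted_cstat(fam_scores[[f]], test, character(0))
    tibble::tibble(model = f, cstat = cs$estimate, ci_low = cs$ci_low,
                   ci_high = cs$ci_high, n_cases = cs$n_cases,
                   n_controls = cs$n_controls)
  })
  if (is.null(comparisons)) {
    nm <- names(fam_scores)
    comparisons <- if (length(nm) > 1) {
      utils::combn(nm, 2, simplify = FALSE)
    } else list()
  }
  comp <- purrr::map_dfr(comparisons, function(pr) {
    dc <- delong_paired(fam_scores[[pr[1]]], fam_scores[[pr[2]]], test,
                        character(0))
    tibble::tibble(model1 = pr[1], model2 = pr[2], delta = dc$delta,
                   ci_low = dc$ci_low, ci_high = dc$ci_high,
                   pvalue = dc$pvalue)
  })
  structure(list(cstats = cstats, comparisons = comp),
            class = "risk_eval_report")
}

#' @export
print.risk_eval_report <- function(x, ...) {
  cat("<risk_eval_report>\n")
  print(x$cstats)
  if (nrow(x$comparisons) > 0) {
    cat("pairwise DeLong comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}
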