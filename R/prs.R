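# Clumping-and-thresholding polygenic risk score: additive dosage scoring,
# maximal-AUC threshold search, standardisation.

#' Score a clumped-and-thresholded PRS
#'
#' `raw_i = sum over retained variants with P <= threshold of
#' beta_l * X_il`, with missing dosages mean-imputed per variant. When no
#' variant passes the threshold a zero score with `n_features = 0` is
#' returned with a warning.
#'
#' @param panel A `genotype_panel` (harmonised orientation with `stats`).
#' @param stats Summary statistics harmonised to the panel.
#' @param retained Clumped variant list (tibble with `id`, from [clump()]),
#'   or a character vector of ids.
#' @param p_threshold Inclusive P-value cutoff (default 1, all retained).
#' @return A `score_vector` of type "PRS".
#' @export
score_prs <- function(panel, stats, retained, p_threshold = 1) {
  ids <- if (is.character(retained)) retained else retained$id
  sel <- stats[stats$id %in% ids & stats$pvalue <= p_threshold, , drop = FALSE]
  sel <- sel[sel$id %in% panel$variants$id, , drop = FALSE]
  if (nrow(sel) == 0) {
    warn("score_prs: no variants pass the threshold; returning zero scores")
    return(new_score_vector(panel$samples, rep(0, length(panel$samples)),
                            "PRS", p_threshold, 0L))
  }
  X <- mean_impute(panel$dosages[, sel$id, drop = FALSE])
  raw <- unname(drop(X %*% sel$beta))
  new_score_vector(panel$samples, raw, "PRS", p_threshold, nrow(sel))
}

#' Default P-value threshold grid for the PRS search
#'
#' Geometric grid from `5e-8` to 1 (high-resolution search).
#'
#' @param n Number of grid points (default 200).
#' @return Increasing numeric vector of thresholds.
#' @export
prs_threshold_grid <- function(n = 200) {
  exp(seq(log(5e-8), log(1), length.out = n))
}

#' PRS threshold search by maximal adjusted AUC
#'
#' Scores the clumped variant set at each candidate threshold and evaluates
#' the covariate-adjusted c-statistic on the training individuals; returns
#' the threshold with maximal c-statistic (ties to the smaller threshold).
#' Scores are accumulated incrementally over the ascending threshold grid,
#' so the full search costs one pass over the retained variants.
#'
#' @param panel Cohort `genotype_panel`.
#' @param stats Harmonised summary statistics.
#' @param retained Clumped variant list (see [score_prs()]).
#' @param cohort Cohort tibble with `sample_id`, `case`, `split`.
#' @param covariates Covariate column names used for adjustment (default
#'   age, sex, pc1..pc10).
#' @param thresholds Candidate thresholds (default [prs_threshold_grid()]).
#' @return List with `score` (best standardised `score_vector`, train
#'   reference) and `report` (tibble: threshold, n_features, cstat).
#' @export
threshold_search <- function(panel, stats, retained, cohort,
                             covariates = default_covariates(),
                             thresholds = prs_threshold_grid()) {
  if (length(thresholds) == 0) abort("threshold_search: no candidate thresholds")
  train <- dplyr::filter(cohort, .data$split == "train")
  if (length(unique(train$case)) < 2) {
    abort("threshold_search: training outcome must contain both classes")
  }
  ids <- if (is.character(retained)) retained else retained$id
  sel <- stats[stats$id %in% ids & stats$id %in% panel$variants$id, ,
               drop = FALSE]
  sel <- dplyr::arrange(sel, .data$pvalue)
  thresholds <- sort(thresholds)
  raw <- rep(0, length(panel$samples))
  names(raw) <- panel$samples
  used <- 0L
  report <- tibble::tibble(threshold = thresholds, n_features = 0L,
                           cstat = NA_real_)
  train_idx <- match(train$sample_id, panel$samples)
  for (k in seq_along(thresholds)) {
    add <- which(sel$pvalue <= thresholds[k])
    add <- add[add > used]
    if (length(add) > 0) {
      X <- mean_impute(panel$dosages[, sel$id[add], drop = FALSE])
      raw <- raw + drop(X %*% sel$beta[add])
      used <- max(add)
    }
    report$n_features[k] <- used
    report$cstat[k] <- if (used == 0 || pop_sd(raw[train_idx]) == 0) 0.5 else {
      sc <- new_score_vector(train$sample_id, raw[train_idx], "PRS")
      adjusted_cstat(sc, train, covariates, ci_method = "none")$estimate
    }
  }
  best_k <- which(report$cstat == max(report$cstat))[1]  # tie: smaller threshold
  best <- score_prs(panel, stats, retained, thresholds[best_k])
  best <- standardize_score(best, train$sample_id)
  list(score = best, report = report)
}

#' Default adjustment covariates: age, sex and ten principal components
#' @return Character vector of covariate names.
#' @export
default_covariates <- function() c("age", "sex", paste0("pc", 1:10))
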