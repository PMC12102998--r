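# Polygenic transcriptome risk scores: thresholded sums of predicted
# expression times summary-level gene effects, over a fixed P-value grid,
# with per-tissue model selection by maximal adjusted AUC.

#' PTRS P-value threshold grid
#'
#' The nine thresholds the score is evaluated at:
#' 1, 0.1, 5e-2, 5e-3, 5e-4, 5e-5, 5e-6, 5e-7, 1e-7.
#'
#' @return Decreasing numeric vector of length 9.
#' @export
ptrs_thresholds <- function() {
  c(1, 0.1, 5e-2, 5e-3, 5e-4, 5e-5, 5e-6, 5e-7, 1e-7)
}

#' Compute a polygenic transcriptome risk score
#'
#' `raw_i = sum over genes with P_g <= p_threshold of T_ig * beta_g`,
#' where `T_ig` is predicted expression and `beta_g` the summary-level gene
#' effect. When no gene passes, a zero score with `n_features = 0` is
#' returned with a warning.
#'
#' @param grex A `grex_matrix` from [predict_grex()].
#' @param assoc Gene-association tibble from [spredixcan()] (same tissue).
#' @param p_threshold Inclusive gene P-value cutoff.
#' @return A `score_vector` of type "PTRS" carrying the tissue label.
#' @export
compute_ptrs <- function(grex, assoc, p_threshold = 1) {
  tissue <- grex$tissue %||% NA_character_
  sel <- assoc[assoc$pvalue <= p_threshold & assoc$gene %in% grex$genes, ,
               drop = FALSE]
  if (nrow(sel) == 0) {
    warn("compute_ptrs: no genes pass the threshold; returning zero scores")
    return(new_score_vector(grex$samples, rep(0, length(grex$samples)),
                            "PTRS", p_threshold, 0L, tissue))
  }
  Tg <- grex$values[, sel$gene, drop = FALSE]
  raw <- drop(Tg %*% sel$effect)
  new_score_vector(grex$samples, raw, "PTRS", p_threshold, nrow(sel), tissue)
}

#' PTRS over the full threshold grid
#'
#' @param grex A `grex_matrix`.
#' @param assoc Gene-association tibble (same tissue).
#' @param thresholds Threshold grid (default [ptrs_thresholds()]).
#' @return List of `score_vector`s, one per threshold, named by threshold.
#' @export
ptrs_grid <- function(grex, assoc, thresholds = ptrs_thresholds()) {
  scores <- lapply(thresholds, function(t) {
    suppressWarnings(compute_ptrs(grex, assoc, t))
  })
  names(scores) <- format(thresholds, scientific = TRUE, trim = TRUE)
  scores
}

#' Select the best PTRS per tissue by maximal adjusted AUC
#'
#' Evaluates each tissue's threshold grid on the training individuals with
#' the covariate-adjusted c-statistic and keeps the maximising threshold;
#' AUC ties break toward the more stringent threshold (fewer genes). The
#' selected score is standardised on the training set.
#'
#' @param grex_list Named list of `grex_matrix` objects, one per tissue.
#' @param assoc_list Named list of gene-association tibbles, matching
#'   `grex_list` names.
#' @param cohort Cohort tibble with `sample_id`, `case`, `split`.
#' @param covariates Adjustment covariates (default [default_covariates()]).
#' @param thresholds Threshold grid (default [ptrs_thresholds()]).
#' @return List with `scores` (named list of best standardised
#'   `score_vector`s per tissue) and `report` (tibble: tissue, threshold,
#'   n_features, cstat, ci_low, ci_high, selected).
#' @export
select_best_ptrs <- function(grex_list, assoc_list, cohort,
                             covariates = default_covariates(),
                             thresholds = ptrs_thresholds()) {
  train <- dplyr::filter(cohort, .data$split == "train")
  if (length(unique(train$case)) < 2) {
    abort("select_best_ptrs: training outcome must contain both classes")
  }
  thresholds <- sort(thresholds)  # ascending: more stringent first
  tissues <- names(grex_list)
  report <- list(); best_scores <- list()
  for (t in tissues) {
    grid <- ptrs_grid(grex_list[[t]], assoc_list[[t]], thresholds)
    rows <- purrr::map_dfr(seq_along(thresholds), function(k) {
      sc <- grid[[k]]
      tr <- sc[sc$sample_id %in% train$sample_id, , drop = FALSE]
      ok <- pop_sd(tr$raw) > 0
      cs <- if (ok) {
        adjusted_cstat(tr, train, covariates, ci_method = "delong")
      } else tibble::tibble(estimate = 0.5, ci_low = NA_real_,
                            ci_high = NA_real_)
      tibble::tibble(tissue = t, threshold = thresholds[k],
                     n_features = attr(grid[[k]], "n_features"),
                     cstat = cs$estimate, ci_low = cs$ci_low,
                     ci_high = cs$ci_high)
    })
    best_k <- which(rows$cstat == max(rows$cstat))[1]  # tie: fewer genes
    rows$selected <- seq_len(nrow(rows)) == best_k
    report[[t]] <- rows
    sc <- grid[[best_k]]
    if (pop_sd(sc$raw[sc$sample_id %in% train$sample_id]) > 0) {
      sc <- standardize_score(sc, train$sample_id)
    } else {
      sc$standardized <- sc$raw
    }
    best_scores[[t]] <- sc
  }
  list(scores = best_scores, report = dplyr::bind_rows(report))
}
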