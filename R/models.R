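# Clinical baseline model, combined weighted score, interaction screening
# and biomarker association/interaction analyses.

#' Rank-based inverse normal transform
#'
#' Maps non-missing values to `qnorm((r - 3/8) / (n + 1/4))` (Blom offset),
#' with ties receiving their average rank; missing values stay missing.
#'
#' @param x Numeric vector, possibly with `NA`s.
#' @return Transformed vector of the same length.
#' @export
#' @examples
#' rank_inverse_normal(c(1, 2, 3))
rank_inverse_normal <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2) abort("rank_inverse_normal: need at least 2 non-missing values")
  v <- x[obs]
  if (length(unique(v)) == 1) {
    warn("rank_inverse_normal: all values equal; returning zeros")
    x[obs] <- 0
    return(x)
  }
  r <- rank(v, ties.method = "average")
  x[obs] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  x
}

#' Impute missing blood counts by chained equations
#'
#' Single-dataset chained-equations imputation: missing cells are
#' initialised at the observed mean, then for a fixed number of cycles each
#' incomplete variable is regressed on age, sex, case status and the other
#' blood count using the configured learner (a random-forest ensemble by
#' default, plain linear regression as the fast fallback); missing cells
#' are replaced by the model prediction, optionally perturbed by a
#' residual-scale Gaussian draw (`noise = TRUE`) when between-imputation
#' variability matters more than point accuracy. Deterministic under a
#' fixed seed. Imputed cells are flagged in the `imputed_cells` attribute.
#'
#' @param cohort Cohort tibble; missingness is expected only in
#'   `eosinophils`/`lymphocytes`.
#' @param method `"rf"` (default) or `"linear"`.
#' @param cycles Number of chained-equation cycles (default 5).
#' @param num_trees Trees per forest when `method = "rf"` (default 100).
#' @param noise Add a residual-SD Gaussian draw to each imputation
#'   (default FALSE: conditional-mean imputation).
#' @param seed Integer seed.
#' @return Completed cohort with attribute `imputed_cells` (tibble:
#'   variable, row).
#' @export
impute_missing <- function(cohort, method = c("rf", "linear"), cycles = 5,
                           num_trees = 100, noise = FALSE, seed = 1L) {
  method <- match.arg(method)
  vars <- intersect(c("eosinophils", "lymphocytes"), names(cohort))
  miss <- lapply(vars, function(v) which(is.na(cohort[[v]])))
  names(miss) <- vars
  if (all(lengths(miss) == 0)) {
    attr(cohort, "imputed_cells") <- tibble::tibble(variable = character(0),
                                                    row = integer(0))
    return(cohort)
  }
  fully_missing <- vars[vapply(vars, function(v) all(is.na(cohort[[v]])),
                               logical(1))]
  if (length(fully_missing) > 0) {
    abort(sprintf("impute_missing: variable(s) entirely missing: %s",
                  paste(fully_missing, collapse = ", ")))
  }
  withr::local_seed(as.integer(seed))
  d <- cohort
  for (v in vars) {
    d[[v]][miss[[v]]] <- mean(d[[v]], na.rm = TRUE)
  }
  base_preds <- intersect(c("age", "sex", "case"), names(d))
  for (cyc in seq_len(cycles)) {
    for (v in vars) {
      rows <- miss[[v]]
      if (length(rows) == 0) next
      preds <- c(base_preds, setdiff(vars, v))
      obs <- setdiff(seq_len(nrow(d)), rows)
      df <- d[c(v, preds)]
      if (method == "rf") {
        fit <- ranger::ranger(
          x = df[obs, preds, drop = FALSE], y = df[[v]][obs],
          num.trees = num_trees, seed = sample.int(1e6, 1),
          num.threads = 1)
        pred_mis <- predict(fit, df[rows, preds, drop = FALSE],
                            num.threads = 1)$predictions
        res_sd <- sqrt(max(fit$prediction.error, 0))
      } else {
        fml <- as.formula(paste(v, "~", paste(preds, collapse = " + ")))
        fit <- lm(fml, df[obs, , drop = FALSE])
        pred_mis <- unname(predict(fit, newdata = df[rows, , drop = FALSE]))
        res_sd <- sd(stats::residuals(fit))
      }
      d[[v]][rows] <- if (noise) {
        pred_mis + rnorm(length(rows), sd = res_sd)
      } else pred_mis
    }
  }
  attr(d, "imputed_cells") <- dplyr::bind_rows(lapply(vars, function(v) {
    tibble::tibble(variable = v, row = miss[[v]])
  }))
  d
}

# Wald-style term table from a glm/lm (or internal ridge) fit
term_table <- function(fit, conf_level = 0.95) {
  if (inherits(fit, "ridge_logistic")) {
    est <- fit$coefficients
    sm <- cbind(est, fit$se, est / fit$se, 2 * pnorm(-abs(est / fit$se)))
    rownames(sm) <- names(est)
  } else {
    sm <- summary(fit)$coefficients
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]), se = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    pvalue = pmax(unname(sm[, 4]), .Machine$double.xmin),
    ci_low = unname(sm[, 1] - zq * sm[, 2]),
    ci_high = unname(sm[, 1] + zq * sm[, 2])
  )
}

new_risk_model_fit <- function(fit, terms, what) {
  structure(list(fit = fit, terms = terms, what = what),
            class = "risk_model_fit")
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat(sprintf("<risk_model_fit> %s\n", x$what))
  print(x$terms)
  invisible(x)
}

#' Baseline clinical risk model
#'
#' Logistic regression of case status on inverse-normal transformed
#' eosinophil and lymphocyte counts, age and sex, fitted on the training
#' rows; the baseline score is the linear predictor, transported to every
#' individual. Blood counts must be complete (see [impute_missing()]); the
#' transform is applied internally via [rank_inverse_normal()] unless
#' columns `eos_int`/`lymph_int` are already present. Quasi-separation is
#' detected from diverging coefficients and refit with a light ridge
#' penalty, with a warning.
#'
#' @param cohort Cohort with complete blood counts and a `split` column.
#' @return List with `fit` (a `risk_model_fit`; per-term log-OR, SE, 95%
#'   CI) and `score` (baseline `score_vector` over all individuals,
#'   standardised on train).
#' @export
fit_baseline <- function(cohort) {
  d <- cohort
  if (!all(c("eos_int", "lymph_int") %in% names(d))) {
    if (anyNA(d$eosinophils) || anyNA(d$lymphocytes)) {
      abort("fit_baseline: blood counts contain missing values; impute first")
    }
    d$eos_int <- rank_inverse_normal(d$eosinophils)
    d$lymph_int <- rank_inverse_normal(d$lymphocytes)
  }
  train <- dplyr::filter(d, .data$split == "train")
  fit <- suppressWarnings(
    glm(case ~ eos_int + lymph_int + age + sex, binomial(), train))
  if (!fit$converged || any(abs(coef(fit)) > 15)) {
    warn("fit_baseline: separation suspected; refitting with ridge penalty")
    fit <- ridge_logistic(case ~ eos_int + lymph_int + age + sex, train,
                          lambda = 1e-4)
  }
  tt <- term_table(fit)
  lp <- unname(predict(fit, newdata = d, type = "link"))
  score <- new_score_vector(d$sample_id, lp, "baseline")
  score <- standardize_score(score, train$sample_id)
  list(fit = new_risk_model_fit(fit, tt, "baseline clinical model"),
       score = score)
}

# minimal ridge-penalised logistic fit, interface-compatible with the
# pieces of glm that fit_baseline needs (coef, predict, term_table)
ridge_logistic <- function(formula, data, lambda = 1e-4, maxit = 50) {
  X <- stats::model.matrix(formula, data)
  y <- stats::model.response(stats::model.frame(formula, data))
  beta <- rep(0, ncol(X))
  H <- NULL
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(H)))
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 se = se, formula = formula, converged = TRUE),
            class = "ridge_logistic")
}

#' @export
predict.ridge_logistic <- function(object, newdata, type = "link", ...) {
  tm <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tm, newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "response") 1 / (1 + exp(-eta)) else eta
}

#' Combine PRS and PTRS into a weighted-sum score
#'
#' Fits `case ~ PRS + PTRS + covariates` by logistic regression on the
#' training rows; the combined raw score is
#' `w_prs * PRS_i + w_ptrs * PTRS_i` with the fitted score coefficients
#' (covariates re-enter only at evaluation), standardised on train and
#' applied everywhere.
#'
#' @param prs,ptrs Standardised score vectors over all individuals.
#' @param cohort Cohort with `split`.
#' @param covariates Adjustment covariates used in the weighting fit.
#' @return A combined `score_vector` with attributes `weights` and `fit`.
#' @export
combine_scores <- function(prs, ptrs, cohort,
                           covariates = default_covariates()) {
  stopifnot("standardized" %in% names(prs), "standardized" %in% names(ptrs))
  d <- cohort
  d$prs <- prs$standardized[match(d$sample_id, prs$sample_id)]
  d$ptrs <- ptrs$standardized[match(d$sample_id, ptrs$sample_id)]
  r <- cor(d$prs, d$ptrs, use = "complete.obs")
  if (abs(r) > 0.999) {
    abort("combine_scores: scores are collinear (|r| > 0.999); use a single score")
  }
  train <- dplyr::filter(d, .data$split == "train")
  fml <- as.formula(paste("case ~ prs + ptrs",
                          if (length(covariates) > 0)
                            paste("+", paste(intersect(covariates, names(d)),
                                             collapse = " + ")) else ""))
  fit <- glm(fml, binomial(), train)
  w <- coef(fit)[c("prs", "ptrs")]
  raw <- w[["prs"]] * d$prs + w[["ptrs"]] * d$ptrs
  sc <- new_score_vector(d$sample_id, raw, "combined",
                         tissue = attr(ptrs, "tissue") %||% NA_character_)
  sc <- standardize_score(sc, train$sample_id)
  attr(sc, "weights") <- w
  attr(sc, "fit") <- new_risk_model_fit(fit, term_table(fit),
                                        "combined-score weighting model")
  sc
}

#' Screen PRS x PTRS interactions to prioritise tissues
#'
#' Per tissue, fits `case ~ PRS + PTRS + PRS:PTRS + covariates` on the
#' training rows; tissues whose interaction P-value falls below the
#' Bonferroni threshold `alpha / n_tissues` are excluded from combination.
#' The per-tissue Pearson correlation of PRS and PTRS is also reported.
#'
#' @param prs Standardised PRS score vector.
#' @param ptrs_list Named list of standardised PTRS score vectors.
#' @param cohort Cohort with `split`.
#' @param covariates Adjustment covariates.
#' @param alpha Family-wise level (default 0.05).
#' @return List with `kept` (tissue names) and `report` (tibble: tissue,
#'   estimate, se, pvalue, pearson_r, excluded).
#' @export
interaction_screen <- function(prs, ptrs_list, cohort,
                               covariates = default_covariates(),
                               alpha = 0.05) {
  train <- dplyr::filter(cohort, .data$split == "train")
  n_tissues <- length(ptrs_list)
  thr <- alpha / n_tissues
  report <- purrr::map_dfr(names(ptrs_list), function(t) {
    d <- train
    d$prs <- prs$standardized[match(d$sample_id, prs$sample_id)]
    d$ptrs <- ptrs_list[[t]]$standardized[match(d$sample_id,
                                                ptrs_list[[t]]$sample_id)]
    fml <- as.formula(paste("case ~ prs * ptrs",
                            if (length(covariates) > 0)
                              paste("+", paste(intersect(covariates, names(d)),
                                               collapse = " + ")) else ""))
    fit <- glm(fml, binomial(), d)
    tt <- term_table(fit)
    row <- tt[tt$term == "prs:ptrs", ]
    tibble::tibble(tissue = t, estimate = row$estimate, se = row$se,
                   pvalue = row$pvalue,
                   pearson_r = cor(d$prs, d$ptrs, use = "complete.obs"))
  })
  report$excluded <- report$pvalue < thr
  list(kept = report$tissue[!report$excluded], report = report)
}

#' Association of PRS and PTRS with blood cell counts
#'
#' On the test rows, fits per (count, tissue) the linear model
#' `INT(count) ~ PRS + PTRS (+ PRS:PTRS) + age + sex + PC1..10`, in two
#' variants: with the product term (`model = "interaction"`) and without
#' (`model = "joint"`). Score-term estimates carry a Bonferroni flag at
#' `alpha / divisor`, the divisor defaulting to three score terms per
#' tissue.
#'
#' @param cohort Cohort with `split` (test rows are used).
#' @param prs Standardised PRS.
#' @param ptrs_list Named list of standardised PTRS score vectors.
#' @param counts Outcome columns (default eosinophils and lymphocytes).
#' @param covariates Adjustment covariates (default age, sex, PCs).
#' @param alpha Family-wise level (default 0.05).
#' @param divisor Bonferroni divisor; default `3 * length(ptrs_list)`.
#' @return Tibble (outcome, tissue, model, term, estimate, se, pvalue,
#'   ci_low, ci_high, significant).
#' @export
biomarker_association <- function(cohort, prs, ptrs_list,
                                  counts = c("eosinophils", "lymphocytes"),
                                  covariates = default_covariates(),
                                  alpha = 0.05, divisor = NULL) {
  divisor <- divisor %||% (3 * length(ptrs_list))
  test <- dplyr::filter(cohort, .data$split == "test")
  cov_str <- paste(intersect(covariates, names(test)), collapse = " + ")
  purrr::map_dfr(counts, function(ct) {
    y <- rank_inverse_normal(test[[ct]])
    purrr::map_dfr(names(ptrs_list), function(t) {
      d <- test
      d$.y <- y
      d$prs <- prs$standardized[match(d$sample_id, prs$sample_id)]
      d$ptrs <- ptrs_list[[t]]$standardized[match(d$sample_id,
                                                  ptrs_list[[t]]$sample_id)]
      purrr::map_dfr(c("interaction", "joint"), function(mv) {
        fml <- as.formula(paste(".y ~",
                                if (mv == "interaction") "prs * ptrs" else "prs + ptrs",
                                if (nzchar(cov_str)) paste("+", cov_str) else ""))
        tt <- term_table(lm(fml, d))
        tt <- tt[tt$term %in% c("prs", "ptrs", "prs:ptrs"), ]
        tt$outcome <- ct; tt$tissue <- t; tt$model <- mv
        tt$significant <- tt$pvalue < alpha / divisor
        tt[c("outcome", "tissue", "model", "term", "estimate", "se",
             "pvalue", "ci_low", "ci_high", "significant")]
      })
    })
  })
}

#' PTRS x lymphocyte interaction in disease risk
#'
#' On the test rows, fits per tissue the logistic model
#' `case ~ PTRS + INT(lymphocytes) + PTRS:INT(lymphocytes) + age + sex +
#' PCs` and reports the interaction term with Bonferroni correction at
#' `alpha / n_tissues`.
#'
#' @param cohort Cohort with `split` and complete lymphocyte counts on the
#'   test rows.
#' @param ptrs_list Named list of standardised PTRS score vectors.
#' @param covariates Adjustment covariates.
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble (tissue, term, estimate, se, pvalue, ci_low, ci_high,
#'   significant).
#' @export
risk_interaction <- function(cohort, ptrs_list,
                             covariates = default_covariates(),
                             alpha = 0.05) {
  test <- dplyr::filter(cohort, .data$split == "test")
  if (anyNA(test$lymphocytes)) {
    abort("risk_interaction: lymphocyte counts must be complete; impute first")
  }
  lymph_int <- rank_inverse_normal(test$lymphocytes)
  thr <- alpha / length(ptrs_list)
  cov_str <- paste(intersect(covariates, names(test)), collapse = " + ")
  purrr::map_dfr(names(ptrs_list), function(t) {
    d <- test
    d$lymph_int <- lymph_int
    d$ptrs <- ptrs_list[[t]]$standardized[match(d$sample_id,
                                                ptrs_list[[t]]$sample_id)]
    fml <- as.formula(paste("case ~ ptrs * lymph_int",
                            if (nzchar(cov_str)) paste("+", cov_str) else ""))
    tt <- term_table(glm(fml, binomial(), d))
    tt <- tt[tt$term == "ptrs:lymph_int", ]
    tt$tissue <- t
    tt$significant <- tt$pvalue < thr
    tt[c("tissue", "term", "estimate", "se", "pvalue", "ci_low", "ci_high",
         "significant")]
  })
}
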