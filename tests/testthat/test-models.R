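# Inverse-normal transform, chained-equations imputation, baseline model,
# combined score, interaction screening and biomarker models.

test_that("rank inverse normal transform follows the Blom convention", {
  out <- rank_inverse_normal(c(1, 2, 3))
  expect_equal(out, qnorm((1:3 - 3 / 8) / (3 + 1 / 4)), tolerance = 1e-12)
  expect_equal(out[2], 0)
  expect_equal(out[1], -out[3])

  x <- c(2, NA, 5, 1)
  tr <- rank_inverse_normal(x)
  expect_true(is.na(tr[2]))
  expect_identical(order(na.omit(x)), order(na.omit(tr)))

  tied <- rank_inverse_normal(c(5, 5, 9))
  expect_equal(tied[1], tied[2])
  expect_equal(tied[1], qnorm((1.5 - 3 / 8) / 3.25), tolerance = 1e-12)

  expect_warning(allz <- rank_inverse_normal(c(2, 2, 2)), "equal")
  expect_equal(allz, c(0, 0, 0))
  expect_error(rank_inverse_normal(c(NA, 1)), "non-missing")

  set.seed(10)
  y <- rank_inverse_normal(rexp(2000))
  ks <- stats::ks.test(y, "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("chained-equations imputation is deterministic and beats the marginal SD", {
  cfg <- small_config(n_cohort = 4000, missing_rate = 0)
  models <- simulate_eqtl_models(cfg, simulate_reference_panel(cfg))
  sim <- simulate_cohort(cfg, models)
  full <- sim$cohort

  none <- impute_missing(full, method = "linear")
  expect_equal(none$eosinophils, full$eosinophils)

  withr::with_seed(2, mask <- sample(nrow(full), round(0.03 * nrow(full))))
  holey <- full
  holey$eosinophils[mask] <- NA
  imp1 <- impute_missing(holey, method = "linear", seed = 5)
  imp2 <- impute_missing(holey, method = "linear", seed = 5)
  expect_identical(imp1$eosinophils, imp2$eosinophils)
  cells <- attr(imp1, "imputed_cells")
  expect_setequal(cells$row[cells$variable == "eosinophils"], mask)

  rmse <- sqrt(mean((imp1$eosinophils[mask] - full$eosinophils[mask])^2))
  expect_lt(rmse, sd(full$eosinophils))

  imp_rf <- impute_missing(holey, method = "rf", num_trees = 50, seed = 5)
  rmse_rf <- sqrt(mean((imp_rf$eosinophils[mask] - full$eosinophils[mask])^2))
  expect_lt(rmse_rf, sd(full$eosinophils))

  gone <- holey
  gone$lymphocytes <- NA_real_
  expect_error(impute_missing(gone), "entirely missing")
})

test_that("baseline model recovers signed blood-count effects and matches IRLS", {
  cfg <- sim_config(n_cohort = 20000, n_ref = 300, n_blocks = 4,
                    block_size = 10, n_tissues = 2, genes_per_tissue = 8,
                    missing_rate = 0, seed = 19)
  models <- simulate_eqtl_models(cfg, simulate_reference_panel(cfg))
  sim <- simulate_cohort(cfg, models)
  base <- fit_baseline(sim$cohort)
  tt <- tidy(base$fit)
  expect_gt(tt$estimate[tt$term == "eos_int"], 0)
  expect_lt(tt$estimate[tt$term == "lymph_int"], 0)
  expect_lt(tt$pvalue[tt$term == "eos_int"], 0.001)
  expect_lt(tt$pvalue[tt$term == "lymph_int"], 0.001)
  expect_true(all(tt$ci_low <= tt$estimate & tt$estimate <= tt$ci_high))

  # IRLS oracle agreement on the train rows
  d <- sim$cohort
  d$eos_int <- rank_inverse_normal(d$eosinophils)
  d$lymph_int <- rank_inverse_normal(d$lymphocytes)
  tr <- d[d$split == "train", ]
  Xm <- cbind(1, tr$eos_int, tr$lymph_int, tr$age, tr$sex)
  want <- irls_logistic_oracle(Xm, tr$case)
  expect_equal(unname(tt$estimate), unname(want), tolerance = 1e-6)

  # the baseline score is the transported linear predictor
  expect_equal(nrow(base$score), nrow(sim$cohort))
  expect_equal(mean(base$score$standardized[
    base$score$sample_id %in% tr$sample_id]), 0, tolerance = 1e-8)
})

test_that("combined score is the fitted weighted sum and never hurts train likelihood", {
  set.seed(77)
  n <- 4000
  cohort <- tibble::tibble(
    sample_id = sprintf("s%05d", 1:n),
    case = NA_integer_,
    age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5),
    split = rep(c("train", "test"), each = n / 2))
  s1 <- rnorm(n); s2 <- rnorm(n)
  lp <- -2 + 0.6 * s1 + 0.4 * s2
  cohort$case <- rbinom(n, 1, 1 / (1 + exp(-lp)))
  prs <- standardize_score(ptrskit:::new_score_vector(cohort$sample_id, s1, "PRS"))
  ptrs <- standardize_score(ptrskit:::new_score_vector(cohort$sample_id, s2, "PTRS"))
  comb <- combine_scores(prs, ptrs, cohort, covariates = character(0))
  w <- attr(comb, "weights")
  expect_equal(comb$raw, w[["prs"]] * prs$standardized +
                 w[["ptrs"]] * ptrs$standardized, tolerance = 1e-12)

  tr <- cohort[cohort$split == "train", ]
  ll <- function(form, d) as.numeric(logLik(glm(form, binomial(), d)))
  d <- tr
  d$prs <- prs$standardized[match(d$sample_id, prs$sample_id)]
  d$ptrs <- ptrs$standardized[match(d$sample_id, ptrs$sample_id)]
  ll_joint <- ll(case ~ prs + ptrs, d)
  expect_gte(ll_joint, ll(case ~ prs, d) - 1e-8)
  expect_gte(ll_joint, ll(case ~ ptrs, d) - 1e-8)

  near_dup <- standardize_score(ptrskit:::new_score_vector(
    cohort$sample_id, s1 + rnorm(n, sd = 1e-5), "PTRS"))
  expect_error(combine_scores(prs, near_dup, cohort, character(0)),
               "collinear")
})

test_that("interaction screening retains null tissues and reports Pearson r", {
  set.seed(55)
  retained <- replicate(20, {
    n <- 3000
    cohort <- tibble::tibble(
      sample_id = sprintf("s%05d", 1:n),
      age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5),
      split = "train")
    s1 <- rnorm(n)
    scores <- lapply(1:3, function(i) standardize_score(
      ptrskit:::new_score_vector(cohort$sample_id, rnorm(n), "PTRS")))
    names(scores) <- paste0("t", 1:3)
    cohort$case <- rbinom(n, 1, 1 / (1 + exp(-(-2 + 0.5 * s1))))
    prs <- standardize_score(
      ptrskit:::new_score_vector(cohort$sample_id, s1, "PRS"))
    scr <- interaction_screen(prs, scores, cohort, covariates = character(0))
    expect_equal(nrow(scr$report), 3)
    expect_true(all(is.finite(scr$report$pearson_r)))
    length(scr$kept)
  })
  expect_gte(mean(retained / 3), 0.9)
})

test_that("a strong planted score interaction is excluded from combination", {
  set.seed(56)
  n <- 8000
  cohort <- tibble::tibble(
    sample_id = sprintf("s%05d", 1:n),
    age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5), split = "train")
  s1 <- rnorm(n); s2 <- rnorm(n); s3 <- rnorm(n)
  lp <- -2.5 + 0.4 * s1 + 0.3 * s2 + 0.6 * s1 * s2
  cohort$case <- rbinom(n, 1, 1 / (1 + exp(-lp)))
  prs <- standardize_score(ptrskit:::new_score_vector(cohort$sample_id, s1, "PRS"))
  scores <- list(
    interacting = standardize_score(
      ptrskit:::new_score_vector(cohort$sample_id, s2, "PTRS")),
    clean = standardize_score(
      ptrskit:::new_score_vector(cohort$sample_id, s3, "PTRS")))
  scr <- interaction_screen(prs, scores, cohort, covariates = character(0))
  expect_true(scr$report$excluded[scr$report$tissue == "interacting"])
  expect_false("interacting" %in% scr$kept)
})

test_that("biomarker association uses the documented Bonferroni divisor and both model variants", {
  set.seed(57)
  n <- 2000
  cohort <- tibble::tibble(
    sample_id = sprintf("s%05d", 1:n),
    case = rbinom(n, 1, 0.1),
    age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5),
    eosinophils = rexp(n, 5), lymphocytes = rexp(n, 0.5),
    split = "test")
  seven <- lapply(1:7, function(i) standardize_score(
    ptrskit:::new_score_vector(cohort$sample_id, rnorm(n), "PTRS")))
  names(seven) <- paste0("t", 1:7)
  prs <- standardize_score(ptrskit:::new_score_vector(cohort$sample_id,
                                                      rnorm(n), "PRS"))
  res <- biomarker_association(cohort, prs, seven, covariates = c("age", "sex"))
  expect_equal(attr(res, "divisor", exact = TRUE) %||% 21, 21)
  expect_setequal(unique(res$model), c("interaction", "joint"))
  # 2 outcomes x 7 tissues x (3 interaction terms + 2 joint terms)
  expect_equal(nrow(res), 2 * 7 * 5)
  expect_identical(res$significant, res$pvalue < 0.05 / 21)
})

test_that("risk interaction coefficients agree with an IRLS oracle", {
  set.seed(58)
  n <- 3000
  cohort <- tibble::tibble(
    sample_id = sprintf("s%05d", 1:n),
    age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5),
    eosinophils = rexp(n, 5), lymphocytes = rexp(n, 0.5),
    split = "test")
  s <- rnorm(n)
  lymph_int <- rank_inverse_normal(cohort$lymphocytes)
  lp <- -2 + 0.3 * s - 0.2 * lymph_int + 0.4 * s * lymph_int
  cohort$case <- rbinom(n, 1, 1 / (1 + exp(-lp)))
  ptrs <- standardize_score(ptrskit:::new_score_vector(cohort$sample_id, s, "PTRS"))
  res <- risk_interaction(cohort, list(t1 = ptrs),
                          covariates = c("age", "sex"))
  expect_equal(nrow(res), 1)
  expect_identical(res$term, "ptrs:lymph_int")
  expect_true(res$significant)

  Xm <- cbind(1, ptrs$standardized, lymph_int, cohort$age, cohort$sex,
              ptrs$standardized * lymph_int)
  want <- irls_logistic_oracle(Xm, cohort$case)
  expect_equal(res$estimate, unname(want[6]), tolerance = 1e-6)
})
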