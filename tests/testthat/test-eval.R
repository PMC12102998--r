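# Stratified splitting, concordance statistics, DeLong machinery and the
# evaluation suite.

test_that("stratified split maintains the case ratio within rounding", {
  set.seed(61)
  n <- 100000
  cohort <- tibble::tibble(
    sample_id = sprintf("s%06d", 1:n),
    case = rbinom(n, 1, 0.04),
    sex = rbinom(n, 1, 0.46),
    age = rnorm(n, 57, 8))
  out <- stratified_split(cohort, 0.8, seed = 3)
  n_cases <- sum(out$case)
  train_cases <- sum(out$case[out$split == "train"])
  expect_lte(abs(train_cases - round(0.8 * n_cases)), 1)
  train_ctrl <- sum(out$case == 0 & out$split == "train")
  expect_lte(abs(train_ctrl - round(0.8 * sum(out$case == 0))), 1)
  # age distribution preserved across the split
  expect_lt(abs(mean(out$age[out$split == "train"]) -
                  mean(out$age[out$split == "test"])), 0.2)

  out2 <- stratified_split(cohort, 0.8, seed = 3)
  expect_identical(out$split, out2$split)

  expect_warning(all_train <- stratified_split(cohort, 1, seed = 1),
                 "test set is empty")
  expect_true(all(all_train$split == "train"))
  expect_error(stratified_split(cohort, 0), "train_fraction")
})

test_that("concordance matches enumerated pairs, perfect and random anchors", {
  sc <- ptrskit:::new_score_vector(letters[1:4], c(2, 3, 1, 2.5), "PRS")
  coh <- tibble::tibble(sample_id = letters[1:4], case = c(1, 1, 0, 0))
  cs <- adjusted_cstat(sc, coh, character(0), ci_method = "none")
  expect_equal(cs$estimate, 0.75)
  expect_equal(cs$n_cases, 2L); expect_equal(cs$n_controls, 2L)

  # perfect separation gives exactly 1
  n <- 200
  coh2 <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         case = rep(c(1, 0), each = n / 2))
  sc2 <- ptrskit:::new_score_vector(coh2$sample_id,
                                    c(rnorm(n / 2, 10), rnorm(n / 2, 0)), "PRS")
  expect_equal(adjusted_cstat(sc2, coh2, character(0),
                              ci_method = "none")$estimate, 1)

  # a score independent of a common outcome sits inside a CI covering 0.5
  set.seed(62)
  n <- 50000
  coh3 <- tibble::tibble(sample_id = sprintf("s%06d", 1:n),
                         case = rbinom(n, 1, 0.04))
  sc3 <- ptrskit:::new_score_vector(coh3$sample_id, rnorm(n), "PRS")
  cs3 <- adjusted_cstat(sc3, coh3, character(0))
  expect_gte(0.5, cs3$ci_low); expect_lte(0.5, cs3$ci_high)

  # ties count one half
  sct <- ptrskit:::new_score_vector(letters[1:4], c(1, 2, 1, 0), "PRS")
  cst <- adjusted_cstat(sct, coh, character(0), ci_method = "none")
  expect_equal(cst$estimate, pairwise_cstat_oracle(c(1, 2, 1, 0),
                                                   c(1, 1, 0, 0)))
})

test_that("concordance equals trapezoidal ROC area and pair enumeration", {
  set.seed(63)
  for (rep in 1:10) {
    n <- 150
    case <- rbinom(n, 1, 0.4)
    if (length(unique(case)) < 2) next
    pred <- rnorm(n) + case * runif(1, 0, 2)
    if (runif(1) < 0.5) pred <- round(pred, 1) # induce ties
    sc <- ptrskit:::new_score_vector(sprintf("s%03d", 1:n), pred, "PRS")
    coh <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), case = case)
    est <- adjusted_cstat(sc, coh, character(0), ci_method = "none")$estimate
    expect_equal(est, trapezoid_auc_oracle(pred, case), tolerance = 1e-12)
    expect_equal(est, pairwise_cstat_oracle(pred, case), tolerance = 1e-12)
  }
})

test_that("unadjusted concordance is invariant to strictly increasing transforms", {
  set.seed(64)
  n <- 500
  coh <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                        case = rbinom(n, 1, 0.3))
  x <- rnorm(n) + coh$case
  c1 <- adjusted_cstat(ptrskit:::new_score_vector(coh$sample_id, x, "PRS"),
                       coh, character(0), ci_method = "none")$estimate
  c2 <- adjusted_cstat(ptrskit:::new_score_vector(coh$sample_id, exp(2 * x),
                                                  "PRS"),
                       coh, character(0), ci_method = "none")$estimate
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("DeLong and pROC agree on the estimate and variance", {
  skip_if_not_installed("pROC")
  set.seed(65)
  n <- 800
  case <- rbinom(n, 1, 0.3)
  pred <- rnorm(n) + case
  sc <- ptrskit:::new_score_vector(sprintf("s%03d", 1:n), pred, "PRS")
  coh <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), case = case)
  cs <- adjusted_cstat(sc, coh, character(0))
  roc <- pROC::roc(case, pred, quiet = TRUE, direction = "<")
  ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))
  expect_equal(cs$estimate, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  expect_equal(cs$ci_low, ci[1], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(cs$ci_high, ci[3], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("paired DeLong comparison is antisymmetric with exact null behaviour", {
  set.seed(66)
  n <- 600
  case <- rbinom(n, 1, 0.3)
  p1 <- rnorm(n) + case
  p2 <- rnorm(n) + 0.5 * case
  ids <- sprintf("s%03d", 1:n)
  coh <- tibble::tibble(sample_id = ids, case = case)
  s1 <- ptrskit:::new_score_vector(ids, p1, "PRS")
  s2 <- ptrskit:::new_score_vector(ids, p2, "PTRS")

  same <- delong_paired(s1, s1, coh, character(0))
  expect_equal(same$delta, 0)
  expect_equal(same$pvalue, 1)

  ab <- delong_paired(s1, s2, coh, character(0))
  ba <- delong_paired(s2, s1, coh, character(0))
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)
  expect_true(ab$ci_low <= ab$delta && ab$delta <= ab$ci_high)

  skip_if_not_installed("pROC")
  pr <- pROC::roc.test(pROC::roc(case, p1, quiet = TRUE, direction = "<"),
                       pROC::roc(case, p2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(ab$pvalue, pr$p.value, tolerance = 1e-9)
})

test_that("paired DeLong SE agrees with a paired-bootstrap oracle", {
  set.seed(67)
  n <- 5000
  case <- rbinom(n, 1, 0.2)
  p1 <- rnorm(n) + 0.8 * case
  p2 <- 0.6 * p1 + rnorm(n, sd = 0.8) + 0.2 * case
  ids <- sprintf("s%05d", 1:n)
  coh <- tibble::tibble(sample_id = ids, case = case)
  dc <- delong_paired(ptrskit:::new_score_vector(ids, p1, "a"),
                      ptrskit:::new_score_vector(ids, p2, "b"),
                      coh, character(0))
  boots <- vapply(1:2000, function(b) {
    idx <- sample(n, replace = TRUE)
    pl1 <- ptrskit:::delong_placements(p1[idx], case[idx])
    pl2 <- ptrskit:::delong_placements(p2[idx], case[idx])
    pl1$theta - pl2$theta
  }, numeric(1))
  expect_lt(abs(dc$se - sd(boots)) / sd(boots), 0.1)
})

test_that("covariate adjustment follows the fitted-probability convention", {
  set.seed(68)
  n <- 3000
  age <- rnorm(n, 57, 8); sex <- rbinom(n, 1, 0.5)
  s <- rnorm(n)
  lp <- -2 + 0.5 * s + 0.05 * (age - 57) + 0.3 * sex
  case <- rbinom(n, 1, 1 / (1 + exp(-lp)))
  coh <- tibble::tibble(sample_id = sprintf("s%05d", 1:n), case = case,
                        age = age, sex = sex)
  sc <- ptrskit:::new_score_vector(coh$sample_id, s, "PRS")
  adj <- adjusted_cstat(sc, coh, c("age", "sex"))
  fit <- glm(case ~ s + age + sex, binomial())
  want <- ptrskit:::delong_placements(unname(predict(fit)), case)$theta
  expect_equal(adj$estimate, want, tolerance = 1e-12)
  # residualisation mode runs and stays in range
  res <- adjusted_cstat(sc, coh, c("age", "sex"), mode = "residual",
                        ci_method = "none")
  expect_gt(res$estimate, 0); expect_lt(res$estimate, 1)
  # stratified bootstrap CI brackets the estimate
  bs <- adjusted_cstat(sc, coh, c("age", "sex"), ci_method = "bootstrap",
                       n_boot = 200)
  expect_true(bs$ci_low <= bs$estimate && bs$estimate <= bs$ci_high)
})

test_that("single-class outcomes are refused", {
  coh <- tibble::tibble(sample_id = c("a", "b"), case = c(1, 1))
  sc <- ptrskit:::new_score_vector(c("a", "b"), c(1, 2), "PRS")
  expect_error(adjusted_cstat(sc, coh, character(0)), "both classes")
})

test_that("the evaluation suite reports every declared family and comparison", {
  set.seed(69)
  n <- 4000
  coh <- tibble::tibble(
    sample_id = sprintf("s%05d", 1:n),
    age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5),
    split = rep(c("train", "test"), each = n / 2))
  s1 <- rnorm(n); s2 <- rnorm(n)
  lp <- -2.2 + 0.6 * s1 + 0.4 * s2
  coh$case <- rbinom(n, 1, 1 / (1 + exp(-lp)))
  scores <- list(
    A = standardize_score(ptrskit:::new_score_vector(coh$sample_id, s1, "PRS")),
    B = standardize_score(ptrskit:::new_score_vector(coh$sample_id, s2, "PTRS")))
  rep <- evaluate_suite(coh, scores,
                        families = list(A = "A", B = "B", AB = c("A", "B")),
                        covariates = c("age", "sex"))
  expect_identical(rep$cstats$model, c("A", "B", "AB"))
  expect_equal(nrow(rep$comparisons), 3) # all pairs of three families
  expect_true(all(rep$cstats$ci_low <= rep$cstats$cstat &
                    rep$cstats$cstat <= rep$cstats$ci_high))
  expect_identical(tidy(rep), rep$cstats)
  expect_identical(glance(rep), rep$comparisons)
})
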