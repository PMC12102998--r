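# Synthetic study generator: LD structure, determinism, liability model,
# summary-statistic calibration.

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(h2_mediated = 0.6, h2_direct = 0.5), "h2")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(eqtl_per_gene = c(1, 30), block_size = 25),
               "eqtl_per_gene")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("reference panel is bit-identical under the same seed and has HWE-consistent dosages", {
  cfg <- small_config()
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$variants$id, p2$variants$id)
  expect_true(all(p1$dosages %in% 0:2))
  maf <- colMeans(p1$dosages) / 2
  expect_true(all(maf > 0.01 & maf < 0.6)) # sampling noise around maf_range
})

test_that("ld_rho = 0 gives near-independent variants", {
  cfg <- small_config(n_ref = 1000, n_blocks = 1, block_size = 10, ld_rho = 0)
  p <- simulate_reference_panel(cfg)
  R <- cor(p$dosages)
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)
})

test_that("adjacent genotype correlation approximates the configured target", {
  adj <- vapply(1:20, function(s) {
    cfg <- sim_config(n_ref = 2000, n_cohort = 100, n_blocks = 1,
                      block_size = 10, ld_rho = 0.9, seed = 1000 + s)
    p <- simulate_reference_panel(cfg)
    R <- cor(p$dosages)
    mean(R[cbind(1:9, 2:10)])
  }, numeric(1))
  expect_gt(mean(adj), 0.8)
  expect_lt(mean(adj), 0.95)
})

test_that("cross-block correlation is near zero", {
  cfg <- small_config(n_ref = 1500, n_blocks = 2, block_size = 5,
                      ld_rho = 0.9)
  p <- simulate_reference_panel(cfg)
  R <- cor(p$dosages)
  cross <- R[1:5, 6:10]
  expect_lt(mean(abs(cross)), 0.06)
})

test_that("eQTL models honour sparsity, sharing and weight-variance accounting", {
  cfg <- small_config(eqtl_per_gene = c(1, 1))
  panel <- simulate_reference_panel(cfg)
  models <- simulate_eqtl_models(cfg, panel)
  expect_true(all(table(models$weights$gene, models$weights$tissue) <= 1))

  cfg2 <- small_config(shared_gene_fraction = 1, n_tissues = 3)
  m2 <- simulate_eqtl_models(cfg2, simulate_reference_panel(cfg2))
  sets <- split(m2$weights$gene, m2$weights$tissue)
  expect_identical(sort(unique(sets[[1]])), sort(unique(sets[[2]])))
  expect_identical(sort(unique(sets[[2]])), sort(unique(sets[[3]])))

  # predicted-expression variance w'Sigma w matches Monte Carlo within 10%
  cfg3 <- sim_config(n_ref = 2000, n_cohort = 5000, n_blocks = 2,
                     block_size = 10, eqtl_per_gene = c(5, 5),
                     n_tissues = 1, genes_per_tissue = 5,
                     shared_gene_fraction = 0, seed = 7)
  ref <- simulate_reference_panel(cfg3)
  m3 <- simulate_eqtl_models(cfg3, ref)
  sim <- simulate_cohort(cfg3, m3)
  grex <- predict_grex(sim$panel, m3$weights)
  ld <- compute_ld(ref)
  for (g in grex$genes) {
    wt <- m3$weights[m3$weights$gene == g, ]
    li <- match(wt$variant_id, ld$ids)
    Sg <- ld$matrix[li, li] * tcrossprod(ld$sd[li])
    v_theory <- drop(crossprod(wt$weight, Sg %*% wt$weight))
    v_mc <- var(grex$values[, g])
    expect_lt(abs(v_mc - v_theory) / v_theory, 0.12)
  }
})

test_that("cohort prevalence, missingness and heritability match configuration", {
  cfg <- sim_config(n_cohort = 50000, n_blocks = 5, block_size = 10,
                    n_ref = 300, n_tissues = 2, genes_per_tissue = 10,
                    prevalence = 0.04, missing_rate = 0.03, seed = 5)
  models <- simulate_eqtl_models(cfg, simulate_reference_panel(cfg))
  sim <- simulate_cohort(cfg, models)
  frac <- mean(sim$cohort$case)
  expect_gt(frac, 0.035); expect_lt(frac, 0.045)
  miss <- mean(is.na(sim$cohort$eosinophils))
  expect_gt(miss, 0.025); expect_lt(miss, 0.035)
  expect_lt(abs(var(sim$truth$components$mediated) - cfg$h2_mediated) /
              cfg$h2_mediated, 0.1)
  expect_lt(abs(var(sim$truth$components$direct) - cfg$h2_direct) /
              cfg$h2_direct, 0.1)
  expect_lt(abs(var(sim$truth$liability) - 1), 0.1)
})

test_that("null heritability decouples case status from genotype score", {
  cfg <- sim_config(n_cohort = 20000, n_blocks = 4, block_size = 10,
                    n_ref = 300, n_tissues = 2, genes_per_tissue = 8,
                    h2_mediated = 0, h2_direct = 0, seed = 9)
  models <- simulate_eqtl_models(cfg, simulate_reference_panel(cfg))
  sim <- simulate_cohort(cfg, models)
  set.seed(1)
  sc <- ptrskit:::new_score_vector(
    sim$cohort$sample_id, drop(sim$panel$dosages %*% rnorm(40)), "PRS")
  cs <- adjusted_cstat(sc, sim$cohort, character(0), ci_method = "none")
  expect_gt(cs$estimate, 0.48); expect_lt(cs$estimate, 0.52)
})

test_that("blood counts carry the configured signed liability effects", {
  cfg <- sim_config(n_cohort = 50000, n_blocks = 4, block_size = 10,
                    n_ref = 300, n_tissues = 2, genes_per_tissue = 8,
                    missing_rate = 0, seed = 21)
  models <- simulate_eqtl_models(cfg, simulate_reference_panel(cfg))
  sim <- simulate_cohort(cfg, models)
  d <- sim$cohort
  d$eos_int <- rank_inverse_normal(d$eosinophils)
  d$lymph_int <- rank_inverse_normal(d$lymphocytes)
  fe <- summary(glm(case ~ eos_int, binomial(), d))$coefficients
  fl <- summary(glm(case ~ lymph_int, binomial(), d))$coefficients
  expect_gt(fe["eos_int", "z value"], 3)
  expect_lt(fl["lymph_int", "z value"], -3)
  expect_gt(mean(d$eosinophils[d$case == 1]), mean(d$eosinophils[d$case == 0]))
  expect_lt(mean(d$lymphocytes[d$case == 1]), mean(d$lymphocytes[d$case == 0]))
})

test_that("null summary statistics are calibrated", {
  cfg <- sim_config(n_ref = 400, n_cohort = 100, n_blocks = 250,
                    block_size = 40, ld_rho = 0.5, h2_mediated = 0,
                    h2_direct = 0, n_tissues = 1, genes_per_tissue = 5,
                    seed = 3)
  panel <- simulate_reference_panel(cfg)
  truth <- list(gene_effects = tibble::tibble(gene = character(0),
                                              effect = numeric(0)),
                variant_effects = tibble::tibble(id = panel$variants$id,
                                                 effect = 0),
                weights = tibble::tibble())
  ss <- simulate_gwas_sumstats(cfg, truth, panel)
  expect_equal(nrow(ss), 10000)
  expect_lt(abs(mean(ss$z)), 0.03)
  expect_gt(var(ss$z), 0.95); expect_lt(var(ss$z), 1.05)
  ks <- suppressWarnings(stats::ks.test(ss$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-variant noncentrality follows the closed form", {
  # b_std = 0.02 at n = 500,000 gives E[z] = 0.02 * sqrt(5e5) = 14.14
  cfg <- sim_config(n_ref = 3000, n_cohort = 100, n_blocks = 2,
                    block_size = 1, ld_rho = 0, n_base_gwas = 5e5,
                    n_tissues = 1, genes_per_tissue = 1,
                    eqtl_per_gene = c(1, 1), seed = 11)
  panel <- simulate_reference_panel(cfg)
  sigma1 <- sd(panel$dosages[, 1])
  truth <- list(
    gene_effects = tibble::tibble(gene = character(0), effect = numeric(0)),
    variant_effects = tibble::tibble(id = panel$variants$id,
                                     effect = c(0.02 / sigma1, 0)),
    weights = tibble::tibble())
  zs <- vapply(1:200, function(s) {
    cfg$seed <- 5000L + s
    simulate_gwas_sumstats(cfg, truth, panel)$z[1]
  }, numeric(1))
  expect_gt(mean(zs), 13.5); expect_lt(mean(zs), 14.8)
})

test_that("LD leaks noncentrality onto null variants proportionally to r", {
  cfg <- sim_config(n_ref = 4000, n_cohort = 100, n_blocks = 1,
                    block_size = 2, ld_rho = 0.9, n_base_gwas = 5e5,
                    n_tissues = 1, genes_per_tissue = 1,
                    eqtl_per_gene = c(1, 1), seed = 13)
  panel <- simulate_reference_panel(cfg)
  r <- cor(panel$dosages)[1, 2]
  sigma1 <- sd(panel$dosages[, 1])
  truth <- list(
    gene_effects = tibble::tibble(gene = character(0), effect = numeric(0)),
    variant_effects = tibble::tibble(id = panel$variants$id,
                                     effect = c(0.02 / sigma1, 0)),
    weights = tibble::tibble())
  Z <- vapply(1:200, function(s) {
    cfg$seed <- 7000L + s
    simulate_gwas_sumstats(cfg, truth, panel)$z
  }, numeric(2))
  ratio <- mean(Z[2, ]) / mean(Z[1, ])
  expect_lt(abs(ratio - r), 0.06)
})

test_that("the whole generated study is deterministic in the seed", {
  cfg <- small_config(n_cohort = 500)
  run <- function() {
    panel <- simulate_reference_panel(cfg)
    models <- simulate_eqtl_models(cfg, panel)
    sim <- simulate_cohort(cfg, models)
    ss <- simulate_gwas_sumstats(cfg, sim$truth, panel)
    list(panel$dosages, models$weights, sim$cohort, sim$truth$liability, ss)
  }
  expect_identical(run(), run())
})
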