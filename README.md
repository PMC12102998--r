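# ptrskit

Risk-score modelling for a binary disease phenotype from GWAS summary
statistics: clumping-and-thresholding polygenic risk scores (PRS),
tissue-specific polygenic transcriptome risk scores (PTRS), clinical
baseline models, weighted score combination, and ROC-based evaluation
with DeLong comparisons — plus a liability-threshold study simulator
that makes the whole pipeline testable end to end.

## Who it is for

Statistical geneticists who want to compare *expression-mediated* genetic
risk against conventional variant-level risk for a common disease (the
motivating setting is atopic dermatitis: ~4% prevalence, polygenic, with
eosinophil counts raised and lymphocyte counts lowered in cases), using
only summary-level inputs: GWAS summary statistics, PredictDB-style
cis-eQTL weight tables, and an external LD reference panel.

## The scores

With genotype dosages `X_il`, GWAS effects `beta_l` and eQTL weights
`w_lg`:

- **PRS (C+T)** — greedy LD clumping (default r² > 0.1 within 250 kb)
  followed by P-value thresholding:
  `PRS_i = sum_{l: P_l <= t} beta_l X_il`, with `t` chosen by maximal
  covariate-adjusted AUC over a geometric grid from 5e-8 to 1.
- **GReX** — predicted expression `T_ig = sum_l w_lg X_il`.
- **Summary-level gene effects** (S-PrediXcan style) —
  `z_g = sum_l w_lg (sigma_l / sigma_g) z_l` with
  `sigma_g^2 = w' Sigma w` from the reference LD, and
  `beta_g = sum_l w_lg sigma_l^2 beta_l / sigma_g^2`.
- **PTRS** — `PTRS_i = sum_{g: P_g <= t} T_ig beta_g` over the fixed gene
  P-value grid `1, 0.1, 5e-2, ..., 5e-7, 1e-7`, the per-tissue threshold
  again chosen by maximal adjusted AUC.
- **Combined** — `w_prs PRS_i + w_ptrs PTRS_i` with weights from a joint
  logistic fit on the training split.

Scores are standardised on the training split (population SD) and
evaluated on the held-out test split with Harrell's c-statistic, DeLong
95% CIs and paired DeLong tests, adjusted for age, sex and ten genetic
principal components.

## Worked example

Everything below is simulated, analysed and printed by the package:

```r
library(ptrskit)

cfg <- sim_config(n_cohort = 10000, n_tissues = 3, genes_per_tissue = 20,
                  seed = 42)
res <- run_ptrs_pipeline(cfg, prs_thresholds = prs_threshold_grid(40))

tidy(res$baseline$fit)
#>   term        estimate      se statistic   pvalue  ci_low ci_high
#> 1 (Intercept)  -1.08   0.412      -2.63  8.47e- 3 -1.89   -0.277
#> 2 eos_int       0.548  0.0587      9.34  9.31e-21  0.433   0.663
#> 3 lymph_int    -0.428  0.0582     -7.35  1.94e-13 -0.542  -0.314
#> 4 age          -0.0420 0.00736    -5.71  1.16e- 8 -0.0564 -0.0276
#> 5 sex           0.0523 0.116       0.452 6.52e- 1 -0.175   0.280
```

The baseline model recovers the planted blood-count biology: eosinophils
raise disease odds (log-OR 0.55), lymphocytes lower them (log-OR −0.43).
The PRS threshold search selects P ≤ 0.116 with 82 clumped variants
(training c-statistic 0.794), and the test-set league table shows the
expression-mediated score from the causal tissue (`tissue01`) leading the
single scores, with the full model (baseline + PRS + PTRS) on top:

```r
res$evaluation$cstats
#>    model                      cstat ci_low ci_high n_cases n_controls
#>  1 baseline                   0.776  0.730   0.822      80       1920
#>  2 PRS                        0.810  0.767   0.853      80       1920
#>  3 PTRS_tissue01              0.814  0.770   0.858      80       1920
#>  4 PTRS_tissue02              0.734  0.685   0.782      80       1920
#>  ...
#> 10 baseline_PRS_PTRS_tissue01 0.878  0.845   0.910      80       1920

glance(res$evaluation)   # paired DeLong comparisons
#> 1 baseline  baseline_PRS  -0.0778 -0.116 -0.0391  0.0000825
#> ...
```

Adding the PRS to the baseline raises the test c-statistic by 0.078
(paired DeLong P = 8e-5). `autoplot(res$evaluation)` draws the forest
plot, `plot_threshold_report(res$prs_report)` the threshold search.

Simulated cohorts are much smaller than the biobank-scale studies this
design mirrors, so absolute c-statistics here are generous; the package's
claims are the *relative* orderings and the calibration properties that
the test suite verifies (see the methods vignette).

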