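# End-to-end pipeline: simulate -> QC/harmonise -> clump -> PRS search ->
# tissue enrichment -> TWAS -> PTRS grid/selection -> baseline ->
# interaction screen -> combined score -> evaluation.

#' Run the full risk-score pipeline on a synthetic study
#'
#' Chains every stage of the framework on data generated under `config`:
#' reference panel and cohort simulation, base-GWAS summary statistics, QC
#' and allele harmonisation (optionally region-wide z imputation), greedy
#' clumping and the PRS threshold search, gene-based tissue enrichment and
#' per-tissue summary TWAS, the PTRS grid with maximal-AUC selection,
#' blood-count transformation/imputation and the clinical baseline model,
#' PRS x PTRS interaction screening, the combined weighted score, and the
#' test-set evaluation suite with paired DeLong comparisons. All
#' randomness derives from `config$seed`, so a given configuration is
#' bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param tissues Explicit tissue selection overriding the enrichment test
#'   (default `NULL`: Bonferroni-significant tissues, falling back to all
#'   tissues when none is significant).
#' @param impute_z Run region-wide summary-statistic imputation for model
#'   variants missing from the (QC-filtered) statistics (default TRUE).
#' @param prs_thresholds Candidate PRS thresholds (default
#'   [prs_threshold_grid()]).
#' @param impute_method Chained-equations learner for missing blood counts
#'   (`"rf"` default, `"linear"` faster).
#' @param covariates Adjustment covariates (default [default_covariates()]).
#' @return A list with the generated data (`config`, `truth`, `cohort`),
#'   intermediate results (`sumstats`, `clumped`, `enrichment`,
#'   `twas`, `prs`, `ptrs`, `baseline`, `screen`, `combined`) and the
#'   final `evaluation` (`risk_eval_report`), `biomarkers` and
#'   `risk_interactions` tables.
#' @export
run_ptrs_pipeline <- function(config, tissues = NULL, impute_z = TRUE,
                              prs_thresholds = prs_threshold_grid(),
                              impute_method = c("rf", "linear"),
                              covariates = default_covariates()) {
  impute_method <- match.arg(impute_method)
  ref_panel <- simulate_reference_panel(config)
  models <- simulate_eqtl_models(config, ref_panel)
  sim <- simulate_cohort(config, models)
  cohort <- sim$cohort
  stats <- simulate_gwas_sumstats(config, sim$truth, ref_panel)
  stats <- qc_filter(stats)
  stats <- harmonize_sumstats(stats, ref_panel$variants)

  ld <- compute_ld(ref_panel)
  if (impute_z) {
    model_ids <- unique(models$weights$variant_id)
    missing_ids <- setdiff(intersect(model_ids, ld$ids), stats$id)
    if (length(missing_ids) > 0) {
      vb <- ref_panel$variants
      for (blk in unique(vb$block[match(missing_ids, vb$id)])) {
        blk_ld <- compute_ld(ref_panel, vb$id[vb$block == blk])
        stats <- impute_region_z(stats, blk_ld,
                                 intersect(missing_ids, blk_ld$ids))
      }
    }
  }

  clumped <- clump(stats, ref_panel)
  prs_search <- threshold_search(sim$panel, stats, clumped, cohort,
                                 covariates, prs_thresholds)
  prs <- prs_search$score

  gene_regions <- models$weights |>
    dplyr::left_join(ref_panel$variants[c("id", "chrom", "pos")],
                     by = c(variant_id = "id")) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$pos),
                     end = max(.data$pos), .groups = "drop")
  gene_z <- gene_test_all(stats, ld, gene_regions)
  enrichment <- tissue_property(gene_z, models$expression,
                                n_tissues = config$n_tissues)
  if (is.null(tissues)) {
    tissues <- enrichment$tissue[which(enrichment$significant)]
    if (length(tissues) == 0) {
      inform("pipeline: no tissue reached Bonferroni significance; using all tissues")
      tissues <- enrichment$tissue
    }
  }

  grex_list <- list(); assoc_list <- list()
  for (t in tissues) {
    wt <- dplyr::filter(models$weights, .data$tissue == t)
    grex_list[[t]] <- predict_grex(sim$panel, wt)
    assoc_list[[t]] <- spredixcan(stats, wt, ld)
  }
  ptrs_sel <- select_best_ptrs(grex_list, assoc_list, cohort, covariates)

  cohort_imp <- impute_missing(cohort, method = impute_method,
                               seed = sub_seed(config$seed, 7L))
  baseline <- fit_baseline(cohort_imp)

  screen <- interaction_screen(prs, ptrs_sel$scores, cohort, covariates)
  kept <- if (length(screen$kept) > 0) screen$kept else names(ptrs_sel$scores)
  kept_report <- dplyr::filter(ptrs_sel$report, .data$selected,
                               .data$tissue %in% kept)
  best_tissue <- kept_report$tissue[which.max(kept_report$cstat)]
  combined <- combine_scores(prs, ptrs_sel$scores[[best_tissue]], cohort,
                             covariates)

  scores <- c(list(baseline = baseline$score, PRS = prs),
              setNames(ptrs_sel$scores,
                       paste0("PTRS_", names(ptrs_sel$scores))),
              list(combined = combined))
  families <- c(
    list(baseline = "baseline", PRS = "PRS"),
    setNames(as.list(paste0("PTRS_", names(ptrs_sel$scores))),
             paste0("PTRS_", names(ptrs_sel$scores))),
    list(baseline_PRS = c("baseline", "PRS")),
    setNames(lapply(kept, function(t) c("baseline", paste0("PTRS_", t))),
             paste0("baseline_PTRS_", kept)),
    setNames(lapply(kept, function(t) c("baseline", "PRS", paste0("PTRS_", t))),
             paste0("baseline_PRS_PTRS_", kept))
  )
  evaluation <- evaluate_suite(cohort_imp, scores, families, covariates)

  biomarkers <- biomarker_association(cohort_imp, prs, ptrs_sel$scores,
                                      covariates = covariates)
  risk_int <- risk_interaction(cohort_imp, ptrs_sel$scores, covariates)

  list(config = config, truth = sim$truth, cohort = cohort_imp,
       ref_panel = ref_panel, cohort_panel = sim$panel,
       weights = models$weights, expression = models$expression,
       sumstats = stats, clumped = clumped,
       prs = prs, prs_report = prs_search$report,
       enrichment = enrichment, gene_z = gene_z,
       twas = assoc_list, grex = grex_list,
       ptrs = ptrs_sel$scores, ptrs_report = ptrs_sel$report,
       baseline = baseline, screen = screen,
       best_tissue = best_tissue, combined = combined,
       evaluation = evaluation, biomarkers = biomarkers,
       risk_interactions = risk_int)
}
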