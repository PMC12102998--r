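#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator into a validated list.
#' The defaults describe the study conditions the package is exercised under:
#' a cohort of 50,000 individuals with 4% case prevalence under a
#' liability-threshold model, equal direct-variant and expression-mediated
#' heritability components (0.2 each), a base GWAS of about half a million
#' individuals summarised analytically from block LD, an LD reference panel
#' of 633 individuals, sparse per-tissue cis-eQTL weight models, and blood
#' cell counts (eosinophils up in cases, lymphocytes down) with 3%
#' missingness.
#'
#' @param n_ref Number of individuals in the external LD reference panel.
#' @param n_cohort Number of individuals in the target cohort.
#' @param n_base_gwas Effective sample size of the external base GWAS whose
#'   summary statistics are generated.
#' @param n_blocks Number of independent LD blocks.
#' @param block_size Variants per LD block.
#' @param ld_rho Target adjacent-variant genotype correlation within a block,
#'   in `[0, 1)`. The latent Gaussian copula is calibrated so the *dosage*
#'   correlation (not the latent correlation) matches this value.
#' @param maf_range Length-2 bounds for minor allele frequencies, in
#'   `(0, 0.5]`. Within a block frequencies are drawn around a shared anchor,
#'   mirroring the frequency similarity of variants in strong LD.
#' @param n_tissues Number of tissues with eQTL weight models.
#' @param genes_per_tissue Genes per tissue model.
#' @param eqtl_per_gene Length-2 range for the number of cis-eQTL weights per
#'   gene.
#' @param shared_gene_fraction Fraction of each tissue's genes drawn from a
#'   gene set common to all tissues.
#' @param h2_mediated Liability variance explained by expression-mediated
#'   effects, in `[0, 1)`.
#' @param h2_direct Liability variance explained by direct variant effects,
#'   in `[0, 1)`.
#' @param causal_tissue Index of the tissue whose genes carry the mediated
#'   liability effects.
#' @param causal_gene_fraction Fraction of the causal tissue's genes with a
#'   nonzero liability effect.
#' @param causal_variant_fraction Fraction of variants with a nonzero direct
#'   liability effect.
#' @param prevalence Expected case fraction, in `(0, 1)`.
#' @param blood_count_effects Named numeric vector with elements
#'   `eosinophils` and `lymphocytes`: correlation of each latent blood-count
#'   driver with the (standardised) liability. The defaults carry the signs
#'   seen in atopic disease: eosinophils positive, lymphocytes negative.
#' @param interaction_strength Coefficient of a planted liability interaction
#'   between the standardised mediated genetic component and the lymphocyte
#'   latent driver. Zero (the default) means no interaction.
#' @param missing_rate Fraction of individuals with missing blood counts
#'   (missing completely at random; both counts missing together, as when a
#'   blood draw is absent).
#' @param train_fraction Training fraction of the stratified cohort split.
#' @param seed Integer seed; every random draw in the generator derives from
#'   it, so identical configurations give bit-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_ref = 200, n_cohort = 500, n_blocks = 4,
#'                   block_size = 10, seed = 1)
#' cfg$n_variants
sim_config <- function(n_ref = 633,
                       n_cohort = 50000,
                       n_base_gwas = 527948,
                       n_blocks = 20,
                       block_size = 25,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_tissues = 7,
                       genes_per_tissue = 50,
                       eqtl_per_gene = c(1, 5),
                       shared_gene_fraction = 0.3,
                       h2_mediated = 0.2,
                       h2_direct = 0.2,
                       causal_tissue = 1,
                       causal_gene_fraction = 0.5,
                       causal_variant_fraction = 0.2,
                       prevalence = 0.04,
                       blood_count_effects = c(eosinophils = 0.25,
                                               lymphocytes = -0.15),
                       interaction_strength = 0,
                       missing_rate = 0.03,
                       train_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_ref = as.integer(n_ref), n_cohort = as.integer(n_cohort),
    n_base_gwas = n_base_gwas, n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), ld_rho = ld_rho,
    maf_range = maf_range, n_tissues = as.integer(n_tissues),
    genes_per_tissue = as.integer(genes_per_tissue),
    eqtl_per_gene = as.integer(eqtl_per_gene),
    shared_gene_fraction = shared_gene_fraction,
    h2_mediated = h2_mediated, h2_direct = h2_direct,
    causal_tissue = as.integer(causal_tissue),
    causal_gene_fraction = causal_gene_fraction,
    causal_variant_fraction = causal_variant_fraction,
    prevalence = prevalence,
    blood_count_effects = blood_count_effects,
    interaction_strength = interaction_strength,
    missing_rate = missing_rate,
    train_fraction = train_fraction,
    seed = as.integer(seed)
  )
  cfg$n_variants <- cfg$n_blocks * cfg$block_size
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid simulation config: ", msg))
  chk(cfg$n_ref > 0 && cfg$n_cohort > 0 && cfg$n_blocks > 0 &&
        cfg$block_size > 0 && cfg$n_tissues > 0 && cfg$genes_per_tissue > 0,
      "all counts must be positive")
  chk(cfg$n_base_gwas > 0, "n_base_gwas must be positive")
  chk(cfg$ld_rho >= 0 && cfg$ld_rho < 1, "ld_rho must be in [0, 1)")
  chk(length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
        cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2],
      "maf_range must be increasing bounds in (0, 0.5]")
  chk(length(cfg$eqtl_per_gene) == 2 && cfg$eqtl_per_gene[1] >= 1 &&
        cfg$eqtl_per_gene[1] <= cfg$eqtl_per_gene[2],
      "eqtl_per_gene must be a positive increasing range")
  chk(cfg$eqtl_per_gene[2] <= cfg$block_size,
      "eqtl_per_gene cannot exceed block_size")
  chk(cfg$h2_mediated >= 0 && cfg$h2_direct >= 0 &&
        cfg$h2_mediated + cfg$h2_direct < 1,
      "h2_mediated + h2_direct must be < 1")
  chk(cfg$prevalence > 0 && cfg$prevalence < 1, "prevalence must be in (0, 1)")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
      "missing_rate must be in [0, 1)")
  chk(cfg$causal_tissue >= 1 && cfg$causal_tissue <= cfg$n_tissues,
      "causal_tissue out of range")
  chk(all(c("eosinophils", "lymphocytes") %in% names(cfg$blood_count_effects)),
      "blood_count_effects must name eosinophils and lymphocytes")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort n=%d (prevalence %.3f), reference n=%d, base GWAS n=%g\n",
              x$n_cohort, x$prevalence, x$n_ref, x$n_base_gwas))
  cat(sprintf("  %d blocks x %d variants, target adjacent r=%.2f, MAF [%.2f, %.2f]\n",
              x$n_blocks, x$block_size, x$ld_rho,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  %d tissues x %d genes, h2 mediated/direct = %.2f/%.2f, seed %d\n",
              x$n_tissues, x$genes_per_tissue, x$h2_mediated, x$h2_direct,
              x$seed))
  invisible(x)
}
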