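# Analytic base-GWAS summary statistics: per-block z-scores drawn from the
# multivariate normal implied by the LD matrix and the standardised joint
# effects, rather than by simulating the base cohort individual by
# individual. This reproduces the LD-induced correlation of z-scores at
# desk scale.

#' Simulate base GWAS summary statistics
#'
#' For each LD block, draws `z ~ N(sqrt(n) * R %*% b_std, R)` where `R` is
#' the block LD (correlation) matrix estimated from the reference panel and
#' `b_std` the standardised joint liability effects (direct plus
#' expression-mediated, per genotype SD). Effect sizes and standard errors
#' are back-computed as `se = 1/sqrt(2 f (1-f) n)`, `beta = z * se`, with
#' `f` the panel effect-allele frequency; two-sided P from the normal.
#' Effect allele is the panel alt allele.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth list from [simulate_cohort()] (or a list with
#'   `gene_effects`, `variant_effects`, `weights`, `variant_map`).
#' @param panel Reference `genotype_panel` supplying LD and frequencies.
#' @param ridge Diagonal inflation used when a block LD matrix is not
#'   positive definite; applied automatically and reported with a message.
#' @return A summary-statistics tibble (chrom, pos, id, effect_allele,
#'   other_allele, eaf, beta, se, pvalue, n, z).
#' @export
simulate_gwas_sumstats <- function(config, truth, panel, ridge = 1e-4) {
  validate_sim_config(config)
  vmap <- panel$variants
  n_gwas <- config$n_base_gwas
  withr::local_seed(sub_seed(config$seed, 6L))

  # joint per-dosage effects: direct + sum over genes of alpha_g * w_lg
  b_dos <- truth$variant_effects$effect[match(vmap$id, truth$variant_effects$id)]
  b_dos[is.na(b_dos)] <- 0
  if (nrow(truth$gene_effects) > 0) {
    causal_tissue <- sprintf("tissue%02d", config$causal_tissue)
    wt <- dplyr::filter(truth$weights, .data$tissue == causal_tissue,
                        .data$gene %in% truth$gene_effects$gene)
    if (nrow(wt) > 0) {
      Wm <- weight_matrix(wt, vmap)
      alpha <- truth$gene_effects$effect[match(colnames(Wm),
                                               truth$gene_effects$gene)]
      med <- drop(Wm %*% alpha)
      b_dos[match(rownames(Wm), vmap$id)] <-
        b_dos[match(rownames(Wm), vmap$id)] + med
    }
  }

  eaf <- colMeans(panel$dosages) / 2
  eaf <- pmin(pmax(eaf, 1 / (2 * length(panel$samples))),
              1 - 1 / (2 * length(panel$samples)))
  sigma <- sqrt(2 * eaf * (1 - eaf))
  b_std <- b_dos * sigma

  z <- numeric(nrow(vmap))
  for (blk in unique(vmap$block)) {
    idx <- which(vmap$block == blk)
    R <- stats::cor(panel$dosages[, idx, drop = FALSE])
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) {
      inform(sprintf("block %s LD matrix not positive definite; ridge %.1e applied",
                     blk, ridge))
      ch <- chol(R + diag(ridge, nrow(R)))
    }
    mu <- sqrt(n_gwas) * drop(R %*% b_std[idx])
    z[idx] <- mu + drop(crossprod(ch, rnorm(length(idx))))
  }

  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n_gwas)
  tibble::tibble(
    chrom = vmap$chrom, pos = vmap$pos, id = vmap$id,
    effect_allele = vmap$alt, other_allele = vmap$ref,
    eaf = unname(eaf), beta = z * se, se = unname(se),
    pvalue = z_to_p(z), n = n_gwas, z = z
  )
}
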