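# Genetically regulated expression (GReX) prediction and summary-level
# (S-PrediXcan-style) gene association.

#' Predict genetically regulated expression
#'
#' `T_ig = sum over model variants of w_lg * X_il`, with dosage counted on
#' the model's effect allele: when the model effect allele is the panel ref
#' allele the contribution uses `2 - X`. Genes with no variant overlap are
#' dropped and reported.
#'
#' @param panel A `genotype_panel`.
#' @param model Weight table for one tissue (columns gene, variant_id,
#'   effect_allele, other_allele, weight; a `tissue` column restricts
#'   nothing but labels the result).
#' @return A `grex_matrix`: list with `samples`, `genes`, `values`
#'   (samples x genes), `tissue`, and `dropped_genes`.
#' @export
predict_grex <- function(panel, model) {
  stopifnot_cols(model, c("gene", "variant_id", "effect_allele", "weight"),
                 "weight model")
  tissue <- if ("tissue" %in% names(model)) unique(model$tissue)[1] else NA_character_
  v <- panel$variants
  m <- model[model$variant_id %in% v$id, , drop = FALSE]
  dropped <- setdiff(unique(model$gene), unique(m$gene))
  if (length(dropped) > 0) {
    inform(sprintf("predict_grex: %d gene(s) with no scored variants dropped",
                   length(dropped)))
  }
  if (nrow(m) == 0) {
    return(structure(list(samples = panel$samples, genes = character(0),
                          values = matrix(0, length(panel$samples), 0),
                          tissue = tissue, dropped_genes = dropped),
                     class = "grex_matrix"))
  }
  vi <- match(m$variant_id, v$id)
  flip <- m$effect_allele == v$ref[vi]        # effect allele is panel ref
  valid <- m$effect_allele == v$alt[vi] | flip
  m <- m[valid, , drop = FALSE]; vi <- vi[valid]; flip <- flip[valid]
  X <- mean_impute(panel$dosages[, v$id[vi], drop = FALSE])
  genes <- unique(m$gene)
  W <- matrix(0, ncol(X), length(genes),
              dimnames = list(colnames(X), genes))
  # 2 - X contribution: w*(2-X) = 2w - w*X, i.e. a constant offset and a
  # sign flip of the weight
  w_eff <- ifelse(flip, -m$weight, m$weight)
  W[cbind(seq_len(nrow(m)), match(m$gene, genes))] <- w_eff
  offset <- tapply(ifelse(flip, 2 * m$weight, 0), m$gene, sum)[genes]
  values <- X %*% W
  values <- sweep(values, 2, ifelse(is.na(offset), 0, offset), "+")
  structure(list(samples = panel$samples, genes = genes, values = values,
                 tissue = tissue,
                 dropped_genes = union(dropped, setdiff(unique(model$gene), genes))),
            class = "grex_matrix")
}

#' @export
print.grex_matrix <- function(x, ...) {
  cat(sprintf("<grex_matrix> %s: %d samples x %d genes\n",
              x$tissue %||% "?", length(x$samples), length(x$genes)))
  invisible(x)
}

#' Summary-level gene association (S-PrediXcan-style)
#'
#' Combines per-variant GWAS z-scores with the eQTL weights and reference
#' LD:
#' `z_g = sum_l w_lg (sigma_l / sigma_g) z_l` with
#' `sigma_g^2 = w' Sigma w` (the predicted-expression variance over the
#' model variants found in the statistics), and the gene effect
#' `beta_g = sum_l w_lg sigma_l^2 beta_l / sigma_g^2`. Both `sigma_l` and
#' `Sigma` come from the external reference panel, never the GWAS. Variants
#' absent from the statistics are dropped from the gene's weights before
#' computing `sigma_g^2`; genes with `sigma_g^2 <= eps` or no overlapping
#' variants are skipped and counted.
#'
#' @param stats Harmonised summary statistics.
#' @param model Weight table for one tissue.
#' @param ld An `ld_matrix` from the reference panel covering the model
#'   variants.
#' @param eps Positive-variance guard (default 1e-8).
#' @return Tibble (gene, tissue, zscore, effect, pvalue, n_snps_used,
#'   pred_var) with attribute `n_skipped`.
#' @export
spredixcan <- function(stats, model, ld, eps = 1e-8) {
  stopifnot_cols(model, c("gene", "variant_id", "effect_allele", "weight"),
                 "weight model")
  tissue <- if ("tissue" %in% names(model)) unique(model$tissue)[1] else NA_character_
  m <- model[model$variant_id %in% stats$id & model$variant_id %in% ld$ids, ,
             drop = FALSE]
  # orient weights to the reference alt allele (z is per alt allele)
  li <- match(m$variant_id, ld$ids)
  flip <- m$effect_allele == ld$ref[li]
  valid <- m$effect_allele == ld$alt[li] | flip
  m <- m[valid, , drop = FALSE]
  m$weight[flip[valid]] <- -m$weight[flip[valid]]
  skipped <- 0L
  res <- purrr::map_dfr(split(m, m$gene), function(g) {
    ids <- g$variant_id
    si <- match(ids, stats$id)
    li <- match(ids, ld$ids)
    w <- g$weight
    sig <- ld$sd[li]
    Sigma <- ld$matrix[li, li, drop = FALSE] * tcrossprod(sig)
    s2 <- drop(crossprod(w, Sigma %*% w))
    if (!is.finite(s2) || s2 <= eps) {
      skipped <<- skipped + 1L
      return(tibble::tibble())
    }
    zg <- sum(w * sig * stats$z[si]) / sqrt(s2)
    bg <- sum(w * sig^2 * stats$beta[si]) / s2
    tibble::tibble(gene = g$gene[1], tissue = tissue, zscore = zg,
                   effect = bg, pvalue = z_to_p(zg),
                   n_snps_used = length(ids), pred_var = s2)
  })
  n_missing <- length(setdiff(unique(model$gene),
                              unique(m$gene)))
  if (n_missing + skipped > 0) {
    inform(sprintf(
      "spredixcan: skipped %d gene(s) with no stats overlap and %d with degenerate variance",
      n_missing, skipped))
  }
  attr(res, "n_skipped") <- n_missing + skipped
  res
}

#' Bonferroni threshold across tested gene-tissue pairs
#'
#' @param assoc Gene-association tibble (possibly several tissues bound
#'   together).
#' @param alpha Family-wise level (default 0.05).
#' @return The corrected per-test threshold `alpha / n_tests`.
#' @export
twas_bonferroni <- function(assoc, alpha = 0.05) {
  n <- nrow(assoc)
  if (n == 0) return(NA_real_)
  alpha / n
}
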