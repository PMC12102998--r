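# Sparse per-tissue cis-eQTL weight models, emulating fine-mapped
# (MASHR/PredictDB-style) prediction tables: each gene has a handful of
# nonzero variant weights drawn from a single LD block.

#' Simulate per-tissue eQTL weight models
#'
#' Generates `config$n_tissues` weight tables. A configurable fraction of
#' genes is shared across all tissues (with tissue-specific weights); the
#' rest are tissue-exclusive. Each gene is anchored to one LD block and
#' receives `eqtl_per_gene` nonzero weights on distinct variants of that
#' block, drawn `N(0, 1)`, with effect allele equal to the panel alt allele.
#' A gene-by-tissue expression matrix is also produced for the tissue
#' enrichment test: genes express above baseline in the tissues whose model
#' contains them.
#'
#' @param config A [sim_config()].
#' @param panel The reference [simulate_reference_panel()] output (supplies
#'   variant metadata).
#' @return A list with `weights` (tibble: tissue, gene, variant_id,
#'   effect_allele, other_allele, weight), `genes` (tibble: gene, block,
#'   shared), and `expression` (tibble: gene plus one column per tissue).
#' @export
simulate_eqtl_models <- function(config, panel) {
  validate_sim_config(config)
  vmap <- panel$variants
  stopifnot_cols(vmap, c("id", "ref", "alt", "block"), "panel$variants")
  withr::local_seed(sub_seed(config$seed, 3L))

  G <- config$genes_per_tissue
  n_shared <- round(config$shared_gene_fraction * G)
  n_unique <- G - n_shared
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))

  shared_genes <- if (n_shared > 0) sprintf("GS%04d", seq_len(n_shared)) else character(0)
  gene_sets <- lapply(seq_len(config$n_tissues), function(t) {
    uniq <- if (n_unique > 0) sprintf("GT%d_%04d", t, seq_len(n_unique)) else character(0)
    c(shared_genes, uniq)
  })
  all_genes <- unique(unlist(gene_sets))
  gene_block <- sample(config$n_blocks, length(all_genes), replace = TRUE)
  names(gene_block) <- all_genes

  rows <- list()
  for (t in seq_len(config$n_tissues)) {
    for (g in gene_sets[[t]]) {
      blk <- gene_block[[g]]
      cand <- which(vmap$block == blk)
      k <- sample(seq(config$eqtl_per_gene[1], config$eqtl_per_gene[2]), 1)
      pick <- sample(cand, min(k, length(cand)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tissue = tissues[t], gene = g,
        variant_id = vmap$id[pick],
        effect_allele = vmap$alt[pick],
        other_allele = vmap$ref[pick],
        weight = rnorm(length(pick))
      )
    }
  }
  weights <- dplyr::bind_rows(rows)

  # expression: baseline 1, +2 where the tissue models the gene, noise 0.5
  in_tissue <- vapply(seq_len(config$n_tissues), function(t) {
    all_genes %in% gene_sets[[t]]
  }, logical(length(all_genes)))
  expr <- 1 + 2 * in_tissue +
    matrix(rnorm(length(all_genes) * config$n_tissues, sd = 0.5),
           ncol = config$n_tissues)
  colnames(expr) <- tissues
  expression <- dplyr::bind_cols(tibble::tibble(gene = all_genes),
                                 tibble::as_tibble(expr))

  genes <- tibble::tibble(
    gene = all_genes,
    block = unname(gene_block),
    shared = all_genes %in% shared_genes
  )
  list(weights = weights, genes = genes, expression = expression)
}
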