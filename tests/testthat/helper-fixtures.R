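# Shared fixtures and independent oracles used across the suite.

# small, fast simulation configuration
small_config <- function(...) {
  defaults <- list(n_ref = 300, n_cohort = 2000, n_blocks = 4,
                   block_size = 10, n_tissues = 2, genes_per_tissue = 10,
                   eqtl_per_gene = c(1, 3),
                   shared_gene_fraction = 0, seed = 42L)
  do.call(sim_config, modifyList(defaults, list(...)))
}

# hand-built genotype panel from an explicit dosage matrix
toy_panel <- function(X, chrom = "1", pos = NULL, ref = "G", alt = "A") {
  m <- ncol(X)
  pos <- pos %||% (seq_len(m) * 1000L)
  variants <- tibble::tibble(
    chrom = rep(chrom, m), pos = as.integer(pos),
    id = colnames(X) %||% sprintf("v%03d", seq_len(m)),
    ref = rep(ref, length.out = m), alt = rep(alt, length.out = m)
  )
  colnames(X) <- variants$id
  ptrskit:::new_genotype_panel(sprintf("s%03d", seq_len(nrow(X))), variants, X)
}

# hand-built summary statistics
toy_sumstats <- function(id, beta, se = 1, pvalue = NULL, eaf = 0.3,
                         chrom = "1", pos = NULL, ea = "A", oa = "G",
                         n = 10000) {
  m <- length(id)
  z <- beta / se
  tibble::tibble(
    chrom = rep(chrom, length.out = m),
    pos = as.integer(pos %||% (seq_len(m) * 1000L)),
    id = id,
    effect_allele = rep(ea, length.out = m),
    other_allele = rep(oa, length.out = m),
    eaf = rep(eaf, length.out = m),
    beta = beta, se = rep(se, length.out = m),
    pvalue = pvalue %||% (2 * pnorm(-abs(z))),
    n = rep(n, length.out = m), z = z
  )
}

# hand-built LD matrix object
toy_ld <- function(R, ids = NULL, sd = 1, eaf = 0.3, pos = NULL,
                   chrom = "1", ref = "G", alt = "A") {
  m <- nrow(R)
  ids <- ids %||% sprintf("v%03d", seq_len(m))
  structure(list(
    ids = ids, matrix = R,
    eaf = rep(eaf, length.out = m), sd = rep(sd, length.out = m),
    chrom = rep(chrom, m), pos = as.integer(pos %||% (seq_len(m) * 1000L)),
    ref = rep(ref, length.out = m), alt = rep(alt, length.out = m),
    dropped = character(0)
  ), class = "ld_matrix")
}

# --- independent oracles -------------------------------------------------

# exhaustive clumping reference: after every removal, re-scan all remaining
# pairs from scratch (no incremental bookkeeping shared with clump())
clump_oracle <- function(stats, panel, r2_max, window_kb) {
  X <- panel$dosages
  remaining <- stats[order(stats$pvalue, stats$pos, stats$id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$id)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (k in seq_len(nrow(remaining))) {
      cand <- remaining[k, ]
      if (cand$chrom != idx$chrom) next
      if (abs(cand$pos - idx$pos) > window_kb * 1000) next
      if (!(idx$id %in% colnames(X)) || !(cand$id %in% colnames(X))) next
      r <- suppressWarnings(cor(X[, idx$id], X[, cand$id]))
      if (!is.na(r) && r^2 > r2_max) drop[k] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}

# naive per-individual scoring loops
prs_loop_oracle <- function(panel, stats, ids, p_threshold) {
  sel <- stats[stats$id %in% ids & stats$pvalue <= p_threshold, ]
  X <- ptrskit:::mean_impute(panel$dosages)
  vapply(seq_len(nrow(X)), function(i) {
    tot <- 0
    for (k in seq_len(nrow(sel))) tot <- tot + sel$beta[k] * X[i, sel$id[k]]
    tot
  }, numeric(1))
}

ptrs_loop_oracle <- function(grex, assoc, p_threshold) {
  sel <- assoc[assoc$pvalue <= p_threshold & assoc$gene %in% grex$genes, ]
  vapply(seq_along(grex$samples), function(i) {
    tot <- 0
    for (k in seq_len(nrow(sel))) {
      tot <- tot + grex$values[i, sel$gene[k]] * sel$effect[k]
    }
    tot
  }, numeric(1))
}

# logistic regression by hand-rolled iteratively reweighted least squares
irls_logistic_oracle <- function(X, y, maxit = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    zresp <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * zresp))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

# linear regression by normal equations
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# area under the empirical ROC curve by the trapezoidal rule
trapezoid_auc_oracle <- function(pred, case) {
  th <- sort(unique(pred), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(pred[case == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(pred[case == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# concordance with ties counted one half, by explicit pair enumeration
pairwise_cstat_oracle <- function(pred, case) {
  x <- pred[case == 1]; y <- pred[case == 0]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}
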