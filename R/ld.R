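# LD matrices from a reference panel, and greedy P-value clumping.

#' Compute an LD (correlation) matrix from a reference panel
#'
#' Pearson correlation of dosages over a set of variants, with per-variant
#' missing dosages mean-imputed. Monomorphic variants are excluded and
#' reported. Optional Ledoit-Wolf-style shrinkage toward the identity for
#' small panels.
#'
#' @param panel A `genotype_panel`.
#' @param ids Variant ids to include (default: all panel variants).
#' @param shrinkage Shrinkage intensity in `[0, 1]` toward the identity
#'   (default 0, none).
#' @return An `ld_matrix`: list with `ids`, `matrix` (symmetric, unit
#'   diagonal), `eaf`, `sd` (genotype SD), `chrom`, `pos`, `ref`, `alt`,
#'   and `dropped` (monomorphic ids).
#' @export
compute_ld <- function(panel, ids = NULL, shrinkage = 0) {
  v <- panel$variants
  ids <- ids %||% v$id
  miss <- setdiff(ids, v$id)
  if (length(miss) > 0) {
    abort(sprintf("compute_ld: %d variant(s) absent from panel", length(miss)))
  }
  X <- mean_impute(panel$dosages[, ids, drop = FALSE])
  sds <- apply(X, 2, sd)
  mono <- sds == 0 | !is.finite(sds)
  if (all(mono)) abort("compute_ld: no polymorphic variants in region")
  if (any(mono)) {
    inform(sprintf("compute_ld: excluded %d monomorphic variant(s)", sum(mono)))
  }
  keep <- ids[!mono]
  X <- X[, keep, drop = FALSE]
  R <- stats::cor(X)
  if (shrinkage > 0) {
    R <- (1 - shrinkage) * R + shrinkage * diag(nrow(R))
  }
  R <- (R + t(R)) / 2
  diag(R) <- 1
  vi <- match(keep, v$id)
  structure(list(
    ids = keep, matrix = R,
    eaf = colMeans(panel$dosages[, keep, drop = FALSE], na.rm = TRUE) / 2,
    sd = sds[!mono],
    chrom = v$chrom[vi], pos = v$pos[vi], ref = v$ref[vi], alt = v$alt[vi],
    dropped = ids[mono]
  ), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants\n", length(x$ids)))
  invisible(x)
}

#' Greedy P-value clumping
#'
#' Repeatedly takes the smallest-P unclaimed variant as an index and removes
#' all unclaimed variants within `window_kb` of it whose squared correlation
#' with the index exceeds `r2_max`. The retained set contains no pair within
#' the window with `r^2 > r2_max`, and always contains the global
#' minimum-P variant. P-value ties break by smaller position, then
#' lexicographic id, so output is invariant to input row order. Variants
#' absent from the panel are treated as unlinked and logged.
#'
#' @param stats Summary statistics harmonised to the panel.
#' @param panel A `genotype_panel` used for LD.
#' @param r2_max Squared-correlation threshold (default 0.1).
#' @param window_kb Window half-width in kilobases (default 250).
#' @return Tibble of retained variants (id, chrom, pos, pvalue, n_members)
#'   ordered by P, with attribute `members`: list of removed member ids per
#'   index.
#' @export
clump <- function(stats, panel, r2_max = 0.1, window_kb = 250) {
  stopifnot_cols(stats, c("id", "chrom", "pos", "pvalue"), "summary statistics")
  ord <- order(stats$pvalue, stats$pos, stats$id)
  s <- stats[ord, , drop = FALSE]
  in_panel <- s$id %in% panel$variants$id
  if (any(!in_panel)) {
    inform(sprintf("clump: %d variant(s) absent from panel treated as unlinked",
                   sum(!in_panel)))
  }
  X <- panel$dosages
  Xc <- NULL  # lazily centred/scaled columns for correlation
  window <- window_kb * 1000
  n <- nrow(s)
  state <- rep("free", n)  # free | index | removed
  members <- list()
  for (i in seq_len(n)) {
    if (state[i] != "free") next
    state[i] <- "index"
    cand <- which(state == "free" & s$chrom == s$chrom[i] &
                    abs(s$pos - s$pos[i]) <= window)
    if (length(cand) == 0 || !in_panel[i]) {
      members[[s$id[i]]] <- character(0)
      next
    }
    cand <- cand[in_panel[cand]]
    if (length(cand) == 0) {
      members[[s$id[i]]] <- character(0)
      next
    }
    xi <- X[, s$id[i]]
    r <- suppressWarnings(
      stats::cor(xi, X[, s$id[cand], drop = FALSE])[1, ])
    hit <- cand[!is.na(r) & r^2 > r2_max]
    state[hit] <- "removed"
    members[[s$id[i]]] <- s$id[hit]
  }
  out <- s[state == "index", , drop = FALSE]
  res <- tibble::tibble(
    id = out$id, chrom = out$chrom, pos = out$pos, pvalue = out$pvalue,
    n_members = lengths(members[out$id])
  )
  attr(res, "members") <- members
  res
}
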