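# Allele harmonisation of summary statistics against target (panel or
# weight-model) alleles, and region-wide conditional-normal imputation of
# missing z-scores against reference LD.

#' Harmonise summary statistics to target alleles
#'
#' Aligns each variant's effect allele to the target alt allele, joining on
#' (chrom, pos). Variants already oriented pass through unchanged; swapped
#' orientation negates `beta` and `z`, reflects `eaf` to `1 - eaf`, and
#' relabels alleles; irreconcilable allele pairs are dropped. Strand
#' ambiguous pairs (A/T, C/G) are dropped by default; with
#' `keep_ambiguous = TRUE` they are retained when both the summary and
#' target frequencies are informative (`|eaf - 0.5| > 0.1`) and orientation
#' is resolved by frequency agreement (requires an `eaf` column in
#' `target`). Harmonising twice equals harmonising once.
#'
#' @param stats Summary-statistics tibble.
#' @param target Tibble with columns chrom, pos, ref, alt (e.g.
#'   `panel$variants`), optionally `eaf` (or `maf` interpreted as the alt
#'   frequency) for ambiguous-variant resolution.
#' @param keep_ambiguous Retain strand-ambiguous variants by frequency
#'   orientation instead of dropping them.
#' @return Harmonised tibble with attribute `harmonize_report` (counts of
#'   kept, flipped, dropped).
#' @export
harmonize_sumstats <- function(stats, target, keep_ambiguous = FALSE) {
  stopifnot_cols(stats, c("chrom", "pos", "effect_allele", "other_allele",
                          "beta", "eaf", "z"), "summary statistics")
  stopifnot_cols(target, c("chrom", "pos", "ref", "alt"), "target alleles")
  tgt <- target
  if (!"eaf" %in% names(tgt) && "maf" %in% names(tgt)) tgt$eaf <- tgt$maf
  key <- paste(stats$chrom, stats$pos)
  tkey <- paste(tgt$chrom, tgt$pos)
  idx <- match(key, tkey)
  present <- !is.na(idx)
  alt <- tgt$alt[idx]; ref <- tgt$ref[idx]
  tfreq <- if ("eaf" %in% names(tgt)) tgt$eaf[idx] else rep(NA_real_, length(idx))

  same <- present & stats$effect_allele == alt & stats$other_allele == ref
  swap <- present & stats$effect_allele == ref & stats$other_allele == alt
  ambiguous <- present & is_strand_ambiguous(stats$effect_allele,
                                             stats$other_allele)
  ambiguous[is.na(ambiguous)] <- FALSE

  action <- rep("drop", nrow(stats))
  action[same] <- "keep"
  action[swap] <- "flip"
  if (!keep_ambiguous) {
    action[ambiguous] <- "drop"
  } else {
    amb <- which(ambiguous & (same | swap))
    informative <- abs(stats$eaf[amb] - 0.5) > 0.1 &
      !is.na(tfreq[amb]) & abs(tfreq[amb] - 0.5) > 0.1
    # orientation by frequency agreement: effect allele is the alt allele
    # when both frequencies sit on the same side of 0.5
    freq_match <- (stats$eaf[amb] - 0.5) * (tfreq[amb] - 0.5) > 0
    action[amb] <- ifelse(!informative, "drop",
                          ifelse(freq_match, "keep", "flip"))
  }

  out <- stats
  fl <- action == "flip"
  out$beta[fl] <- -out$beta[fl]
  out$z[fl] <- -out$z[fl]
  out$eaf[fl] <- 1 - out$eaf[fl]
  tmp <- out$effect_allele[fl]
  out$effect_allele[fl] <- out$other_allele[fl]
  out$other_allele[fl] <- tmp
  keep <- action != "drop"
  res <- out[keep, , drop = FALSE]
  attr(res, "harmonize_report") <- tibble::tibble(
    n_kept = sum(action == "keep"), n_flipped = sum(fl),
    n_dropped = sum(!keep), n_unmatched = sum(!present)
  )
  res
}

#' Impute missing summary z-scores region-wide from reference LD
#'
#' For target variants absent from the summary statistics but present in a
#' reference LD block, imputes `z_u = S_uo (S_oo + lambda I)^{-1} z_o`
#' (conditional-normal / Gaussian imputation), attaching the predicted
#' imputation quality `r2_pred = diag(S_uo (S_oo + lambda I)^{-1} S_ou)`.
#' Effect sizes and standard errors for imputed rows are back-filled from
#' the reference frequency and the median sample size of observed rows.
#' Imputed rows carry `imputed = TRUE`.
#'
#' @param stats Harmonised summary statistics.
#' @param ld An `ld_matrix` (see [compute_ld()]) covering the region.
#' @param targets Variant ids to impute; defaults to all LD variants absent
#'   from `stats`.
#' @param lambda Ridge regularisation added to the observed-observed LD
#'   block (default 0.1).
#' @return `stats` with imputed rows appended, plus `imputed` and `r2_pred`
#'   columns.
#' @export
impute_region_z <- function(stats, ld, targets = NULL, lambda = 0.1) {
  if (!"imputed" %in% names(stats)) stats$imputed <- FALSE
  if (!"r2_pred" %in% names(stats)) stats$r2_pred <- NA_real_
  targets <- targets %||% setdiff(ld$ids, stats$id)
  targets <- setdiff(intersect(targets, ld$ids), stats$id)
  if (length(targets) == 0) return(stats)
  obs <- intersect(ld$ids, stats$id)
  if (length(obs) == 0) {
    inform("impute_region_z: no observed variants in region; nothing imputed")
    return(stats)
  }
  oi <- match(obs, ld$ids); ui <- match(targets, ld$ids)
  S_oo <- ld$matrix[oi, oi, drop = FALSE]
  S_uo <- ld$matrix[ui, oi, drop = FALSE]
  A <- solve(S_oo + diag(lambda, length(oi)), t(S_uo))  # (S_oo+lI)^{-1} S_ou
  z_o <- stats$z[match(obs, stats$id)]
  z_u <- drop(crossprod(A, z_o))
  r2 <- colSums(A * t(S_uo))
  n_med <- stats::median(stats$n[match(obs, stats$id)])
  f_u <- ld$eaf[ui]
  se_u <- 1 / sqrt(2 * f_u * (1 - f_u) * n_med)
  new_rows <- tibble::tibble(
    chrom = ld$chrom[ui], pos = ld$pos[ui], id = targets,
    effect_allele = ld$alt[ui], other_allele = ld$ref[ui],
    eaf = f_u, beta = z_u * se_u, se = se_u,
    pvalue = z_to_p(z_u), n = n_med, z = z_u,
    imputed = TRUE, r2_pred = r2
  )
  dplyr::bind_rows(stats, new_rows[names(new_rows) %in% names(stats)])
}
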