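# Reading, writing and QC of GWAS summary statistics.

SUMSTATS_FILE_COLS <- c("CHR", "POS", "ID", "EA", "OA", "EAF", "BETA",
                        "SE", "P", "N")

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file with header columns
#' CHR, POS, ID, EA, OA, EAF, BETA, SE, P, N. Rows whose numeric fields do
#' not parse are dropped and counted (attribute `n_dropped`, plus a
#' message). P-values of 0 or 1 are clamped to the nearest representable
#' open-interval values, with a warning, so downstream normal-quantile
#' arithmetic stays finite. The z-score column is derived as `beta/se`.
#'
#' @param path File path.
#' @return A summary-statistics tibble (chrom, pos, id, effect_allele,
#'   other_allele, eaf, beta, se, pvalue, n, z) with attribute `n_dropped`.
#' @export
read_sumstats <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(SUMSTATS_FILE_COLS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("summary-statistics file %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    chrom = raw$CHR, pos = suppressWarnings(as.integer(raw$POS)),
    id = raw$ID,
    effect_allele = toupper(raw$EA), other_allele = toupper(raw$OA),
    eaf = num(raw$EAF), beta = num(raw$BETA), se = num(raw$SE),
    pvalue = num(raw$P), n = num(raw$N)
  )
  ok <- stats::complete.cases(out[c("pos", "eaf", "beta", "se", "pvalue", "n")]) &
    out$se > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("read_sumstats: dropped %d unparseable row(s)", n_dropped))
  }
  out <- out[ok, , drop = FALSE]
  clamp_lo <- out$pvalue <= 0
  clamp_hi <- out$pvalue >= 1
  if (any(clamp_lo | clamp_hi)) {
    warn(sprintf("read_sumstats: clamped %d boundary P-value(s) into (0, 1)",
                 sum(clamp_lo | clamp_hi)))
    out$pvalue[clamp_lo] <- .Machine$double.xmin
    out$pvalue[clamp_hi] <- 1 - .Machine$double.eps
  }
  out$z <- out$beta / out$se
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_sumstats()]; writes the CHR/POS/ID/EA/OA/EAF/BETA/SE/P/N
#' tab-separated layout.
#'
#' @param stats Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot_cols(stats, c("chrom", "pos", "id", "effect_allele",
                          "other_allele", "eaf", "beta", "se", "pvalue", "n"),
                 "summary statistics")
  out <- tibble::tibble(
    CHR = stats$chrom, POS = stats$pos, ID = stats$id,
    EA = stats$effect_allele, OA = stats$other_allele,
    EAF = stats$eaf, BETA = stats$beta, SE = stats$se,
    P = stats$pvalue, N = stats$n
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter summary statistics on allele frequency and biallelic status
#'
#' Retains common biallelic variants: minor allele frequency strictly above
#' `maf_min` and single-base effect/other alleles. Removal counts by reason
#' are attached as the `qc_report` attribute.
#'
#' @param stats Summary-statistics tibble with an `eaf` column.
#' @param maf_min Strict lower bound on minor allele frequency
#'   (default 0.01).
#' @return Filtered tibble with attribute `qc_report`.
#' @export
#' @examples
#' ss <- tibble::tibble(chrom = "1", pos = 1:4, id = paste0("v", 1:4),
#'   effect_allele = "A", other_allele = "G",
#'   eaf = c(0.5, 0.011, 0.01, 0.995), beta = 0, se = 1,
#'   pvalue = 0.5, n = 1000, z = 0)
#' nrow(qc_filter(ss)) # 2
qc_filter <- function(stats, maf_min = 0.01) {
  stopifnot_cols(stats, c("eaf", "effect_allele", "other_allele"),
                 "summary statistics")
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  rare <- !(maf > maf_min)
  not_snv <- !(stats$effect_allele %in% DNA_BASES &
                 stats$other_allele %in% DNA_BASES &
                 stats$effect_allele != stats$other_allele)
  keep <- !rare & !not_snv
  out <- stats[keep, , drop = FALSE]
  attr(out, "qc_report") <- tibble::tibble(
    reason = c("maf_below_threshold", "not_biallelic_snv"),
    n_removed = c(sum(rare & !not_snv), sum(not_snv))
  )
  out
}
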