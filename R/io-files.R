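# File interchange: VCF genotype panels (DS dosage field), weight-model
# tables, cohort tables.

#' Write a genotype panel as VCF
#'
#' Writes a VCFv4.2 text file with GT (rounded dosage) and DS (dosage)
#' FORMAT fields, one column per sample.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  X <- panel$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- X[, j]
    gt <- ifelse(is.na(ds), "./.", gt_codes[pmin(pmax(round(ds), 0), 2) + 1])
    ds_str <- ifelse(is.na(ds), ".", formatC(ds, format = "g", digits = 6))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT:DS", paste(gt, ds_str, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Reads genotypes via the `vcfR` package. The DS (dosage) FORMAT field is
#' preferred; when absent, GT is converted to an alt-allele count.
#'
#' @param path VCF path (plain or gzipped).
#' @return A `genotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_panel_vcf() requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  variants <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt_keys) {
    D <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    G <- vcfR::extract.gt(vcf, element = "GT")
    D <- apply(G, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  samples <- colnames(D)
  new_genotype_panel(samples, variants, t(D))
}

#' Read / write eQTL weight-model tables
#'
#' Tab-separated tables with columns tissue, gene, variant_id,
#' effect_allele, other_allele, weight (PredictDB-style, flattened across
#' tissues).
#'
#' @param path File path.
#' @return `read_weight_models()` returns the weights tibble;
#'   `write_weight_models()` returns `path` invisibly.
#' @export
read_weight_models <- function(path) {
  w <- readr::read_tsv(path, col_types = readr::cols(
    tissue = readr::col_character(), gene = readr::col_character(),
    variant_id = readr::col_character(),
    effect_allele = readr::col_character(),
    other_allele = readr::col_character(),
    weight = readr::col_double()), progress = FALSE)
  bad <- !is.finite(w$weight) | w$weight == 0
  if (any(bad)) {
    inform(sprintf("read_weight_models: dropped %d zero/non-finite weight(s)",
                   sum(bad)))
    w <- w[!bad, , drop = FALSE]
  }
  dup <- duplicated(w[c("tissue", "gene", "variant_id")])
  if (any(dup)) {
    warn(sprintf("read_weight_models: removed %d duplicate (gene, variant) pair(s)",
                 sum(dup)))
    w <- w[!dup, , drop = FALSE]
  }
  w
}

#' @rdname read_weight_models
#' @param weights Weights tibble.
#' @export
write_weight_models <- function(weights, path) {
  stopifnot_cols(weights, c("tissue", "gene", "variant_id", "effect_allele",
                            "other_allele", "weight"), "weight model")
  readr::write_tsv(weights, path, progress = FALSE)
  invisible(path)
}

#' Read / write a cohort table
#'
#' Tab-separated cohort table: sample_id, case, age, sex, pc1..pc10,
#' eosinophils, lymphocytes, split.
#'
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    split = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}
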