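# Score vectors: per-individual risk scores with provenance, plus
# standardisation with a declared reference set.

new_score_vector <- function(sample_id, raw, score_type, threshold = NA_real_,
                             n_features = NA_integer_, tissue = NA_character_) {
  out <- tibble::tibble(sample_id = sample_id, raw = raw)
  attr(out, "score_type") <- score_type
  attr(out, "threshold") <- threshold
  attr(out, "n_features") <- as.integer(n_features)
  attr(out, "tissue") <- tissue
  class(out) <- c("score_vector", class(out))
  out
}

#' Score metadata accessors
#'
#' @param score A score vector (from [score_prs()], [compute_ptrs()],
#'   [standardize_score()], ...).
#' @return `score_info()` returns a one-row tibble with the score's type,
#'   P-value threshold, feature count and tissue.
#' @export
score_info <- function(score) {
  tibble::tibble(
    score_type = attr(score, "score_type") %||% NA_character_,
    threshold = attr(score, "threshold") %||% NA_real_,
    n_features = attr(score, "n_features") %||% NA_integer_,
    tissue = attr(score, "tissue") %||% NA_character_
  )
}

#' @export
print.score_vector <- function(x, ...) {
  info <- score_info(x)
  cat(sprintf("<score_vector> %s%s, %d individuals, %s features, threshold %s\n",
              info$score_type,
              if (!is.na(info$tissue)) paste0(" [", info$tissue, "]") else "",
              nrow(x),
              ifelse(is.na(info$n_features), "?", info$n_features),
              format(info$threshold)))
  NextMethod()
}

#' Standardise a score on a reference set
#'
#' Centres and scales the raw score using the mean and population (ddof 0)
#' standard deviation computed on the declared reference set, then applies
#' that transform to every individual. Anchoring the reference on the
#' training samples and transporting the same `(mu, sigma)` to the test set
#' avoids test-set leakage.
#'
#' @param score A score vector.
#' @param reference Either a character vector of `sample_id`s defining the
#'   reference set (default: all samples), or a numeric `c(mu, sigma)`.
#' @return The score vector with a `standardized` column and attributes
#'   `center`/`scale`.
#' @export
#' @examples
#' s <- new_score_vector(c("a", "b", "c"), c(1, 2, 3), "PRS")
#' standardize_score(s)$standardized
standardize_score <- function(score, reference = NULL) {
  if (is.numeric(reference) && length(reference) == 2) {
    mu <- reference[1]; sigma <- reference[2]
  } else {
    ids <- reference %||% score$sample_id
    x <- score$raw[score$sample_id %in% ids]
    if (length(x) == 0) abort("standardize_score: empty reference set")
    mu <- mean(x); sigma <- pop_sd(x)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    abort("standardize_score: degenerate score (zero variance on reference)")
  }
  score$standardized <- (score$raw - mu) / sigma
  attr(score, "center") <- mu
  attr(score, "scale") <- sigma
  score
}
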