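# internal helpers shared across modules

# population (ddof = 0) standard deviation
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# column-wise mean imputation of a dosage matrix
mean_impute <- function(X) {
  miss <- is.na(X)
  if (!any(miss)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  X[miss] <- mu[idx[, 2]]
  X
}

# two-sided normal p-value from a z-score, clamped away from 0
z_to_p <- function(z) {
  p <- 2 * pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

# deterministic integer sub-seed; keeps everything below 2^31
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_strand_ambiguous <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
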