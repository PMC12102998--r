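# LD-structured genotype simulation via a calibrated Gaussian copula.
#
# Dosages are drawn by mapping a latent AR(1) Gaussian chain through the
# binomial(2, f) quantile function, which keeps Hardy-Weinberg marginals.
# Discretisation attenuates correlation, so the latent correlation of each
# adjacent pair is calibrated (Hermite-series expansion of the quantile step
# function, solved by root finding) so that the *genotype* correlation hits
# the configured target.

# Hermite coefficients of g(z) = qbinom(pnorm(z), 2, f), a two-step function
# with jumps at the HWE genotype-class quantiles.
hermite_coefs <- function(f, K = 60L) {
  t1 <- qnorm((1 - f)^2)
  t2 <- qnorm(1 - f^2)
  he <- function(k, x) { # probabilists' Hermite He_k(x)
    if (k == 0) return(1)
    if (k == 1) return(x)
    a <- 1; b <- x
    for (j in 2:k) { cc <- x * b - (j - 1) * a; a <- b; b <- cc }
    b
  }
  lf <- lfactorial(seq_len(K))
  vapply(seq_len(K), function(k) {
    (dnorm(t1) * he(k - 1, t1) + dnorm(t2) * he(k - 1, t2)) * exp(-lf[k] / 2)
  }, numeric(1))
}

# theoretical dosage correlation of two copula-mapped variants at latent r
copula_dosage_cor <- function(r, f1, f2, K = 60L) {
  a <- hermite_coefs(f1, K)
  b <- hermite_coefs(f2, K)
  sum(a * b * r^seq_len(K)) / sqrt(4 * f1 * (1 - f1) * f2 * (1 - f2))
}

# latent correlation achieving a target dosage correlation (capped near 1
# when the marginals make the target unattainable); `ca`/`cb` are cached
# Hermite coefficient vectors for the two marginals
calibrate_latent_cor <- function(target, f1, f2, ca = NULL, cb = NULL) {
  if (target <= 0) return(0)
  ca <- ca %||% hermite_coefs(f1)
  cb <- cb %||% hermite_coefs(f2)
  denom <- sqrt(4 * f1 * (1 - f1) * f2 * (1 - f2))
  g <- function(r) sum(ca * cb * r^seq_along(ca)) / denom
  slope <- ca[1] * cb[1] / denom
  if (target < 0.02) return(min(target / slope, 0.99999)) # linear regime
  upper <- 0.99999
  if (g(upper) <= target) return(upper)
  uniroot(function(r) g(r) - target, c(0, upper), tol = 1e-8)$root
}

# per-block latent correlation matrix whose copula-mapped dosages follow
# rho^|i-j| (Cholesky factor returned); eigenvalue-clipped to PSD
block_latent_chol <- function(maf, rho) {
  m <- length(maf)
  if (m == 1 || rho == 0) return(diag(m))
  coefs <- lapply(maf, hermite_coefs)
  S <- diag(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      s <- calibrate_latent_cor(rho^(j - i), maf[i], maf[j],
                                coefs[[i]], coefs[[j]])
      S[i, j] <- S[j, i] <- s
    }
  }
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(S, symmetric = TRUE)
    S <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
    S <- stats::cov2cor(S)
    ch <- chol(S)
  }
  ch
}

# Deterministic variant metadata shared by the reference panel and the
# cohort: positions, block labels, allele pair, per-variant MAF (drawn
# around a per-block anchor, as variants in strong LD have similar
# frequencies), and the calibrated latent AR chain.
make_variant_map <- function(config) {
  withr::local_seed(sub_seed(config$seed, 1L))
  nb <- config$n_blocks; bs <- config$block_size
  m <- nb * bs
  block <- rep(seq_len(nb), each = bs)
  within <- rep(seq_len(bs), times = nb)
  # 5 kb spacing within a block, 2 Mb between block starts: a 250 kb
  # clumping window spans most of a block and never crosses blocks
  pos <- (block - 1L) * 2000000L + within * 5000L
  lo <- config$maf_range[1]; hi <- config$maf_range[2]
  jit <- min(0.02, (hi - lo) / 4)
  anchor <- runif(nb, lo + jit, hi - jit)
  maf <- pmin(hi, pmax(lo, rep(anchor, each = bs) + runif(m, -jit, jit)))
  ref <- sample(DNA_BASES, m, replace = TRUE)
  # alt differs from ref and is never its complement (no strand-ambiguous
  # variants in the generated data; ambiguity handling is exercised in
  # harmonisation on explicit inputs)
  alt <- vapply(ref, function(r) {
    sample(setdiff(DNA_BASES, c(r, COMPLEMENT[[r]])), 1)
  }, character(1))
  out <- tibble::tibble(
    chrom = "1", pos = pos,
    id = sprintf("var%04d", seq_len(m)),
    ref = ref, alt = unname(alt),
    maf = maf, block = block
  )
  attr(out, "latent_chol") <- lapply(seq_len(nb), function(b) {
    block_latent_chol(maf[block == b], config$ld_rho)
  })
  out
}

# draw an n x m dosage matrix following a variant map
draw_dosages <- function(vmap, n) {
  m <- nrow(vmap)
  chols <- attr(vmap, "latent_chol")
  X <- matrix(0, n, m)
  for (b in unique(vmap$block)) {
    idx <- which(vmap$block == b)
    Z <- matrix(rnorm(n * length(idx)), n) %*% chols[[b]]
    for (k in seq_along(idx)) {
      j <- idx[k]
      f <- vmap$maf[j]
      # binomial(2, f) quantile map via its two HWE cell boundaries,
      # expressed directly on the latent Gaussian scale
      X[, j] <- (Z[, k] > qnorm((1 - f)^2)) + (Z[, k] > qnorm(1 - f^2))
    }
  }
  colnames(X) <- vmap$id
  X
}

new_genotype_panel <- function(samples, variants, dosages) {
  stopifnot(nrow(dosages) == length(samples),
            ncol(dosages) == nrow(variants))
  rownames(dosages) <- samples
  structure(list(samples = samples, variants = variants, dosages = dosages),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Simulate an LD reference panel
#'
#' Draws a panel of unrelated individuals with block-structured linkage
#' disequilibrium. Genotype dosages (alt-allele counts in `{0, 1, 2}`) come
#' from a latent AR(1) Gaussian copula whose parameter is calibrated per
#' adjacent pair so the realised genotype correlation approximates
#' `config$ld_rho`; marginals respect Hardy-Weinberg at the drawn allele
#' frequencies. Blocks are mutually independent.
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel`: list with `samples`, `variants`
#'   (tibble: chrom, pos, id, ref, alt, maf, block), and an
#'   `n x m` `dosages` matrix.
#' @export
#' @examples
#' panel <- simulate_reference_panel(
#'   sim_config(n_ref = 100, n_blocks = 2, block_size = 5, seed = 1))
#' dim(panel$dosages)
simulate_reference_panel <- function(config) {
  validate_sim_config(config)
  vmap <- make_variant_map(config)
  withr::local_seed(sub_seed(config$seed, 2L))
  X <- draw_dosages(vmap, config$n_ref)
  new_genotype_panel(sprintf("ref%05d", seq_len(config$n_ref)), vmap, X)
}
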