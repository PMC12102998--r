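# Target cohort generation under a liability-threshold model with both
# expression-mediated and direct variant effects, demographic covariates,
# genotype-derived principal components, and blood cell counts linked to
# liability (eosinophils up in cases, lymphocytes down) with MCAR
# missingness.

#' Simulate the target cohort
#'
#' Draws cohort genotypes from the same variant map as the reference panel,
#' builds latent liability as the sum of an expression-mediated component
#' (causal-tissue GReX times gene effects, scaled to `h2_mediated`), a
#' direct-variant component (scaled to `h2_direct`), an optional planted
#' interaction between the standardised mediated component and the
#' lymphocyte latent driver, small age/sex effects, and Gaussian noise.
#' Case status is liability above the threshold implied by
#' `config$prevalence`. Blood counts are log-normal transforms of latent
#' drivers correlated with liability at the configured signed strengths;
#' both counts are set missing together, completely at random, at
#' `config$missing_rate`. Principal components are the top 10 singular
#' directions of the centred dosage matrix (iid normals for tiny cohorts).
#' The cohort is split into train/test by [stratified_split()].
#'
#' @param config A [sim_config()].
#' @param models Output of [simulate_eqtl_models()].
#' @param truth Optional partially filled ground-truth list; normally the
#'   `models` list itself is all that is needed.
#' @return A list with `panel` (cohort `genotype_panel`), `cohort`
#'   (tibble: sample_id, case, age, sex, pc1..pc10, eosinophils,
#'   lymphocytes, split), and `truth` (gene/variant effects, liability and
#'   its components, threshold, weights).
#' @export
simulate_cohort <- function(config, models, truth = NULL) {
  validate_sim_config(config)
  vmap <- make_variant_map(config)
  withr::local_seed(sub_seed(config$seed, 4L))
  n <- config$n_cohort
  X <- draw_dosages(vmap, n)
  samples <- sprintf("id%06d", seq_len(n))

  causal_tissue <- sprintf("tissue%02d", config$causal_tissue)
  wt <- dplyr::filter(models$weights, .data$tissue == causal_tissue)
  tissue_genes <- unique(wt$gene)
  n_causal_genes <- max(0L, round(config$causal_gene_fraction * length(tissue_genes)))

  # mediated component: alpha on a random subset of the causal tissue's genes
  mediated <- numeric(n)
  gene_effects <- tibble::tibble(gene = character(0), effect = numeric(0))
  if (config$h2_mediated > 0 && n_causal_genes > 0) {
    causal_genes <- sample(tissue_genes, n_causal_genes)
    Wm <- weight_matrix(wt[wt$gene %in% causal_genes, ], vmap)
    Tg <- X[, rownames(Wm), drop = FALSE] %*% Wm
    alpha <- rnorm(ncol(Tg))
    raw <- drop(Tg %*% alpha)
    s <- pop_sd(raw)
    scale_f <- if (s > 0) sqrt(config$h2_mediated) / s else 0
    mediated <- (raw - mean(raw)) * scale_f
    gene_effects <- tibble::tibble(gene = colnames(Tg), effect = alpha * scale_f)
  }

  # direct component: gamma on a random subset of variants
  direct <- numeric(n)
  variant_effects <- tibble::tibble(id = vmap$id, effect = 0)
  if (config$h2_direct > 0) {
    n_causal_var <- max(1L, round(config$causal_variant_fraction * nrow(vmap)))
    idx <- sort(sample(nrow(vmap), n_causal_var))
    gamma <- rnorm(n_causal_var)
    raw <- drop(X[, idx, drop = FALSE] %*% gamma)
    s <- pop_sd(raw)
    scale_f <- if (s > 0) sqrt(config$h2_direct) / s else 0
    direct <- (raw - mean(raw)) * scale_f
    variant_effects$effect[idx] <- gamma * scale_f
  }

  # latent drivers of the blood counts; L0 also feeds the planted interaction
  E0 <- rnorm(n)
  L0 <- rnorm(n)
  delta <- config$interaction_strength
  interaction <- if (delta != 0 && pop_sd(mediated) > 0) {
    delta * (mediated / pop_sd(mediated)) * L0
  } else numeric(n)

  age <- rnorm(n, 57, 8)
  sex <- rbinom(n, 1L, 0.46)
  age_eff <- -0.10; sex_eff <- 0.05
  demog <- age_eff * (age - 57) / 8 + sex_eff * (sex - 0.46)

  eps_sd <- sqrt(max(0, 1 - config$h2_mediated - config$h2_direct))
  liability <- mediated + direct + interaction + demog + rnorm(n, sd = eps_sd)
  # empirical quantile: robust to the mild non-normality of the genetic
  # components, so the realised case fraction tracks the target prevalence
  threshold <- unname(quantile(liability, 1 - config$prevalence))
  case <- as.integer(liability > threshold)

  # blood counts: latent = b * std liability + sqrt(1-b^2) * intrinsic driver
  liab_std <- (liability - mean(liability)) / pop_sd(liability)
  b_e <- config$blood_count_effects[["eosinophils"]]
  b_l <- config$blood_count_effects[["lymphocytes"]]
  eos_lat <- b_e * liab_std + sqrt(1 - b_e^2) * E0
  lymph_lat <- b_l * liab_std + sqrt(1 - b_l^2) * L0
  eosinophils <- exp(log(0.16) + 0.6 * eos_lat)
  lymphocytes <- exp(log(1.9) + 0.35 * lymph_lat)
  miss <- runif(n) < config$missing_rate
  eosinophils[miss] <- NA_real_
  lymphocytes[miss] <- NA_real_

  pcs <- cohort_pcs(X)

  cohort <- tibble::tibble(sample_id = samples, case = case,
                           age = age, sex = sex)
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(pcs))
  cohort$eosinophils <- eosinophils
  cohort$lymphocytes <- lymphocytes
  cohort <- stratified_split(cohort, config$train_fraction,
                             seed = sub_seed(config$seed, 5L))

  truth <- list(
    gene_effects = gene_effects,
    variant_effects = variant_effects,
    weights = models$weights,
    liability = liability,
    components = list(mediated = mediated, direct = direct,
                      interaction = interaction),
    threshold = threshold,
    lymph_driver = L0,
    variant_map = vmap
  )
  list(panel = new_genotype_panel(samples, vmap, X),
       cohort = cohort, truth = truth)
}

# dense gene weight matrix (variants x genes) from a weight table, oriented
# to the alt allele of the variant map
weight_matrix <- function(wt, vmap) {
  genes <- unique(wt$gene)
  ids <- unique(wt$variant_id)
  W <- matrix(0, length(ids), length(genes), dimnames = list(ids, genes))
  flip <- wt$effect_allele != vmap$alt[match(wt$variant_id, vmap$id)]
  w <- ifelse(flip, -wt$weight, wt$weight)
  W[cbind(match(wt$variant_id, ids), match(wt$gene, genes))] <- w
  W
}

# top-10 principal components of the centred dosage matrix, standardised;
# iid normal fallback for cohorts too small to support them
cohort_pcs <- function(X, k = 10L) {
  n <- nrow(X); m <- ncol(X)
  pcs <- if (n >= 50 && m >= k) {
    Xc <- sweep(X, 2, colMeans(X))
    ev <- eigen(crossprod(Xc), symmetric = TRUE)
    scores <- Xc %*% ev$vectors[, seq_len(k), drop = FALSE]
    apply(scores, 2, function(v) {
      s <- pop_sd(v); if (s > 0) (v - mean(v)) / s else rnorm(n)
    })
  } else {
    matrix(rnorm(n * k), n, k)
  }
  colnames(pcs) <- paste0("pc", seq_len(k))
  pcs
}
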