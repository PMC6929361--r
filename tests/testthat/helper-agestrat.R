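# Shared fixture builders: small, fast simulation configurations.

# Compact configuration for unit tests; overrides are merged into the
# defaults of each sub-model.
small_config <- function(n_genes = 500L, seed = 1L,
                         attribute_models = NULL,
                         peptide = list(), go = list(), homolog = list(),
                         ptm = list()) {
  if (is.null(attribute_models)) {
    attribute_models <- list(
      turnover = attribute_model(2.6, -0.113, c(0.35, 0.45, 0.55, 0.70, 0.90),
                                 constraint = "positive"))
  }
  homolog_model <- utils::modifyList(
    list(n_pairs = 300L, species_factor = 0.91, ratio_noise_sd = 0.15,
         disease_base_rate = 0.05, disease_extreme_rate = 0.6,
         extreme_quantile = 0.05), homolog)
  homolog_model$n_pairs <- min(homolog_model$n_pairs, n_genes)
  go_model <- utils::modifyList(
    list(n_categories = 5L, category_size_range = c(20L, 60L),
         planted_shift_by_category = 0), go)
  go_model$category_size_range <- pmin(go_model$category_size_range,
                                       max(2L, n_genes %/% 2L))
  simulation_config(
    n_genes = n_genes,
    attribute_models = attribute_models,
    peptide_model = utils::modifyList(
      list(min_peptides = 3L, max_peptides = 30L,
           cv_intercept = 0.02, cv_slope = 0.04), peptide),
    go_model = go_model,
    homolog_model = homolog_model,
    ptm_model = utils::modifyList(
      list(p_meth_by_group = c(0.030, 0.024, 0.018, 0.014, 0.010),
           p_acet_by_group = c(0.24, 0.18, 0.14, 0.10, 0.08),
           p_phos_by_group = c(0.12, 0.18, 0.24, 0.30, 0.36)), ptm),
    seed = seed)
}

# Noise-free configuration: exact linear age model for turnover.
noiseless_config <- function(n_genes = 200L, baseline = 2.5,
                             age_slope = -0.1, seed = 1L) {
  small_config(
    n_genes = n_genes, seed = seed,
    attribute_models = list(
      turnover = attribute_model(baseline, age_slope, rep(0, 5),
                                 constraint = "positive")))
}

# Independent Mann-Whitney oracle: U by explicit pair counting and p by
# exhaustive enumeration over all group assignments.
oracle_mann_whitney <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  mu <- n1 * n2 / 2
  u_obs <- u_of(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) u_of(comb[i], comb[-i]))
  list(statistic = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12))
}

# Independent Spearman oracle: average ranks computed from first principles,
# then the explicit Pearson product-moment formula.
oracle_spearman_r <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

turnover_map <- function(genes) stats::setNames(genes$turnover, genes$gene_id)
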