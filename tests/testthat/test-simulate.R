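test_that("noise-free configuration reproduces the linear age model exactly", {
  cfg <- noiseless_config(baseline = 2.5, age_slope = -0.1)
  g <- generate_gene_table(cfg)
  expect_equal(g$turnover, 2.5 - 0.1 * g$age_rank, tolerance = 1e-12)
  expect_true(all(g$turnover[g$age_group == "u_org"] == 2.0))
})

test_that("generation is deterministic given the seed and varies across seeds", {
  cfg1 <- small_config(seed = 11)
  cfg2 <- small_config(seed = 12)
  g1a <- generate_gene_table(cfg1)
  g1b <- generate_gene_table(cfg1)
  g2 <- generate_gene_table(cfg2)
  expect_identical(g1a, g1b)
  expect_false(identical(g1a$turnover, g2$turnover))
  expect_identical(generate_peptides(g1a, cfg1), generate_peptides(g1a, cfg1))
  expect_identical(generate_go_annotations(g1a, cfg1),
                   generate_go_annotations(g1a, cfg1))
  expect_identical(generate_homolog_pairs(g1a, cfg1),
                   generate_homolog_pairs(g1a, cfg1))
  expect_identical(generate_ptm_labels(g1a, cfg1),
                   generate_ptm_labels(g1a, cfg1))
})

test_that("group counts fall within binomial 99% bounds of expectation", {
  props <- c(0.24, 0.45, 0.19, 0.10, 0.02)
  cfg <- simulation_config(n_genes = 10000L, group_proportions = props,
                           homolog_model = utils::modifyList(
                             simulation_config()$homolog_model,
                             list(n_pairs = 2000L)),
                           seed = 5)
  g <- generate_gene_table(cfg)
  counts <- table(factor(g$age_group,
                         levels = c("u_org", "u_euk", "OBD", "chor", "mamm")))
  lo <- qbinom(0.005, 10000, props)
  hi <- qbinom(0.995, 10000, props)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("invalid proportions are a configuration error", {
  expect_error(simulation_config(group_proportions = c(0.5, 0.2, 0.1, 0.1, 0.05)),
               "group_proportions")
})

test_that("generated stability and abundance values are strictly positive", {
  for (s in 1:5) {
    cfg <- simulation_config(n_genes = 800L,
                             homolog_model = utils::modifyList(
                               simulation_config()$homolog_model,
                               list(n_pairs = 500L)),
                             seed = s)
    g <- generate_gene_table(cfg)
    expect_true(all(g$turnover > 0))
    expect_true(all(g$mrna_half_life > 0))
    expect_true(all(g$abundance > 0))
    pep <- generate_peptides(g[1:50, ], cfg)
    expect_true(all(pep$peptide_ratio > 0))
  }
})

test_that("a negative planted slope yields a negative sample age correlation", {
  neg <- 0L
  for (s in 1:20) {
    g <- generate_gene_table(small_config(n_genes = 2000L, seed = 100 + s))
    r <- spearman_age_correlation(g$age_rank, g$turnover)$r
    neg <- neg + (r < 0)
  }
  expect_gte(neg, 19L)
})

test_that("zero-noise peptides equal their protein turnover", {
  cfg <- small_config(n_genes = 50L,
                      peptide = list(cv_intercept = 0, cv_slope = 0))
  g <- generate_gene_table(cfg)
  pep <- generate_peptides(g, cfg)
  expect_equal(pep$peptide_ratio,
               stats::setNames(g$turnover, g$gene_id)[pep$protein_id],
               ignore_attr = TRUE)
  ps <- protein_peptide_stats(pep)
  expect_true(all(ps$variance == 0))
})

test_that("fixed peptide count gives every protein exactly that many peptides", {
  cfg <- small_config(n_genes = 40L,
                      peptide = list(min_peptides = 15L, max_peptides = 15L))
  g <- generate_gene_table(cfg)
  pep <- generate_peptides(g, cfg)
  expect_true(all(table(pep$protein_id) == 15))
})

test_that("planted GO shifts order the recovered category means", {
  cfg <- small_config(n_genes = 2000L, seed = 42,
                      go = list(n_categories = 3L,
                                category_size_range = c(150L, 150L),
                                planted_shift_by_category = c(-0.4, 0, 0.4)))
  g <- generate_gene_table(cfg)
  go <- generate_go_annotations(g, cfg)
  tm <- turnover_map(g)
  means <- vapply(split(go$gene_id, go$category_id),
                  function(ids) mean(tm[ids]), numeric(1))
  expect_true(means[["GO:0000001"]] < means[["GO:0000002"]])
  expect_true(means[["GO:0000002"]] < means[["GO:0000003"]])
})

test_that("oversized categories are a configuration error", {
  cfg <- small_config(n_genes = 100L, go = list(category_size_range = c(20L, 90L)))
  g <- generate_gene_table(cfg)
  cfg$go_model$category_size_range <- c(20L, 200L)
  expect_error(generate_go_annotations(g, cfg), "configuration error")
})

test_that("deterministic species scaling gives exact ratios and fractions", {
  cfg0 <- small_config(n_genes = 300L,
                       homolog = list(n_pairs = 200L, species_factor = 1,
                                      ratio_noise_sd = 0))
  g <- generate_gene_table(cfg0)
  hom <- generate_homolog_pairs(g, cfg0)
  expect_true(all(hom$ratio == 1))
  expect_equal(pair_turnover_comparison(hom)$fraction_human_higher, 0)
  expect_equal(pair_turnover_comparison(hom)$fraction_ties, 1)

  cfg1 <- small_config(n_genes = 300L,
                       homolog = list(n_pairs = 200L, species_factor = 0.91,
                                      ratio_noise_sd = 0))
  hom1 <- generate_homolog_pairs(g, cfg1)
  expect_equal(hom1$ratio, rep(1 / 0.91, 200), tolerance = 1e-12)
  expect_equal(pair_turnover_comparison(hom1)$fraction_human_higher, 1)
})

test_that("disease counts concentrate in extreme ratio bins", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- small_config(n_genes = 1500L, seed = 300 + s,
                        homolog = list(n_pairs = 1200L,
                                       disease_base_rate = 0.05,
                                       disease_extreme_rate = 0.6,
                                       extreme_quantile = 0.05))
    g <- generate_gene_table(cfg)
    hom <- generate_homolog_pairs(g, cfg)
    db <- disease_ratio_bins(hom, 30L)
    full <- db[!db$partial, ]
    interior <- full$disease_sum[4:(nrow(full) - 3)]
    hits <- hits + (full$disease_sum[1] > stats::median(interior) &&
                      full$disease_sum[nrow(full)] > stats::median(interior))
  }
  expect_gte(hits, 4L)
})

test_that("PTM label draws respect degenerate probabilities", {
  cfg <- small_config(n_genes = 200L,
                      ptm = list(p_meth_by_group = rep(0, 5),
                                 p_acet_by_group = rep(0, 5),
                                 p_phos_by_group = rep(0, 5)))
  g <- generate_gene_table(cfg)
  ptm <- generate_ptm_labels(g, cfg)
  expect_identical(lengths(ptm), c(methylated = 0L, acetylated = 0L,
                                   phosphorylated = 0L))

  cfg2 <- small_config(n_genes = 200L,
                       ptm = list(p_meth_by_group = c(1, 0, 0, 0, 0),
                                  p_acet_by_group = rep(0, 5),
                                  p_phos_by_group = rep(0, 5)))
  ptm2 <- generate_ptm_labels(g, cfg2)
  expect_setequal(ptm2$methylated, g$gene_id[g$age_group == "u_org"])
  asg <- exclusive_ptm_assignment(ptm2$methylated, ptm2$acetylated,
                                  ptm2$phosphorylated, g$gene_id)
  expect_equal(sum(asg$ptm_class == "methylated"),
               sum(g$age_group == "u_org"))
})
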