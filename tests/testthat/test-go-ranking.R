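test_that("category statistics use only members with turnover values", {
  tm <- c(g1 = 1.8, g2 = 2.0, g3 = 2.2)
  expect_equal(category_stat(c("g1", "g2", "g3"), tm), list(stat = 2.0, n = 3L))
  expect_equal(category_stat(c("g1", "g2", "g3"), tm, "median")$stat, 2.0)
  expect_equal(category_stat(c("g1", "g2", "g3", "g9"), tm)$n, 3L)
  expect_equal(category_stat("g9", tm)$n, 0L)
})

test_that("bootstrap null moments match the closed-form standard error", {
  set.seed(7)
  pool <- rnorm(1e4)
  null <- bootstrap_null(pool, 100L, n_iter = 1000L, seed = 5)
  expect_lt(abs(null$boot_mean - mean(pool)), 0.02)
  expect_lt(abs(null$boot_sd - 0.1) / 0.1, 0.15)   # sigma / sqrt(n)
  expect_identical(null, bootstrap_null(pool, 100L, n_iter = 1000L, seed = 5))
  expect_error(bootstrap_null(rep(2.0, 100), 10L, seed = 1), "degenerate")
})

test_that("significance converts z to two-sided normal p with strict star thresholds", {
  s0 <- category_significance(2.0, 2.0, 0.1)
  expect_equal(s0$z, 0)
  expect_equal(s0$p, 1)
  expect_equal(s0$stars, "")

  zc <- stats::qnorm(0.975)
  sb <- category_significance(2.0 + zc * 0.1, 2.0, 0.1)
  expect_equal(sb$p, 0.05, tolerance = 1e-12)
  expect_equal(sb$stars, "")     # strict "<": the boundary is not starred
  expect_equal(category_significance(2.0, 1.0, 0.4)$stars, "*")
  expect_equal(category_significance(4.0, 1.0, 0.9)$stars, "***")
  expect_error(category_significance(1, 1, 0), "positive")
})

test_that("z is antisymmetric under reflection of the pool about its mean", {
  set.seed(9)
  pool <- rnorm(2000, 2, 0.5)
  cat_vals <- sample(pool, 80)
  null_a <- bootstrap_null(pool, 80L, seed = 11)
  za <- category_significance(mean(cat_vals), null_a$boot_mean,
                              null_a$boot_sd)$z
  refl <- 2 * mean(pool) - pool
  null_b <- bootstrap_null(refl, 80L, seed = 11)
  zb <- category_significance(mean(2 * mean(pool) - cat_vals),
                              null_b$boot_mean, null_b$boot_sd)$z
  expect_equal(za, -zb, tolerance = 1e-10)
})

test_that("planted shifts are recovered in the ranking order", {
  cfg <- small_config(n_genes = 2500L, seed = 23,
                      go = list(n_categories = 3L,
                                category_size_range = c(200L, 200L),
                                planted_shift_by_category = c(0.4, -0.4, 0)))
  g <- generate_gene_table(cfg)
  go <- generate_go_annotations(g, cfg)
  ranked <- rank_categories(go, turnover_map(g), n_iter = 300L,
                            min_size = 50L, seed = 2)
  expect_equal(ranked$category_id,
               c("GO:0000002", "GO:0000003", "GO:0000001"))
  expect_equal(ranked$stars[1], "***")
  expect_equal(ranked$stars[3], "***")
})

test_that("ranking does not depend on category order in the input", {
  cfg <- small_config(n_genes = 1200L, seed = 29,
                      go = list(n_categories = 4L,
                                category_size_range = c(60L, 120L)))
  g <- generate_gene_table(cfg)
  go <- generate_go_annotations(g, cfg)
  shuffled <- go[rev(seq_len(nrow(go))), ]
  a <- rank_categories(go, turnover_map(g), n_iter = 200L, min_size = 20L,
                       seed = 3)
  b <- rank_categories(shuffled, turnover_map(g), n_iter = 200L,
                       min_size = 20L, seed = 3)
  expect_equal(a, b)
})

test_that("a single usable category is trivially rank 1", {
  tm <- stats::setNames(rexp(200) + 0.5, sprintf("g%03d", 1:200))
  go <- data.frame(category_id = "GO:0000001", name = "only",
                   gene_id = names(tm)[1:60], stringsAsFactors = FALSE)
  ranked <- rank_categories(go, tm, n_iter = 200L, min_size = 10L, seed = 1)
  expect_equal(nrow(ranked), 1L)
})

test_that("cross-species rank correlation handles identity, reversal and disjoint sets", {
  a <- data.frame(category_id = sprintf("GO:%07d", 1:10),
                  stat = seq(1, 2, length.out = 10))
  expect_equal(cross_species_rank_correlation(a, a)$r, 1)
  rev_a <- a[rev(seq_len(nrow(a))), ]
  expect_equal(cross_species_rank_correlation(a, rev_a)$r, -1)
  b <- data.frame(category_id = sprintf("GO:%07d", 11:20), stat = 1:10)
  expect_error(cross_species_rank_correlation(a, b), "shared")
})
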