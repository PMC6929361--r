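test_that("Spearman correlation handles perfect monotone association", {
  res <- spearman_rank_correlation(1:5, c(10, 8, 6, 4, 2))
  expect_equal(res$r, -1)
  expect_equal(res$p, 0)
  expect_equal(res$n, 5L)
})

test_that("Spearman matches an independent rank-then-Pearson oracle under ties", {
  set.seed(17)
  checked <- 0L
  while (checked < 50L) {
    n <- sample(4:50, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x * runif(1, -1, 1) + rnorm(n)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(spearman_rank_correlation(x, y)$r, oracle_spearman_r(x, y),
                 tolerance = 1e-10)
    checked <- checked + 1L
  }
})

test_that("Spearman errors on degenerate input", {
  expect_error(spearman_rank_correlation(1:2, 2:1), "at least 3")
  expect_error(spearman_rank_correlation(c(1, 1, 1), 1:3), "zero variance")
})

test_that("Spearman null distribution is centred with rare large estimates", {
  rs <- numeric(100)
  set.seed(99)
  for (i in 1:100) {
    rs[i] <- spearman_rank_correlation(rnorm(1000), rnorm(1000))$r
  }
  expect_lt(abs(mean(rs)), 0.02)
  expect_lte(sum(abs(rs) > 0.1), 2L)
})

test_that("exact permutation p agrees with the permutation definition", {
  # perfect monotone n = 5: only identity and reversal reach |r| = 1
  res <- spearman_rank_correlation(1:5, c(3, 5, 8, 9, 12), exact = TRUE)
  expect_equal(res$p, 2 / factorial(5))
  expect_error(spearman_rank_correlation(1:11, rnorm(11), exact = TRUE),
               "n <= 10")
})

test_that("Mann-Whitney exact enumeration handles ties and extremes", {
  res_tie <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_tie$statistic, 4.5)
  expect_equal(res_tie$p, 1.0)
  expect_equal(res_tie$method, "exact enumeration")

  res_ext <- mann_whitney_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res_ext$statistic, 0)
  expect_equal(res_ext$p, 0.1)   # 2 of the 20 arrangements are as extreme

  expect_error(mann_whitney_test(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney agrees with the pair-counting enumeration oracle", {
  set.seed(5)
  for (i in 1:40) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    got <- mann_whitney_test(x, y)
    want <- oracle_mann_whitney(x, y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(8)
  x <- rnorm(100); y <- rnorm(120, 0.5)
  got <- mann_whitney_test(x, y)
  expect_equal(got$method, "normal approximation")
  expect_equal(got$p, stats::wilcox.test(x, y, exact = FALSE)$p.value)
})

test_that("ANOVA produces all pairwise comparisons with the stated Bonferroni factor", {
  set.seed(2)
  groups <- split(rnorm(100), rep(letters[1:5], each = 20))
  res <- anova_bonferroni(groups)
  expect_equal(nrow(res$pairwise), 10L)
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, 10 * res$pairwise$p_raw))
})

test_that("ANOVA detects a 5-SD group shift", {
  set.seed(3)
  res <- anova_bonferroni(list(a = rnorm(50), b = rnorm(50, 5)))
  expect_lt(res$p, 1e-6)
})

test_that("ANOVA type-I error is calibrated at the nominal 5% level", {
  set.seed(123)
  rejections <- 0L
  n_sim <- 5000L
  for (i in seq_len(n_sim)) {
    g <- split(rnorm(60), rep(1:3, each = 20))
    names(g) <- c("a", "b", "c")
    if (anova_bonferroni(g)$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("small groups are excluded from the group comparison", {
  set.seed(4)
  res <- anova_bonferroni(list(a = rnorm(10), b = rnorm(10), c = 1))
  expect_equal(res$excluded, "c")
  expect_equal(nrow(res$pairwise), 1L)
})

test_that("the rank-based alternative runs Kruskal-Wallis with Mann-Whitney pairs", {
  set.seed(6)
  groups <- split(rexp(90), rep(letters[1:3], each = 30))
  res <- anova_bonferroni(groups, method = "kruskal")
  kw <- stats::kruskal.test(unlist(groups),
                            factor(rep(letters[1:3], each = 30)))
  expect_equal(res$p, kw$p.value)
  expect_equal(unique(res$pairwise$method), "mann_whitney")
})
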