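make_groups <- function(counts, labels = c("u_org", "u_euk", "chor", "mamm")) {
  stats::setNames(lapply(counts, function(k) rep(1, k)),
                  labels[seq_along(counts)])
}

test_that("an undersized youngest group merges into its older neighbour", {
  g <- merge_small_groups(make_groups(c(34, 34, 14, 9)), min_n = 10)
  expect_equal(names(g), c("u_org", "u_euk", "chor+mamm"))
  expect_equal(lengths(g), c("u_org" = 34L, "u_euk" = 34L,
                             "chor+mamm" = 23L))
})

test_that("groups above the threshold are left untouched", {
  before <- make_groups(c(20, 30, 15, 12))
  expect_identical(merge_small_groups(before, 10), before)
})

test_that("an undersized oldest group merges into its younger neighbour", {
  g <- merge_small_groups(make_groups(c(5, 5, 100), c("a", "b", "c")), 10)
  expect_equal(names(g), c("a+b", "c"))
  expect_equal(unname(lengths(g)), c(10L, 100L))
})

test_that("merging conserves the total count and the age order", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    counts <- sample(1:40, k, replace = TRUE)
    groups <- stats::setNames(
      lapply(seq_len(k), function(j) rep(j, counts[j])), paste0("grp", 1:k))
    merged <- merge_small_groups(groups, 10)
    expect_equal(sum(lengths(merged)), sum(counts))
    expect_true(all(lengths(merged) >= pmin(10, sum(counts))))
    # values were tagged by original age position: order must be preserved
    expect_equal(unlist(merged, use.names = FALSE),
                 sort(unlist(merged, use.names = FALSE)))
  }
})

test_that("group summaries compute the stated central value and sample variance", {
  s <- group_summaries(list(a = c(1, 2, 3), b = 5))
  expect_equal(s$central_value, c(2, 5))
  expect_equal(s$variance, c(1, 0))   # (1 + 0 + 1) / 2 and singleton
  expect_equal(s$n, c(3L, 1L))

  twin <- group_summaries(list(x = c(4, 7, 1), y = c(1, 4, 7)))
  expect_equal(twin$central_value[1], twin$central_value[2])
  expect_equal(twin$variance[1], twin$variance[2])

  expect_warning(group_summaries(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("transcription rates follow the steady-state inverse law", {
  hl <- c(g1 = 1, g2 = 2, g3 = 4)
  tr <- derive_transcription_rates(hl)
  expect_equal(tr$mode, "decay_only")
  expect_equal(unname(tr$rates["g1"]), log(2))
  expect_equal(unname(tr$rates["g1"] / tr$rates["g2"]), 2)
  expect_equal(unname(tr$rates["g2"] / tr$rates["g3"]), 2)

  ab <- c(g1 = 10, g2 = 10, g3 = 40)
  tr2 <- derive_transcription_rates(hl, ab)
  expect_equal(tr2$mode, "abundance_scaled")
  expect_equal(unname(tr2$rates["g3"] / tr2$rates["g1"]), 1)

  expect_warning(tr3 <- derive_transcription_rates(c(g1 = 2, g2 = -1)),
                 "rejected")
  expect_equal(tr3$n_rejected, 1L)
})

test_that("the joint age-attribute analysis recovers the planted trend", {
  g <- generate_gene_table(small_config(n_genes = 3000L, seed = 31))
  res <- age_attribute_analysis(g, turnover_map(g))
  expect_lt(res$correlation$r, 0)
  expect_lt(res$test$p, 1e-4)
  # oldest group has the smallest median turnover
  expect_lt(res$summaries$central_value[1],
            res$summaries$central_value[nrow(res$summaries)])
  expect_equal(sum(res$summaries$n), res$n)
})
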