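pairs_df <- function(h, m, disease = 0, ids = sprintf("h%03d", seq_along(h))) {
  data.frame(human_id = ids, mouse_id = sub("h", "m", ids),
             human_turnover = h, mouse_turnover = m, ratio = h / m,
             disease_count = rep_len(disease, length(h)),
             stringsAsFactors = FALSE)
}

test_that("paired comparison reports ties separately from the higher fraction", {
  eq <- pair_turnover_comparison(pairs_df(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(eq$fraction_human_higher, 0)
  expect_equal(eq$fraction_ties, 1)

  sc <- pair_turnover_comparison(pairs_df(c(2, 3, 4), c(2, 3, 4) * 0.91))
  expect_equal(sc$fraction_human_higher, 1)
  expect_equal(sc$mean_ratio, 1 / 0.91, tolerance = 1e-12)
  expect_error(pair_turnover_comparison(pairs_df(2, 1)), "at least 2")
})

test_that("disease bins conserve the total disease count", {
  set.seed(15)
  p <- pairs_df(runif(90, 1, 3), runif(90, 1, 3),
                disease = rpois(90, 0.5))
  db <- disease_ratio_bins(p, 30L)
  expect_equal(nrow(db), 3L)
  expect_equal(sum(db$disease_sum), sum(p$disease_count))
  expect_true(all(diff(db$ratio_low) > 0))

  z <- disease_ratio_bins(pairs_df(runif(60, 1, 3), runif(60, 1, 3)), 30L)
  expect_true(all(z$disease_sum == 0))
  expect_error(disease_ratio_bins(p, 1L), "configuration error")
})

test_that("ratio analysis is equivariant under swapping the species", {
  set.seed(16)
  p <- pairs_df(runif(50, 1, 3), runif(50, 1, 3))
  swapped <- p
  swapped$human_turnover <- p$mouse_turnover
  swapped$mouse_turnover <- p$human_turnover
  swapped$ratio <- 1 / p$ratio
  a <- pair_turnover_comparison(p)
  b <- pair_turnover_comparison(swapped)
  expect_equal(b$fraction_human_higher, 1 - a$fraction_human_higher -
                 a$fraction_ties)
  expect_equal(sort(1 / swapped$ratio), sort(p$ratio))
})

test_that("turnover-decrease fractions follow the planted species factor", {
  h <- seq(1, 4, length.out = 420)
  det <- pairs_df(h, h * 0.91)
  fb <- turnover_decrease_fraction_bins(det, 210L)
  expect_equal(fb$fraction_mouse_lower, c(1, 1))
  # bins are sorted descending by human turnover
  expect_gte(fb$human_turnover_low[1], fb$human_turnover_high[2])

  set.seed(18)
  sym <- pairs_df(h, h * exp(rnorm(420, 0, 0.2)))
  fs <- turnover_decrease_fraction_bins(sym, 210L)
  expect_true(all(abs(fs$fraction_mouse_lower - 0.5) < 0.12))
})

test_that("exclusive assignment labels exact membership patterns", {
  asg <- exclusive_ptm_assignment(methylated = "p1",
                                  acetylated = c("p2", "p4"),
                                  phosphorylated = c("p3", "p4"),
                                  universe = c("p1", "p2", "p3", "p4", "p5"))
  cls <- stats::setNames(as.character(asg$ptm_class), asg$protein_id)
  expect_equal(unname(cls[c("p1", "p2", "p3", "p4", "p5")]),
               c("methylated", "acetylated", "phosphorylated", "multiple",
                 "none"))
  expect_equal(sum(table(asg$ptm_class)), 5L)
})

test_that("class turnover comparison accepts strongly unbalanced classes", {
  set.seed(19)
  ids <- sprintf("p%04d", 1:2500)
  meth <- ids[1:27]
  acet <- ids[28:440]          # 413 proteins
  phos <- ids[441:1937]        # 1497 proteins
  tm <- stats::setNames(c(rnorm(27, 1.9, 0.3), rnorm(413, 1.9, 0.3),
                          rnorm(1497, 2.3, 0.3), rnorm(563, 2.1, 0.3)),
                        ids)
  tm <- pmax(tm, 0.05)
  asg <- exclusive_ptm_assignment(meth, acet, phos, ids)
  res <- ptm_turnover_comparison(asg, tm)
  expect_equal(res$medians$n, c(27L, 413L, 1497L))
  expect_lt(res$medians$median_turnover[2], res$medians$median_turnover[3])
  acet_phos <- res$pairwise[res$pairwise$group_a == "acetylated" &
                              res$pairwise$group_b == "phosphorylated", ]
  expect_lt(acet_phos$p_adjusted, 0.05)
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, nrow(res$pairwise) * res$pairwise$p_raw))
})

test_that("identical PTM sets give identical fraction curves and normalized shares", {
  g <- generate_gene_table(small_config(n_genes = 400L, seed = 33))
  ids <- g$gene_id[seq(1, 400, by = 3)]
  asg <- exclusive_ptm_assignment(character(0), ids, ids, g$gene_id)
  suppressWarnings(pf <- ptm_age_fractions(asg, g))
  expect_equal(pf$within_group$acetylated, pf$within_group$phosphorylated)
  expect_equal(pf$across_group$acetylated, pf$across_group$phosphorylated)
  present <- pf$across_group$n_group > 0
  expect_equal(sum(pf$across_group$acetylated[present]), 1, tolerance = 1e-9)
})

test_that("planted old-biased acetylation doubles the oldest-group share", {
  cfg <- small_config(n_genes = 5000L, seed = 37)
  g <- generate_gene_table(cfg)
  ptm <- generate_ptm_labels(g, cfg)
  asg <- exclusive_ptm_assignment(ptm$methylated, ptm$acetylated,
                                  ptm$phosphorylated, g$gene_id)
  pf <- ptm_age_fractions(asg, g)
  ratio <- pf$within_group$acetylated[1] / pf$within_group$phosphorylated[1]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
  expect_lt(pf$mann_whitney$p, 1e-3)
})
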