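# Bootstrap-null ranking of GO categories by central protein turnover.
# For every category, random sets of matched size are resampled from the
# full turnover pool; the category statistic is expressed in standard
# deviations of that null distribution (z) and converted to a two-sided
# normal tail probability with significance stars.

#' Central turnover of a category
#'
#' @param gene_ids Character vector of category member ids.
#' @param turnover Named numeric vector (gene_id -> turnover).
#' @param statistic `"mean"` (default, the published table statistic) or
#'   `"median"`.
#' @return List with `stat` and `n` (number of members with turnover
#'   values); `stat` is `NA` when no member has a value.
#' @export
category_stat <- function(gene_ids, turnover, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  vals <- turnover[intersect(gene_ids, names(turnover))]
  vals <- vals[is.finite(vals)]
  n <- length(vals)
  if (n == 0L) return(list(stat = NA_real_, n = 0L))
  fun <- if (statistic == "mean") mean else stats::median
  list(stat = unname(fun(vals)), n = n)
}

#' Bootstrap null distribution for a category size
#'
#' Draws `n_iter` sets of `n_cat` turnover values with replacement from the
#' pool (without-replacement subsampling via `replace = FALSE`), computes
#' the statistic of each set, and returns the mean and SD (n - 1) of the
#' resulting null distribution.  Deterministic given `seed`.
#'
#' @param pool Numeric vector of all turnover values.
#' @param n_cat Category size (2 <= n_cat <= length(pool)).
#' @param n_iter Number of bootstrap sets (default 1000).
#' @param statistic `"mean"` or `"median"`.
#' @param seed Integer seed.
#' @param replace Sample with replacement (default TRUE).
#' @return List with `boot_mean`, `boot_sd`.
#' @export
bootstrap_null <- function(pool, n_cat, n_iter = 1000L,
                           statistic = c("mean", "median"), seed = 1L,
                           replace = TRUE) {
  statistic <- match.arg(statistic)
  pool <- pool[is.finite(pool)]
  if (!is_count(n_cat, min = 2L) || n_cat > length(pool)) {
    stop("n_cat must satisfy 2 <= n_cat <= pool size", call. = FALSE)
  }
  if (!is_count(n_iter)) stop("n_iter must be a positive integer", call. = FALSE)
  stats_null <- with_seed(seed, {
    draws <- matrix(pool[sample.int(length(pool), n_iter * n_cat,
                                    replace = replace)],
                    nrow = n_cat, ncol = n_iter)
    if (statistic == "mean") colMeans(draws) else apply(draws, 2, stats::median)
  })
  boot_sd <- stats::sd(stats_null)
  if (!is.finite(boot_sd) || boot_sd == 0) {
    stop("degenerate null: bootstrap SD is zero (constant pool)",
         call. = FALSE)
  }
  list(boot_mean = mean(stats_null), boot_sd = boot_sd)
}

#' Significance of a category statistic against its bootstrap null
#'
#' `z = (stat - boot_mean) / boot_sd`; p is the two-sided normal tail
#' probability; stars use strict thresholds `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05.
#'
#' @param stat Category statistic.
#' @param boot_mean,boot_sd Null moments from [bootstrap_null()].
#' @param empirical_null Optional numeric vector of null statistics; when
#'   supplied, p is the empirical two-sided tail fraction (granularity
#'   1/length) instead of the normal approximation.
#' @return List with `z`, `p`, `stars`.
#' @export
category_significance <- function(stat, boot_mean, boot_sd,
                                  empirical_null = NULL) {
  if (!is_number(boot_sd) || boot_sd <= 0) {
    stop("boot_sd must be positive", call. = FALSE)
  }
  z <- (stat - boot_mean) / boot_sd
  p <- if (is.null(empirical_null)) {
    2 * stats::pnorm(-abs(z))
  } else {
    min(1, 2 * mean(abs(empirical_null - boot_mean) >= abs(stat - boot_mean)))
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(z = z, p = p, stars = stars)
}

#' Rank GO categories by central turnover with bootstrap-null significance
#'
#' Computes the per-category statistic, draws each category's matched-size
#' bootstrap null from the full turnover pool, and returns the categories
#' sorted ascending by statistic (ties broken by category id).  Categories
#' with fewer than `min_size` members carrying turnover values are excluded;
#' categories with no overlap are skipped with a warning.
#'
#' @param go Long-format GO annotation data frame (`category_id`, `name`,
#'   `gene_id`), as from [read_go_annotations()] or
#'   [generate_go_annotations()].
#' @param turnover Named numeric vector (gene_id -> turnover).
#' @param statistic `"mean"` (default) or `"median"`.
#' @param n_iter Bootstrap iterations per category (default 1000).
#' @param min_size Minimum category size (default 50).
#' @param seed Integer seed; per-category sub-seeds are derived from it and
#'   the category id, so results do not depend on category order.
#' @param replace Passed to [bootstrap_null()].
#' @return Data frame of class `category_ranking` with columns
#'   `category_id`, `name`, `stat`, `n`, `boot_mean`, `boot_sd`, `z`, `p`,
#'   `stars`, sorted ascending by `stat`.
#' @export
rank_categories <- function(go, turnover, statistic = c("mean", "median"),
                            n_iter = 1000L, min_size = 50L, seed = 1L,
                            replace = TRUE) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("category_id", "name", "gene_id") %in% names(go)))
  pool <- turnover[is.finite(turnover)]
  ids <- split(go$gene_id, go$category_id)
  nm <- vapply(split(go$name, go$category_id), function(x) x[1], character(1))
  res <- vector("list", length(ids))
  skipped <- character()
  for (i in seq_along(ids)) {
    cid <- names(ids)[i]
    cs <- category_stat(ids[[i]], pool, statistic)
    if (cs$n == 0L) {
      skipped <- c(skipped, cid)
      next
    }
    if (cs$n < min_size || cs$n < 2L) next
    null <- bootstrap_null(pool, cs$n, n_iter = n_iter, statistic = statistic,
                           seed = derive_seed(seed, cid), replace = replace)
    sig <- category_significance(cs$stat, null$boot_mean, null$boot_sd)
    res[[i]] <- data.frame(category_id = cid, name = nm[[cid]],
                           stat = cs$stat, n = cs$n,
                           boot_mean = null$boot_mean, boot_sd = null$boot_sd,
                           z = sig$z, p = sig$p, stars = sig$stars,
                           stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipped categories with no turnover overlap: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("no usable categories", call. = FALSE)
  out <- do.call(rbind, res)
  out <- out[order(out$stat, out$category_id), ]
  rownames(out) <- NULL
  class(out) <- c("category_ranking", "data.frame")
  out
}

#' @export
print.category_ranking <- function(x, ...) {
  cat("GO categories ranked by turnover (", nrow(x), " categories)\n", sep = "")
  show <- data.frame(Category = x$category_id, Name = x$name,
                     Turnover = round(x$stat, 2), N = x$n,
                     z = round(x$z, 2), Significance = x$stars)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Cross-species correlation of category rankings
#'
#' Spearman correlation of the rank positions of the categories shared
#' between two rankings (at least 3 shared ids required).
#'
#' @param ranking_a,ranking_b `category_ranking` data frames (or any data
#'   frames with `category_id` and `stat`, assumed sorted by rank).
#' @return An `agestrat_cor` object.
#' @export
cross_species_rank_correlation <- function(ranking_a, ranking_b) {
  shared <- intersect(ranking_a$category_id, ranking_b$category_id)
  if (length(shared) < 3L) {
    stop("need at least 3 shared categories", call. = FALSE)
  }
  ra <- match(shared, ranking_a$category_id)
  rb <- match(shared, ranking_b$category_id)
  spearman_rank_correlation(ra, rb)
}
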