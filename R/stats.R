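# Core statistical tests used throughout the age-attribute analyses.

#' Spearman rank correlation with large-sample p-value
#'
#' Computes Spearman's r on average ranks (ties share the mean rank) and a
#' two-sided p-value from the large-sample t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.  An exact
#' permutation p-value is available for small samples (`exact = TRUE`,
#' n <= 10), obtained by enumerating all permutations of one variable.
#'
#' @param x,y Paired numeric vectors (n >= 3, finite, each with nonzero
#'   variance).
#' @param exact Use exact permutation p (only for n <= 10).
#' @return List of class `agestrat_cor` with elements `r`, `p`, `n`,
#'   `method`.
#' @export
spearman_rank_correlation <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("undefined correlation: need at least 3 paired values",
                   call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero variance in a variable", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10L) stop("exact permutation p only supported for n <= 10",
                      call. = FALSE)
    perms <- permutations_of(n)
    robs <- abs(r)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= robs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    method <- "exact permutation"
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  structure(list(r = r, p = p, n = n, method = method),
            class = "agestrat_cor")
}

#' @export
print.agestrat_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r = %.4f, p = %.4g, n = %d (%s)\n",
              x$r, x$p, x$n, x$method))
  invisible(x)
}

# All n! permutations of 1..n as a matrix (rows).  Used only for small n.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from the rank sum with average ranks for ties.  When both
#' samples have at most `exact_limit` observations the p-value is obtained by
#' exhaustive enumeration of all group assignments (valid under ties, where
#' the classical exact distribution does not apply); otherwise the
#' tie-corrected normal approximation of [stats::wilcox.test()] is used.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact `NULL` (auto: exact when both n <= `exact_limit`), or
#'   logical.
#' @param exact_limit Largest per-group size for the enumeration branch.
#' @return List of class `agestrat_mw` with elements `statistic` (U of the
#'   first sample), `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact = NULL, exact_limit = 8L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty", call. = FALSE)
  if (is.null(exact)) exact <- (n1 <= exact_limit && n2 <= exact_limit)
  comb <- c(x, y)
  rk <- rank(comb, ties.method = "average")
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  structure(list(statistic = u_obs, p = p, n1 = n1, n2 = n2, method = method),
            class = "agestrat_mw")
}

#' @export
print.agestrat_mw <- function(x, ...) {
  cat(sprintf("Mann-Whitney test: U = %.1f, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$statistic, x$p, x$n1, x$n2, x$method))
  invisible(x)
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Runs a one-way ANOVA on raw values across age groups, followed by all
#' pairwise two-sample t tests (pooled variance, consistent with the ANOVA
#' model) with a Bonferroni factor of `m = G * (G - 1) / 2` over the included
#' groups.  A rank-based alternative (`method = "kruskal"`) replaces the
#' ANOVA by Kruskal-Wallis and the pairwise t tests by Mann-Whitney tests,
#' useful because turnover distributions are right-skewed.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups).
#'   Groups with fewer than 2 observations are excluded and noted.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @return List of class `agestrat_anova` with elements `method`,
#'   `statistic` (F or Kruskal-Wallis chi-squared), `df`, `p`, `pairwise`
#'   (data frame: `group_a`, `group_b`, `statistic`, `p_raw`, `p_adjusted`,
#'   `method`) and `excluded` (names of dropped groups).
#' @export
anova_bonferroni <- function(values_by_group, method = c("anova", "kruskal")) {
  method <- match.arg(method)
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  values_by_group <- lapply(values_by_group, function(v) v[is.finite(v)])
  sizes <- lengths(values_by_group)
  excluded <- names(values_by_group)[sizes < 2L]
  values_by_group <- values_by_group[sizes >= 2L]
  G <- length(values_by_group)
  if (G < 2L) stop("need at least 2 groups with n >= 2", call. = FALSE)
  groups <- names(values_by_group)
  val <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(groups, lengths(values_by_group)), levels = groups)
  if (method == "anova") {
    tab <- stats::anova(stats::lm(val ~ grp))
    statistic <- tab[["F value"]][1]
    df <- unname(tab[["Df"]])
    p <- tab[["Pr(>F)"]][1]
  } else {
    kw <- stats::kruskal.test(val, grp)
    statistic <- unname(kw$statistic)
    df <- unname(kw$parameter)
    p <- kw$p.value
  }
  pairs <- utils::combn(groups, 2)
  m <- ncol(pairs)
  pw <- vector("list", m)
  for (i in seq_len(m)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (method == "anova") {
      tt <- stats::t.test(values_by_group[[a]], values_by_group[[b]],
                          var.equal = TRUE)
      stat_i <- unname(tt$statistic); p_i <- tt$p.value
      lab <- "anova_bonferroni"
    } else {
      mw <- mann_whitney_test(values_by_group[[a]], values_by_group[[b]],
                              exact = FALSE)
      stat_i <- mw$statistic; p_i <- mw$p
      lab <- "mann_whitney"
    }
    pw[[i]] <- data.frame(group_a = a, group_b = b, statistic = stat_i,
                          p_raw = p_i, p_adjusted = min(1, m * p_i),
                          method = lab, stringsAsFactors = FALSE)
  }
  structure(list(method = method, statistic = statistic, df = df, p = p,
                 pairwise = do.call(rbind, pw), excluded = excluded),
            class = "agestrat_anova")
}

#' @export
print.agestrat_anova <- function(x, ...) {
  lab <- if (x$method == "anova") "One-way ANOVA" else "Kruskal-Wallis"
  cat(sprintf("%s: statistic = %.3f, p = %.4g\n", lab, x$statistic, x$p))
  cat("Pairwise comparisons (Bonferroni over",
      nrow(x$pairwise), "pairs):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  if (length(x$excluded)) {
    cat("Excluded groups (n < 2):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
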