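# Post-translational-modification class analyses: exclusive class
# assignment, class-wise turnover comparison, and age-group PTM fractions.

#' Exclusive PTM class assignment
#'
#' Labels every protein of the universe by its exact membership pattern in
#' the methylated / acetylated / phosphorylated sets: proteins carrying
#' exactly one modification get that class, proteins carrying several get
#' `"multiple"` (excluded from exclusive analyses), the rest `"none"`.
#'
#' @param methylated,acetylated,phosphorylated Character vectors of protein
#'   ids.
#' @param universe Character vector of proteins to classify (typically the
#'   proteins with turnover values).
#' @return Data frame of class `ptm_assignment` with columns `protein_id`,
#'   `methylated`, `acetylated`, `phosphorylated` (logical membership) and
#'   `ptm_class` (factor: methylated, acetylated, phosphorylated, multiple,
#'   none).  Class counts partition the universe.
#' @export
exclusive_ptm_assignment <- function(methylated, acetylated, phosphorylated,
                                     universe) {
  universe <- unique(as.character(universe))
  m <- universe %in% methylated
  a <- universe %in% acetylated
  p <- universe %in% phosphorylated
  total <- m + a + p
  cls <- ifelse(total == 0L, "none",
         ifelse(total > 1L, "multiple",
         ifelse(m, "methylated", ifelse(a, "acetylated", "phosphorylated"))))
  out <- data.frame(protein_id = universe,
                    methylated = m, acetylated = a, phosphorylated = p,
                    ptm_class = factor(cls, levels = c("methylated",
                                                       "acetylated",
                                                       "phosphorylated",
                                                       "multiple", "none")),
                    stringsAsFactors = FALSE)
  class(out) <- c("ptm_assignment", "data.frame")
  out
}

#' Turnover comparison across exclusive PTM classes
#'
#' Median turnover per exclusive class (methylated, acetylated,
#' phosphorylated) and pairwise Mann-Whitney tests with Bonferroni
#' correction over the tested pairs.  Empty classes are omitted from the
#' pairwise comparisons.
#'
#' @param assignments A [exclusive_ptm_assignment()] result.
#' @param turnover Named numeric vector (protein_id -> turnover).
#' @return List of class `ptm_turnover` with `medians` (data frame: class,
#'   n, median_turnover) and `pairwise` (data frame: group_a, group_b,
#'   statistic, p_raw, p_adjusted, method).
#' @export
ptm_turnover_comparison <- function(assignments, turnover) {
  classes <- c("methylated", "acetylated", "phosphorylated")
  vals <- lapply(classes, function(cl) {
    ids <- assignments$protein_id[assignments$ptm_class == cl]
    v <- turnover[intersect(ids, names(turnover))]
    unname(v[is.finite(v)])
  })
  names(vals) <- classes
  med <- data.frame(class = classes,
                    n = unname(lengths(vals)),
                    median_turnover = vapply(vals, function(v) {
                      if (length(v)) stats::median(v) else NA_real_
                    }, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  nonempty <- classes[lengths(vals) > 0L]
  if (length(nonempty) < 2L) {
    stop("need at least 2 nonempty exclusive classes", call. = FALSE)
  }
  pairs <- utils::combn(nonempty, 2)
  m <- ncol(pairs)
  pw <- vector("list", m)
  for (i in seq_len(m)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    mw <- mann_whitney_test(vals[[a]], vals[[b]], exact = FALSE)
    pw[[i]] <- data.frame(group_a = a, group_b = b, statistic = mw$statistic,
                          p_raw = mw$p, p_adjusted = min(1, m * mw$p),
                          method = "mann_whitney", stringsAsFactors = FALSE)
  }
  structure(list(medians = med, pairwise = do.call(rbind, pw)),
            class = "ptm_turnover")
}

#' @export
print.ptm_turnover <- function(x, ...) {
  cat("Turnover by exclusive PTM class\n")
  print(x$medians, row.names = FALSE, digits = 4)
  cat("Pairwise Mann-Whitney (Bonferroni over", nrow(x$pairwise), "pairs):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' PTM fractions by age group, under both normalization conventions
#'
#' For each age group and PTM class, computes: convention A (within-group) -
#' the share of the group's proteins carrying the PTM; convention B
#' (across-group) - the share of the PTM's proteins that fall in the group
#' (sums to 1 over groups).  By default raw set membership is used (a
#' protein with several PTMs counts for each); `exclusive = TRUE` restricts
#' to exclusive classes.  Also reports a Mann-Whitney test comparing the age
#' ranks of acetylated vs. phosphorylated proteins.
#'
#' @param assignments A [exclusive_ptm_assignment()] result.
#' @param gene_age Data frame with `gene_id`, `age_group`, `age_rank`.
#' @param scheme An [age_group_scheme()] fixing group order.
#' @param exclusive Use exclusive classes instead of raw membership.
#' @return List of class `ptm_age_fractions` with `within_group` and
#'   `across_group` data frames (columns `group`, `n_group`, then one column
#'   per PTM class), `mann_whitney` (`agestrat_mw`, acetylated vs.
#'   phosphorylated age ranks) and `counts` (proteins per class).
#' @export
ptm_age_fractions <- function(assignments, gene_age,
                              scheme = age_group_scheme(),
                              exclusive = FALSE) {
  stopifnot(all(c("gene_id", "age_group", "age_rank") %in% names(gene_age)))
  idx <- match(assignments$protein_id, gene_age$gene_id)
  keep <- !is.na(idx)
  a <- assignments[keep, , drop = FALSE]
  grp <- factor(gene_age$age_group[idx[keep]], levels = scheme$groups)
  rankv <- gene_age$age_rank[idx[keep]]
  classes <- c("methylated", "acetylated", "phosphorylated")
  member <- if (exclusive) {
    sapply(classes, function(cl) a$ptm_class == cl)
  } else {
    as.matrix(a[, classes])
  }
  n_group <- table(grp)
  if (any(n_group == 0L)) {
    warning("group(s) with 0 proteins, fractions undefined: ",
            paste(names(n_group)[n_group == 0L], collapse = ", "),
            call. = FALSE)
  }
  counts <- rowsum(member + 0, grp)          # groups x classes
  class_tot <- colSums(counts)
  within <- sweep(counts, 1, as.numeric(n_group), "/")
  across <- sweep(counts, 2, class_tot, "/")
  to_df <- function(mat) {
    df <- data.frame(group = rownames(mat), n_group = as.integer(n_group),
                     stringsAsFactors = FALSE)
    for (cl in classes) df[[cl]] <- unname(mat[, cl])
    df
  }
  mw <- mann_whitney_test(rankv[member[, "acetylated"] > 0],
                          rankv[member[, "phosphorylated"] > 0],
                          exact = FALSE)
  structure(list(within_group = to_df(within),
                 across_group = to_df(across),
                 mann_whitney = mw,
                 counts = class_tot,
                 exclusive = exclusive),
            class = "ptm_age_fractions")
}

#' @export
print.ptm_age_fractions <- function(x, ...) {
  cat("PTM fractions by age group (",
      if (x$exclusive) "exclusive classes" else "raw membership", ")\n",
      sep = "")
  cat("Within-group shares (convention A):\n")
  print(x$within_group, row.names = FALSE, digits = 3)
  cat("Across-group shares (convention B, columns sum to 1):\n")
  print(x$across_group, row.names = FALSE, digits = 3)
  cat(sprintf("Acetylated vs phosphorylated age ranks: Mann-Whitney p = %.3g\n",
              x$mann_whitney$p))
  invisible(x)
}
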