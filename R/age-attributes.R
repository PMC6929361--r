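# Age stratification: small-group merging, group summaries, age correlation,
# and steady-state transcription-rate derivation.

#' Merge undersized age groups into their neighbours
#'
#' Groups are given in age order (oldest to youngest).  Any group with fewer
#' than `min_n` members is combined with its adjacent group on the older
#' side, or the younger side when no older neighbour exists; merged labels
#' concatenate the constituents in age order (e.g. `"chor+mamm"`).  Merging
#' proceeds youngest-first and repeats until every group reaches `min_n` (or
#' a single group remains).  Total gene count and age ordering are preserved.
#'
#' @param values_by_group Named list of numeric vectors in age order
#'   (oldest first).
#' @param min_n Minimum group size (default 10).
#' @return Named list of numeric vectors, in age order, with merged labels.
#' @export
merge_small_groups <- function(values_by_group, min_n = 10L) {
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  groups <- values_by_group
  repeat {
    sizes <- lengths(groups)
    if (length(groups) <= 1L || all(sizes >= min_n)) break
    i <- max(which(sizes < min_n))        # youngest undersized group first
    j <- if (i > 1L) i - 1L else i + 1L   # older neighbour, else younger
    lo <- min(i, j); hi <- max(i, j)
    merged <- c(groups[[lo]], groups[[hi]])
    nm <- paste(names(groups)[lo], names(groups)[hi], sep = "+")
    groups[[lo]] <- merged
    names(groups)[lo] <- nm
    groups[[hi]] <- NULL
  }
  groups
}

#' Per-group central value and variance
#'
#' @param values_by_group Named list of numeric vectors (age order
#'   recommended).  Groups that are empty after removing non-finite values
#'   are excluded with a warning.
#' @param statistic `"median"` (default) or `"mean"` for the central value.
#' @return Data frame with columns `group`, `n`, `central_value`, `variance`
#'   (sample variance, n - 1 denominator; 0 for singletons).
#' @export
group_summaries <- function(values_by_group, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  values_by_group <- lapply(values_by_group, function(v) v[is.finite(v)])
  empty <- lengths(values_by_group) == 0L
  if (any(empty)) {
    warning("excluding empty group(s): ",
            paste(names(values_by_group)[empty], collapse = ", "),
            call. = FALSE)
    values_by_group <- values_by_group[!empty]
  }
  if (!length(values_by_group)) stop("no nonempty groups", call. = FALSE)
  fun <- if (statistic == "median") stats::median else mean
  data.frame(group = names(values_by_group),
             n = unname(lengths(values_by_group)),
             central_value = vapply(values_by_group, fun, numeric(1)),
             variance = vapply(values_by_group, sample_var, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation between gene age and an attribute
#'
#' Convenience wrapper around [spearman_rank_correlation()] with the age
#' direction convention that a larger age value means an older gene, so
#' attributes that decrease with age (such as protein turnover) yield
#' negative correlations.
#'
#' @param age Numeric age values or ranks (larger = older).
#' @param attribute Paired attribute values.
#' @param exact Passed to [spearman_rank_correlation()].
#' @return An `agestrat_cor` object (elements `r`, `p`, `n`).
#' @export
spearman_age_correlation <- function(age, attribute, exact = FALSE) {
  spearman_rank_correlation(age, attribute, exact = exact)
}

#' Derive relative transcription rates from mRNA half-lives
#'
#' At steady state, transcription rates are proportional to degradation
#' rates, so the relative transcription rate of a gene is `ln(2) / half-life`
#' (decay-only mode) or `abundance * ln(2) / half-life` when steady-state
#' abundance is supplied (abundance-scaled mode).  Rows with nonpositive
#' half-lives are rejected and counted.
#'
#' @param half_life Named numeric vector of mRNA half-lives (> 0), names are
#'   gene ids.
#' @param abundance Optional named numeric vector of mRNA abundances; genes
#'   absent from `abundance` are dropped in abundance-scaled mode.
#' @return List of class `transcription_rates` with elements `rates` (named
#'   numeric), `mode` (`"decay_only"` or `"abundance_scaled"`) and
#'   `n_rejected`.
#' @export
derive_transcription_rates <- function(half_life, abundance = NULL) {
  if (is.null(names(half_life))) stop("half_life must be named by gene id",
                                      call. = FALSE)
  bad <- !is.finite(half_life) | half_life <= 0
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning(sprintf("%d gene(s) with nonpositive half-life rejected",
                    n_rejected), call. = FALSE)
  }
  hl <- half_life[!bad]
  if (!length(hl)) stop("no usable half-lives", call. = FALSE)
  if (is.null(abundance)) {
    rates <- log(2) / hl
    mode <- "decay_only"
  } else {
    common <- intersect(names(hl), names(abundance)[is.finite(abundance)])
    if (!length(common)) stop("no genes shared between half_life and abundance",
                              call. = FALSE)
    rates <- abundance[common] * log(2) / hl[common]
    mode <- "abundance_scaled"
  }
  structure(list(rates = rates, mode = mode, n_rejected = n_rejected),
            class = "transcription_rates")
}

#' @export
print.transcription_rates <- function(x, ...) {
  cat(sprintf("Relative transcription rates (%s mode): %d genes, %d rejected\n",
              x$mode, length(x$rates), x$n_rejected))
  invisible(x)
}

#' Split attribute values by age group
#'
#' Joins a gene/age table with a named attribute vector and returns the
#' attribute values grouped by age class, in age order (oldest first).
#'
#' @param gene_age Data frame from [read_gene_age_table()] (needs `gene_id`,
#'   `age_group`).
#' @param attribute Named numeric vector (gene_id -> value).
#' @param scheme An [age_group_scheme()] fixing the group order.
#' @return Named list of numeric vectors, ordered oldest to youngest;
#'   only groups present in the data are returned.
#' @export
values_by_age_group <- function(gene_age, attribute,
                                scheme = age_group_scheme()) {
  stopifnot(all(c("gene_id", "age_group") %in% names(gene_age)))
  common <- intersect(gene_age$gene_id, names(attribute))
  if (!length(common)) stop("no genes shared between age table and attribute",
                            call. = FALSE)
  sub <- gene_age[match(common, gene_age$gene_id), ]
  vals <- unname(attribute[common])
  out <- split(vals, factor(sub$age_group, levels = scheme$groups))
  out[lengths(out) > 0L]
}

#' Full age-vs-attribute analysis for one attribute
#'
#' Stratifies genes by age group (merging undersized groups), computes group
#' summaries, the Spearman age correlation (on age ranks) and the ANOVA with
#' Bonferroni post-hoc comparisons.
#'
#' @param gene_age Data frame with `gene_id`, `age_group`, `age_rank`.
#' @param attribute Named numeric vector (gene_id -> value).
#' @param scheme An [age_group_scheme()]; its `min_group_size` drives the
#'   merging step.
#' @param statistic Central statistic for group summaries.
#' @param test `"anova"` or `"kruskal"` for the group comparison.
#' @return List of class `age_attribute_analysis` with `summaries`
#'   (data frame), `correlation` (`agestrat_cor`), `test`
#'   (`agestrat_anova`), `n`.
#' @export
age_attribute_analysis <- function(gene_age, attribute,
                                   scheme = age_group_scheme(),
                                   statistic = c("median", "mean"),
                                   test = c("anova", "kruskal")) {
  statistic <- match.arg(statistic)
  test <- match.arg(test)
  by_group <- values_by_age_group(gene_age, attribute, scheme)
  merged <- merge_small_groups(by_group, scheme$min_group_size)
  common <- intersect(gene_age$gene_id, names(attribute))
  sub <- gene_age[match(common, gene_age$gene_id), ]
  structure(list(summaries = group_summaries(merged, statistic),
                 correlation = spearman_age_correlation(
                   sub$age_rank, unname(attribute[common])),
                 test = anova_bonferroni(merged, method = test),
                 n = length(common)),
            class = "age_attribute_analysis")
}

#' @export
print.age_attribute_analysis <- function(x, ...) {
  cat("Age-group analysis of", x$n, "genes\n")
  print(x$summaries, row.names = FALSE, digits = 4)
  print(x$correlation)
  cat(sprintf("Group comparison (%s): p = %.4g\n", x$test$method, x$test$p))
  invisible(x)
}
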