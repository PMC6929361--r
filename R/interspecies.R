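# Cross-species ortholog turnover comparison: paired means, ratio binning
# with disease-count sums, and binned fractions of pairs whose turnover
# decreases from human to mouse.

#' Paired human/mouse turnover comparison
#'
#' @param pairs Ortholog-pair data frame with `human_turnover`,
#'   `mouse_turnover` (>= 2 pairs).
#' @return List of class `pair_comparison` with `mean_human`, `mean_mouse`,
#'   `mean_ratio`, `fraction_human_higher` (ties excluded from the
#'   numerator), `fraction_ties`, `mann_whitney_p` (two-sided, on the two
#'   value lists), `n`.
#' @export
pair_turnover_comparison <- function(pairs) {
  stopifnot(all(c("human_turnover", "mouse_turnover") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  h <- pairs$human_turnover
  m <- pairs$mouse_turnover
  mw <- mann_whitney_test(h, m, exact = FALSE)
  structure(list(mean_human = mean(h),
                 mean_mouse = mean(m),
                 mean_ratio = mean(h / m),
                 fraction_human_higher = mean(h > m),
                 fraction_ties = mean(h == m),
                 mann_whitney_p = mw$p,
                 n = n),
            class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("Ortholog turnover comparison (%d pairs)\n", x$n))
  cat(sprintf("  mean human = %.3f, mean mouse = %.3f, mean ratio = %.3f\n",
              x$mean_human, x$mean_mouse, x$mean_ratio))
  cat(sprintf("  fraction human > mouse = %.3f (ties %.3f), Mann-Whitney p = %.3g\n",
              x$fraction_human_higher, x$fraction_ties, x$mann_whitney_p))
  invisible(x)
}

#' Disease counts summed over turnover-ratio bins
#'
#' Pairs are sorted ascending by `(ratio, human_id)` and cut into
#' consecutive bins of `bin_size` (default 30, the published bin size); the
#' final partial bin is flagged.  Bin sums conserve the total disease count.
#'
#' @param pairs Ortholog-pair data frame with `ratio`, `disease_count`,
#'   `human_id`; needs at least `bin_size` pairs.
#' @param bin_size Pairs per bin (>= 2).
#' @return Data frame with `bin_index`, `n_pairs`, `ratio_low`,
#'   `ratio_high`, `disease_sum`, `partial`.
#' @export
disease_ratio_bins <- function(pairs, bin_size = 30L) {
  if (!is_count(bin_size, min = 2L)) {
    stop("configuration error: bin_size must be an integer >= 2",
         call. = FALSE)
  }
  stopifnot(all(c("ratio", "disease_count", "human_id") %in% names(pairs)))
  if (nrow(pairs) < bin_size) {
    stop("need at least bin_size pairs", call. = FALSE)
  }
  s <- pairs[order(pairs$ratio, pairs$human_id), ]
  chunks <- chunk_indices(nrow(s), bin_size)
  out <- lapply(seq_along(chunks), function(i) {
    idx <- chunks[[i]]
    data.frame(bin_index = i,
               n_pairs = length(idx),
               ratio_low = min(s$ratio[idx]),
               ratio_high = max(s$ratio[idx]),
               disease_sum = sum(s$disease_count[idx]),
               partial = length(idx) < bin_size)
  })
  do.call(rbind, out)
}

#' Binned fraction of pairs with lower turnover in mouse
#'
#' Pairs are sorted descending by human turnover (ties broken by
#' `human_id`) and cut into consecutive bins of `bin_size` (default 210, the
#' published bin size); per bin, the fraction of pairs whose mouse turnover
#' is strictly below the human value is reported.
#'
#' @param pairs Ortholog-pair data frame with `human_turnover`,
#'   `mouse_turnover`, `human_id`; needs at least `bin_size` pairs.
#' @param bin_size Pairs per bin (>= 2).
#' @return Data frame with `bin_index`, `n_pairs`, `human_turnover_high`,
#'   `human_turnover_low`, `fraction_mouse_lower`, `partial`.
#' @export
turnover_decrease_fraction_bins <- function(pairs, bin_size = 210L) {
  if (!is_count(bin_size, min = 2L)) {
    stop("configuration error: bin_size must be an integer >= 2",
         call. = FALSE)
  }
  stopifnot(all(c("human_turnover", "mouse_turnover", "human_id") %in%
                  names(pairs)))
  if (nrow(pairs) < bin_size) {
    stop("need at least bin_size pairs", call. = FALSE)
  }
  s <- pairs[order(-pairs$human_turnover, pairs$human_id), ]
  chunks <- chunk_indices(nrow(s), bin_size)
  out <- lapply(seq_along(chunks), function(i) {
    idx <- chunks[[i]]
    data.frame(bin_index = i,
               n_pairs = length(idx),
               human_turnover_high = max(s$human_turnover[idx]),
               human_turnover_low = min(s$human_turnover[idx]),
               fraction_mouse_lower = mean(s$mouse_turnover[idx] <
                                             s$human_turnover[idx]),
               partial = length(idx) < bin_size)
  })
  do.call(rbind, out)
}
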