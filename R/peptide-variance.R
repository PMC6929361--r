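# Per-protein peptide-variance statistics and turnover binning.  The
# normalized variance (variance over the squared central turnover) is
# scale-free: rescaling all peptide values of a protein leaves it unchanged.

#' Per-protein peptide statistics
#'
#' For every protein with at least `min_peptides` quantified peptide values,
#' computes the central turnover, the sample variance of its peptide values,
#' and the normalized variance `variance / central^2` where `central` is the
#' protein's median peptide turnover (default; the mean is available via
#' `normalizer = "mean"`).
#'
#' @param peptides Data frame with columns `protein_id`, `peptide_ratio`
#'   (positive values).
#' @param min_peptides Minimum number of peptide measurements per protein
#'   (default 3); proteins below the threshold are dropped and counted
#'   (attribute `n_dropped`).
#' @param normalizer `"median"` (default) or `"mean"`: the central turnover
#'   used both as the reported protein turnover and as the normalizer.
#' @return Data frame of class `peptide_stats` with columns `protein_id`,
#'   `n_peptides`, `median_turnover`, `variance`, `normalized_variance`.
#' @export
protein_peptide_stats <- function(peptides, min_peptides = 3L,
                                  normalizer = c("median", "mean")) {
  normalizer <- match.arg(normalizer)
  stopifnot(all(c("protein_id", "peptide_ratio") %in% names(peptides)))
  if (nrow(peptides) == 0L) stop("empty peptide table", call. = FALSE)
  if (any(peptides$peptide_ratio <= 0)) {
    stop("peptide values must be positive", call. = FALSE)
  }
  cfun <- if (normalizer == "median") stats::median else mean
  by_prot <- split(peptides$peptide_ratio, peptides$protein_id)
  n <- lengths(by_prot)
  keep <- n >= min_peptides
  n_dropped <- sum(!keep)
  by_prot <- by_prot[keep]
  if (!length(by_prot)) stop("no protein passes the min_peptides filter",
                             call. = FALSE)
  central <- vapply(by_prot, cfun, numeric(1))
  variance <- vapply(by_prot, sample_var, numeric(1))
  out <- data.frame(protein_id = names(by_prot),
                    n_peptides = unname(n[keep]),
                    median_turnover = unname(central),
                    variance = unname(variance),
                    normalized_variance = unname(variance / central^2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "normalizer") <- normalizer
  class(out) <- c("peptide_stats", "data.frame")
  out
}

#' Bin proteins by turnover and aggregate normalized variance
#'
#' Proteins are sorted ascending by `(median_turnover, protein_id)` and cut
#' into consecutive bins of `bin_size` (default 93, the published bin size);
#' the final partial bin is retained and flagged.  The bin value is the
#' median of the member normalized variances (the mean is available via
#' `aggregate = "mean"`).
#'
#' @param stats A [protein_peptide_stats()] result.
#' @param bin_size Proteins per bin (>= 2).
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Data frame with columns `bin_index`, `n_proteins`,
#'   `turnover_low`, `turnover_high`, `bin_value`, `partial`.
#' @export
bin_by_turnover <- function(stats, bin_size = 93L,
                            aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!is_count(bin_size, min = 2L)) {
    stop("configuration error: bin_size must be an integer >= 2",
         call. = FALSE)
  }
  stopifnot(nrow(stats) >= 1L)
  ord <- order(stats$median_turnover, stats$protein_id)
  s <- stats[ord, ]
  afun <- if (aggregate == "median") stats::median else mean
  chunks <- chunk_indices(nrow(s), bin_size)
  out <- lapply(seq_along(chunks), function(i) {
    idx <- chunks[[i]]
    data.frame(bin_index = i,
               n_proteins = length(idx),
               turnover_low = min(s$median_turnover[idx]),
               turnover_high = max(s$median_turnover[idx]),
               bin_value = afun(s$normalized_variance[idx]),
               partial = length(idx) < bin_size)
  })
  do.call(rbind, out)
}

#' Proteins quantified with an exact number of peptides
#'
#' Display/fixture subset mirroring the published panel of proteins measured
#' with exactly 15 peptides.
#'
#' @param stats A [protein_peptide_stats()] result.
#' @param exact_n Required peptide count (default 15).
#' @return Subset of `stats` (possibly empty).
#' @export
peptide_count_subset <- function(stats, exact_n = 15L) {
  stats[stats$n_peptides == exact_n, , drop = FALSE]
}

#' Normalize peptide values by the protein's central turnover
#'
#' Divides each peptide value by the protein median (or any supplied
#' positive normalizer), so the median of the output equals 1 and the sample
#' variance of the output equals the protein's normalized variance.
#'
#' @param values Positive peptide values.
#' @param center Normalizer; defaults to `median(values)`.
#' @return Numeric vector of normalized values.
#' @export
normalize_peptides <- function(values, center = stats::median(values)) {
  if (!is_number(center) || center <= 0) {
    stop("normalizer must be a positive number", call. = FALSE)
  }
  values / center
}
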