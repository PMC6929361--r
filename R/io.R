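# Readers and writers for the tabular input formats.  All files are TSV with
# a header line, UTF-8, "." decimal separator; lines starting with "#" are
# comments.  Every reader either returns a typed table or fails with a
# located error; rows skipped in lenient modes are counted and reported.

#' Read a gene/age table
#'
#' Expects columns `gene_id` plus `age_branch` and/or `age_numeric` (column
#' names are configurable because gene-age resources differ in their output
#' layout).  Branch labels are mapped to age groups via the scheme; age rank
#' is assigned so that the oldest group has the largest rank.
#'
#' @param path TSV file path.
#' @param scheme An [age_group_scheme()].
#' @param strict If `TRUE`, an unmapped branch label is an error; otherwise
#'   such rows are skipped and counted (see attribute `n_unmapped` and the
#'   warning).
#' @param column_map Named character vector mapping the canonical column
#'   names (`gene_id`, `age_branch`, `age_numeric`) to the names used in the
#'   file.
#' @return Data frame with columns `gene_id`, `age_branch`, `age_group`,
#'   `age_rank`, `age_numeric` (NA when absent).  Attributes `n_unmapped`
#'   and `unmapped_branches` report skipped rows in lenient mode.
#' @export
read_gene_age_table <- function(path, scheme = age_group_scheme(),
                                strict = FALSE,
                                column_map = c(gene_id = "gene_id",
                                               age_branch = "age_branch",
                                               age_numeric = "age_numeric")) {
  df <- read_tsv(path)
  id_col <- column_map[["gene_id"]]
  br_col <- column_map[["age_branch"]]
  num_col <- column_map[["age_numeric"]]
  require_columns(df, id_col, path)
  if (!(br_col %in% names(df)) && !(num_col %in% names(df))) {
    stop(sprintf("format error in %s: need column %s or %s",
                 path, br_col, num_col), call. = FALSE)
  }
  out <- data.frame(gene_id = as.character(df[[id_col]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene_id)) || anyNA(out$gene_id)) {
    stop(sprintf("format error in %s: empty gene_id", path), call. = FALSE)
  }
  if (anyDuplicated(out$gene_id)) {
    stop(sprintf("format error in %s: duplicate gene_id", path), call. = FALSE)
  }
  out$age_branch <- if (br_col %in% names(df)) as.character(df[[br_col]]) else NA_character_
  out$age_numeric <- if (num_col %in% names(df)) as.numeric(df[[num_col]]) else NA_real_
  unmapped <- character()
  if (br_col %in% names(df)) {
    grp <- unname(scheme$branch_to_group[out$age_branch])
    miss <- !is.na(out$age_branch) & is.na(grp)
    if (any(miss)) {
      unmapped <- unique(out$age_branch[miss])
      if (strict) {
        stop(sprintf("mapping error in %s: unmapped branch label(s) %s",
                     path, paste(unmapped, collapse = ", ")), call. = FALSE)
      }
      warning(sprintf("%d row(s) with unmapped branch label skipped (%s)",
                      sum(miss), paste(unmapped, collapse = ", ")),
              call. = FALSE)
      out <- out[!miss, , drop = FALSE]
      grp <- grp[!miss]
    }
    out$age_group <- grp
    out$age_rank <- unname(scheme$ranks[grp])
  } else {
    out$age_group <- NA_character_
    out$age_rank <- NA_integer_
  }
  rownames(out) <- NULL
  out <- out[, c("gene_id", "age_branch", "age_group", "age_rank", "age_numeric")]
  attr(out, "n_unmapped") <- length(unmapped)
  attr(out, "unmapped_branches") <- unmapped
  out
}

#' Read a per-gene attribute table
#'
#' Expects columns `gene_id` and a numeric `value` column.  Empty value cells
#' are skipped and counted; non-numeric cells are a format error with the
#' offending row number; duplicate gene ids are resolved by the configured
#' rule (default: median, matching the analysis' preference for medians).
#'
#' @param path TSV file path.
#' @param attribute_name Name recorded on the result (attribute
#'   `attribute_name`).
#' @param transform One of `"none"`, `"log2"`, `"log10"`.
#' @param duplicates One of `"median"`, `"first"`, `"error"`.
#' @param value_col Name of the value column in the file.
#' @return Named numeric vector (gene_id -> value) with attributes
#'   `attribute_name` and `n_skipped`.
#' @export
read_attribute_table <- function(path, attribute_name,
                                 transform = c("none", "log2", "log10"),
                                 duplicates = c("median", "first", "error"),
                                 value_col = "value") {
  transform <- match.arg(transform)
  duplicates <- match.arg(duplicates)
  df <- read_tsv(path, colClasses = "character")
  require_columns(df, c("gene_id", value_col), path)
  raw <- df[[value_col]]
  empty <- is.na(raw) | !nzchar(trimws(raw))
  vals <- suppressWarnings(as.numeric(raw))
  bad <- !empty & is.na(vals)
  if (any(bad)) {
    stop(sprintf("format error in %s: non-numeric value at data row %d",
                 path, which(bad)[1]), call. = FALSE)
  }
  n_skipped <- sum(empty | !is.finite(vals))
  keep <- !empty & is.finite(vals)
  if (!any(keep)) stop(sprintf("no usable rows in %s", path), call. = FALSE)
  if (n_skipped > 0) {
    warning(sprintf("%d row(s) with empty or non-finite value skipped in %s",
                    n_skipped, path), call. = FALSE)
  }
  ids <- df$gene_id[keep]
  vals <- vals[keep]
  if (anyDuplicated(ids)) {
    if (duplicates == "error") {
      stop(sprintf("format error in %s: duplicate gene_id under strict mode",
                   path), call. = FALSE)
    }
    agg <- if (duplicates == "median") {
      tapply(vals, ids, stats::median)
    } else {
      tapply(vals, ids, function(x) x[1])
    }
    out <- stats::setNames(as.numeric(agg), names(agg))
    # preserve first-appearance order
    out <- out[unique(ids)]
  } else {
    out <- stats::setNames(vals, ids)
  }
  out <- switch(transform, none = out, log2 = log2(out), log10 = log10(out))
  if (any(!is.finite(out))) {
    stop(sprintf("format error in %s: %s transform produced non-finite values",
                 path, transform), call. = FALSE)
  }
  attr(out, "attribute_name") <- attribute_name
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read GO annotations (long format)
#'
#' One row per category membership; columns `category_id`, `name`,
#' `gene_id`.  Category ids must match the GO accession pattern
#' `GO:NNNNNNN`.
#'
#' @param path TSV file path.
#' @return Data frame with columns `category_id`, `name`, `gene_id`.
#' @export
read_go_annotations <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  require_columns(df, c("category_id", "name", "gene_id"), path)
  bad <- !grepl("^GO:[0-9]{7}$", df$category_id)
  if (any(bad)) {
    stop(sprintf("format error in %s: malformed category_id at data row %d",
                 path, which(bad)[1]), call. = FALSE)
  }
  df <- df[, c("category_id", "name", "gene_id")]
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Read a per-peptide turnover table
#'
#' Columns `protein_id`, `peptide_ratio`.  Nonpositive or non-finite ratios
#' are rejected and counted (attribute `n_rejected`).
#'
#' @param path TSV file path.
#' @return Data frame with columns `protein_id`, `peptide_ratio`.
#' @export
read_peptide_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("protein_id", "peptide_ratio"), path)
  v <- suppressWarnings(as.numeric(df$peptide_ratio))
  bad <- is.na(v) | !is.finite(v) | v <= 0
  if (all(bad)) stop(sprintf("no usable rows in %s", path), call. = FALSE)
  if (any(bad)) {
    warning(sprintf("%d row(s) with nonpositive or non-numeric peptide_ratio rejected in %s",
                    sum(bad), path), call. = FALSE)
  }
  out <- data.frame(protein_id = as.character(df$protein_id[!bad]),
                    peptide_ratio = v[!bad], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read an ortholog-pair table
#'
#' Columns `human_id`, `mouse_id`, `human_turnover`, `mouse_turnover` and
#' optionally `disease_count`.  A missing disease count is treated as 0 with
#' a warning (absence from the disease catalogue = no recorded disease).
#' The human/mouse turnover ratio is computed on read.
#'
#' @param path TSV file path.
#' @return Data frame with columns `human_id`, `mouse_id`, `human_turnover`,
#'   `mouse_turnover`, `ratio`, `disease_count`.
#' @export
read_homolog_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("human_id", "mouse_id", "human_turnover",
                        "mouse_turnover"), path)
  ht <- suppressWarnings(as.numeric(df$human_turnover))
  mt <- suppressWarnings(as.numeric(df$mouse_turnover))
  bad <- is.na(ht) | is.na(mt) | ht <= 0 | mt <= 0
  if (all(bad)) stop(sprintf("no usable rows in %s", path), call. = FALSE)
  if (any(bad)) {
    warning(sprintf("%d row(s) with missing or nonpositive turnover rejected in %s",
                    sum(bad), path), call. = FALSE)
  }
  dc <- if ("disease_count" %in% names(df)) {
    suppressWarnings(as.numeric(df$disease_count))
  } else {
    rep(NA_real_, nrow(df))
  }
  n_na <- sum(is.na(dc[!bad]))
  if (n_na > 0) {
    warning(sprintf("%d missing disease_count value(s) treated as 0 in %s",
                    n_na, path), call. = FALSE)
    dc[is.na(dc)] <- 0
  }
  out <- data.frame(human_id = as.character(df$human_id[!bad]),
                    mouse_id = as.character(df$mouse_id[!bad]),
                    human_turnover = ht[!bad],
                    mouse_turnover = mt[!bad],
                    ratio = ht[!bad] / mt[!bad],
                    disease_count = as.integer(dc[!bad]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a PTM membership list (one gene id per line)
#'
#' @param path Plain-text file; lines starting with "#" are comments.
#' @return Character vector of gene ids (unique, order preserved).
#' @export
read_ptm_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Write an analysis report as JSON
#'
#' @param results A list of results (coerced via jsonlite).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
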