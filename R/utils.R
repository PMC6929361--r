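# Internal helpers: seeded evaluation, seed derivation, TSV I/O, input checks.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' disturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a deterministic sub-seed for a named stage
#'
#' A single top-level seed spawns independent per-stage seeds so that stage
#' order cannot change results.  Result is kept inside the 32-bit integer
#' range.
#' @noRd
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483629 + 1)
}

#' Stop with a located, stage-tagged error
#' @noRd
stop_located <- function(stage, ..., call. = FALSE) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = call.)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Write a data frame as a commented TSV
#'
#' UTF-8, tab separated, "." decimal separator, header line, optional leading
#' "#" comment lines (used to record the simulation seed).
#' @noRd
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by write_tsv (comment lines start with "#")
#' @noRd
read_tsv <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = colClasses,
                          na.strings = c("NA", ""))
  if (nrow(df) == 0L) stop("no usable rows in ", path, call. = FALSE)
  df
}

#' Check that required columns are present
#' @noRd
require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("format error in %s: missing required column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Split a vector into consecutive chunks of a fixed size
#'
#' Returns a list of index vectors; the last chunk may be partial.
#' @noRd
chunk_indices <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' Recursively drop S3 classes so a config echoes cleanly into JSON
#' @noRd
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Sample variance with the n-1 denominator; 0 for a single observation
#' @noRd
sample_var <- function(x) {
  if (length(x) < 2L) return(0)
  stats::var(x)
}
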