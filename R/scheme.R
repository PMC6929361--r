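#' Taxonomic age-group scheme
#'
#' Defines the ordered taxonomic age classes used to stratify genes and the
#' mapping from taxonomic branch labels (as emitted by gene-age resources such
#' as ProteinHistorian) to those classes.  The default scheme uses five
#' classes ordered oldest to youngest: genes already present in unicellular
#' organisms (`u_org`), unicellular eukaryotes (`u_euk`),
#' Ophistokonta/Bilateria/Deuterostomia (`OBD`), chordates (`chor`) and
#' mammals (`mamm`).  Age rank is assigned so that the oldest class receives
#' the largest rank (5 for the default scheme) and the youngest rank 1;
#' a larger age value therefore always means an older gene.
#'
#' @param groups Character vector of group labels ordered oldest to youngest.
#' @param branch_to_group Named character vector mapping each taxonomic branch
#'   label to one group label.  Every value must be an element of `groups`.
#' @param min_group_size Minimum group size used when merging small groups
#'   (default 10).
#'
#' @return An object of class `age_group_scheme`: a list with elements
#'   `groups`, `branch_to_group`, `min_group_size` and `ranks` (named integer
#'   vector, oldest group = largest rank).
#'
#' @examples
#' sch <- age_group_scheme()
#' sch$ranks[["u_org"]]   # 5: oldest class
#' age_rank_of(c("Eukaryota", "Mammalia"), sch)
#' @export
age_group_scheme <- function(groups = c("u_org", "u_euk", "OBD", "chor", "mamm"),
                             branch_to_group = default_branch_map(groups),
                             min_group_size = 10L) {
  if (!is.character(groups) || length(groups) < 2L || anyDuplicated(groups)) {
    stop("groups must be >= 2 unique labels ordered oldest to youngest",
         call. = FALSE)
  }
  if (length(branch_to_group)) {
    if (is.null(names(branch_to_group)) || any(!nzchar(names(branch_to_group)))) {
      stop("branch_to_group must be a named character vector", call. = FALSE)
    }
    bad <- setdiff(unique(branch_to_group), groups)
    if (length(bad)) {
      stop("branch_to_group maps to unknown group(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is_count(min_group_size)) stop("min_group_size must be a positive integer",
                                      call. = FALSE)
  ranks <- stats::setNames(rev(seq_along(groups)), groups)
  structure(list(groups = groups,
                 branch_to_group = branch_to_group,
                 min_group_size = as.integer(min_group_size),
                 ranks = ranks),
            class = "age_group_scheme")
}

#' Default branch-label mapping for the five-class scheme
#'
#' Covers the coarse taxonomic labels typically found in gene-age tables.
#' Group labels themselves always map to themselves so that pre-grouped
#' tables round-trip.
#' @param groups Ordered group labels (oldest to youngest).
#' @return Named character vector branch label -> group label.
#' @export
default_branch_map <- function(groups = c("u_org", "u_euk", "OBD", "chor", "mamm")) {
  map <- c(
    Cellular_organisms = "u_org", Bacteria = "u_org", Archaea = "u_org",
    Prokaryota = "u_org",
    Eukaryota = "u_euk", Fungi = "u_euk",
    Opisthokonta = "OBD", Ophistokonta = "OBD", Metazoa = "OBD",
    Bilateria = "OBD", Deuterostomia = "OBD",
    Chordata = "chor", Vertebrata = "chor", Euteleostomi = "chor",
    Tetrapoda = "chor",
    Mammalia = "mamm", Eutheria = "mamm", Primates = "mamm"
  )
  map <- map[map %in% groups]
  c(map, stats::setNames(groups, groups))
}

#' @export
print.age_group_scheme <- function(x, ...) {
  cat("Age-group scheme (", length(x$groups), " classes, oldest -> youngest)\n",
      sep = "")
  cat("  ", paste(sprintf("%s (rank %d)", x$groups, x$ranks), collapse = " > "),
      "\n", sep = "")
  cat("  mapped branch labels: ", length(x$branch_to_group),
      "; min group size: ", x$min_group_size, "\n", sep = "")
  invisible(x)
}

#' Age rank of taxonomic branch labels under a scheme
#'
#' @param branch Character vector of branch labels.
#' @param scheme An [age_group_scheme()].
#' @return Integer vector of age ranks (`NA` for unmapped labels).
#' @export
age_rank_of <- function(branch, scheme = age_group_scheme()) {
  stopifnot(inherits(scheme, "age_group_scheme"))
  grp <- unname(scheme$branch_to_group[branch])
  out <- unname(scheme$ranks[grp])
  as.integer(out)
}

#' Read an age-group scheme from a two-column TSV
#'
#' The file must contain columns `branch` and `group`; groups are ordered
#' oldest to youngest by first appearance unless `groups` is given.
#'
#' @param path Path to a TSV file with columns `branch`, `group`.
#' @param groups Optional explicit group order (oldest to youngest).
#' @param min_group_size Passed to [age_group_scheme()].
#' @return An [age_group_scheme()].
#' @export
read_age_group_scheme <- function(path, groups = NULL, min_group_size = 10L) {
  df <- read_tsv(path)
  require_columns(df, c("branch", "group"), path)
  if (is.null(groups)) groups <- unique(df$group)
  age_group_scheme(groups = groups,
                   branch_to_group = stats::setNames(df$group, df$branch),
                   min_group_size = min_group_size)
}
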