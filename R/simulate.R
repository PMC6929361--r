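# Synthetic-data generator: emulates the six input tables of the gene-age
# analysis with planted, configurable age-dependent structure.  All draws are
# deterministic given the configuration seed; each table uses an independent
# sub-stream derived from that seed.

#' Attribute generative model
#'
#' Linear-in-age-rank mean with group-heteroscedastic Gaussian noise:
#' `value = baseline + age_slope * age_rank + Normal(0, noise_sd_by_group[g])`.
#' Per-group noise standard deviations are ordered oldest to youngest, which
#' allows planting the empirical pattern that attribute variance shrinks with
#' gene age.
#'
#' @param baseline Intercept of the linear age model.
#' @param age_slope Change in the attribute mean per unit of age rank
#'   (rank 5 = oldest class under the default scheme).
#' @param noise_sd_by_group Positive noise SDs, one per age group, ordered
#'   oldest to youngest.
#' @param constraint `"none"`, `"positive"` (values floored at a small
#'   positive constant, used for turnover, half-lives and abundance) or
#'   `"unit"` (values clamped to \[0, 1\], used for disorder and conservation
#'   fractions).
#' @return A list of class `attribute_model`.
#' @export
attribute_model <- function(baseline, age_slope, noise_sd_by_group,
                            constraint = c("none", "positive", "unit")) {
  constraint <- match.arg(constraint)
  if (!is_number(baseline) || !is_number(age_slope)) {
    stop("baseline and age_slope must be finite numbers", call. = FALSE)
  }
  if (!is.numeric(noise_sd_by_group) || any(!is.finite(noise_sd_by_group)) ||
      any(noise_sd_by_group < 0)) {
    stop("noise_sd_by_group must be nonnegative finite numbers", call. = FALSE)
  }
  structure(list(baseline = baseline, age_slope = age_slope,
                 noise_sd_by_group = noise_sd_by_group,
                 constraint = constraint),
            class = "attribute_model")
}

#' Default attribute models
#'
#' Five attributes with planted age trends whose magnitudes emulate the
#' published correlations: protein turnover (Spearman vs. age about -0.20 at
#' the default group proportions; slope calibrated by Monte Carlo), mRNA
#' half-life (about +0.23), disorder fraction (about -0.18), conservation
#' score (about +0.67) and abundance (about +0.12).  Turnover noise SDs
#' decrease from youngest to oldest group, planting the observed decrease of
#' group variance with age.
#' @return Named list of [attribute_model()] objects.
#' @export
default_attribute_models <- function() {
  list(
    turnover = attribute_model(2.6, -0.113, c(0.35, 0.45, 0.55, 0.70, 0.90),
                               constraint = "positive"),
    mrna_half_life = attribute_model(3.0, 0.65, rep(2.6, 5),
                                     constraint = "positive"),
    disorder = attribute_model(0.60, -0.030, rep(0.16, 5),
                               constraint = "unit"),
    conservation = attribute_model(0.45, 0.075, rep(0.08, 5),
                                   constraint = "unit"),
    abundance = attribute_model(4.0, 0.37, rep(3.0, 5),
                                constraint = "positive")
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  Defaults emulate
#' the published study conditions: 3853 genes with the five-group proportions
#' of the human turnover analysis (904, 1745, 749, 378, 77), a turnover model
#' calibrated to a population age correlation of -0.20, peptide counts of
#' 3-30 with a turnover-dependent coefficient of variation, GO categories
#' with sizes spanning 50-556 members, 2107 ortholog pairs with a
#' mouse/human turnover factor of 0.91 and lognormal ratio noise 0.15, a
#' two-regime Poisson disease model concentrated in extreme ratio quantiles,
#' and PTM membership probabilities planting an old-biased acetylation and a
#' young-biased phosphorylation (2:1 acetylation:phosphorylation share in the
#' oldest group).
#'
#' @param n_genes Number of genes to simulate.
#' @param group_proportions Five nonnegative weights summing to 1, ordered
#'   oldest to youngest group.
#' @param attribute_models Named list of [attribute_model()] objects.
#' @param peptide_model List with `min_peptides`, `max_peptides`,
#'   `cv_intercept`, `cv_slope`: per-protein peptide counts are uniform on
#'   `[min_peptides, max_peptides]` and peptide values are
#'   `Normal(turnover, cv * turnover)` with
#'   `cv = cv_intercept + cv_slope * turnover`, truncated at 0 by resampling.
#' @param go_model List with `n_categories`, `category_size_range` (length-2
#'   integer), `planted_shift_by_category` (numeric, recycled to
#'   `n_categories`; shift 0 = null category drawn uniformly).
#' @param homolog_model List with `n_pairs`, `species_factor`,
#'   `ratio_noise_sd`, `disease_base_rate`, `disease_extreme_rate`,
#'   `extreme_quantile`.
#' @param ptm_model List with `p_meth_by_group`, `p_acet_by_group`,
#'   `p_phos_by_group`: per-group Bernoulli membership probabilities,
#'   ordered oldest to youngest.
#' @param seed Integer seed; all generators are deterministic given the
#'   configuration (including the seed).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 3853L,
                              group_proportions = c(904, 1745, 749, 378, 77) / 3853,
                              attribute_models = default_attribute_models(),
                              peptide_model = list(min_peptides = 3L,
                                                   max_peptides = 30L,
                                                   cv_intercept = 0.02,
                                                   cv_slope = 0.04),
                              go_model = list(n_categories = 30L,
                                              category_size_range = c(50L, 556L),
                                              planted_shift_by_category = 0),
                              homolog_model = list(n_pairs = 2107L,
                                                   species_factor = 0.91,
                                                   ratio_noise_sd = 0.15,
                                                   disease_base_rate = 0.05,
                                                   disease_extreme_rate = 0.6,
                                                   extreme_quantile = 0.05),
                              ptm_model = list(
                                p_meth_by_group = c(0.030, 0.024, 0.018, 0.014, 0.010),
                                p_acet_by_group = c(0.24, 0.18, 0.14, 0.10, 0.08),
                                p_phos_by_group = c(0.12, 0.18, 0.24, 0.30, 0.36)),
                              seed = 1L) {
  cfg <- structure(list(n_genes = n_genes,
                        group_proportions = group_proportions,
                        attribute_models = attribute_models,
                        peptide_model = peptide_model,
                        go_model = go_model,
                        homolog_model = homolog_model,
                        ptm_model = ptm_model,
                        seed = seed),
                   class = "simulation_config")
  errs <- validate_simulation_config(cfg)
  if (length(errs)) {
    stop("invalid simulation configuration:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  cfg$go_model$planted_shift_by_category <-
    rep_len(cfg$go_model$planted_shift_by_category, cfg$go_model$n_categories)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `simulation_config` (or plain list with the same fields).
#' @return Character vector of violations, each naming the offending field;
#'   empty when the configuration is valid.
#' @export
validate_simulation_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (!is_count(config$n_genes)) add("n_genes: must be a positive integer")
  p <- config$group_proportions
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    add("group_proportions: must be nonnegative finite weights")
  } else if (abs(sum(p) - 1) > 1e-9) {
    add("group_proportions: must sum to 1 (+/- 1e-9)")
  }
  am <- config$attribute_models
  if (!is.list(am) || is.null(names(am)) || any(!nzchar(names(am)))) {
    add("attribute_models: must be a named list")
  } else {
    for (nm in names(am)) {
      m <- am[[nm]]
      if (!inherits(m, "attribute_model")) {
        add(sprintf("attribute_models.%s: not an attribute_model", nm))
      } else if (is.numeric(p) && length(m$noise_sd_by_group) != length(p)) {
        add(sprintf("attribute_models.%s.noise_sd_by_group: needs one SD per group",
                    nm))
      }
    }
  }
  pm <- config$peptide_model
  if (!is_count(pm$min_peptides)) add("peptide_model.min_peptides: positive integer required")
  if (!is_count(pm$max_peptides) || pm$max_peptides < pm$min_peptides) {
    add("peptide_model.max_peptides: integer >= min_peptides required")
  }
  if (!is_number(pm$cv_intercept) || pm$cv_intercept < 0) {
    add("peptide_model.cv_intercept: nonnegative number required")
  }
  if (!is_number(pm$cv_slope)) add("peptide_model.cv_slope: finite number required")
  gm <- config$go_model
  if (!is_count(gm$n_categories)) add("go_model.n_categories: positive integer required")
  sr <- gm$category_size_range
  if (!is.numeric(sr) || length(sr) != 2L || any(sr < 2) || sr[2] < sr[1]) {
    add("go_model.category_size_range: increasing integer pair >= 2 required")
  } else if (is_count(config$n_genes) && sr[2] > config$n_genes) {
    add("go_model.category_size_range: category size exceeds n_genes")
  }
  if (!is.numeric(gm$planted_shift_by_category) ||
      any(!is.finite(gm$planted_shift_by_category))) {
    add("go_model.planted_shift_by_category: finite numerics required")
  }
  hm <- config$homolog_model
  if (!is_count(hm$n_pairs)) add("homolog_model.n_pairs: positive integer required")
  else if (is_count(config$n_genes) && hm$n_pairs > config$n_genes) {
    add("homolog_model.n_pairs: cannot exceed n_genes")
  }
  if (!is_number(hm$species_factor) || hm$species_factor <= 0) {
    add("homolog_model.species_factor: positive number required")
  }
  if (!is_number(hm$ratio_noise_sd) || hm$ratio_noise_sd < 0) {
    add("homolog_model.ratio_noise_sd: nonnegative number required")
  }
  if (!is_number(hm$disease_base_rate) || hm$disease_base_rate < 0) {
    add("homolog_model.disease_base_rate: nonnegative number required")
  }
  if (!is_number(hm$disease_extreme_rate) || hm$disease_extreme_rate < 0) {
    add("homolog_model.disease_extreme_rate: nonnegative number required")
  }
  if (!is_number(hm$extreme_quantile) || hm$extreme_quantile <= 0 ||
      hm$extreme_quantile >= 0.5) {
    add("homolog_model.extreme_quantile: must lie in (0, 0.5)")
  }
  tm <- config$ptm_model
  for (nm in c("p_meth_by_group", "p_acet_by_group", "p_phos_by_group")) {
    v <- tm[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1) ||
        (is.numeric(p) && length(v) != length(p))) {
      add(sprintf("ptm_model.%s: one probability per group required", nm))
    }
  }
  if (!is_count(config$seed, min = 0L)) add("seed: nonnegative integer required")
  errs
}

# Representative numeric ages (arbitrary units, oldest first) for G groups.
representative_ages <- function(G) round(seq(3500, 100, length.out = G))

#' Generate the synthetic gene table
#'
#' Draws each gene's age group from the configured proportions and each
#' configured attribute from its linear-in-rank model with group-specific
#' Gaussian noise.  Positive-valued attributes are floored at 0.05; unit
#' attributes are clamped to \[0, 1\].
#'
#' @param config A [simulation_config()].
#' @param scheme An [age_group_scheme()] supplying the ordered group labels.
#' @return A data frame with columns `gene_id`, `species`, `age_branch`,
#'   `age_group`, `age_rank` (largest = oldest), `age_numeric` and one column
#'   per configured attribute.
#' @export
generate_gene_table <- function(config, scheme = age_group_scheme()) {
  stopifnot(inherits(config, "simulation_config"))
  G <- length(config$group_proportions)
  if (length(scheme$groups) != G) {
    stop("configuration error: scheme defines ", length(scheme$groups),
         " groups but group_proportions has ", G, call. = FALSE)
  }
  n <- config$n_genes
  ages <- representative_ages(G)
  with_seed(derive_seed(config$seed, "genes"), {
    gidx <- sample.int(G, n, replace = TRUE, prob = config$group_proportions)
    rank <- G + 1L - gidx
    df <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                     species = "human",
                     age_branch = scheme$groups[gidx],
                     age_group = scheme$groups[gidx],
                     age_rank = rank,
                     age_numeric = ages[gidx],
                     stringsAsFactors = FALSE)
    for (nm in names(config$attribute_models)) {
      m <- config$attribute_models[[nm]]
      v <- m$baseline + m$age_slope * rank +
        stats::rnorm(n, 0, m$noise_sd_by_group[gidx])
      v <- switch(m$constraint,
                  none = v,
                  positive = pmax(v, 0.05),
                  unit = pmin(pmax(v, 0), 1))
      df[[nm]] <- v
    }
    df
  })
}

#' Generate per-peptide turnover measurements
#'
#' For each protein, draws a uniform peptide count and peptide turnover
#' values from `Normal(turnover, cv * turnover)` with
#' `cv = cv_intercept + cv_slope * turnover`; nonpositive draws are resampled
#' (turnover ratios are positive).
#'
#' @param genes Gene table from [generate_gene_table()]; must carry a
#'   `turnover` column.
#' @param config A [simulation_config()].
#' @return Data frame with columns `protein_id`, `peptide_ratio`.
#' @export
generate_peptides <- function(genes, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!"turnover" %in% names(genes)) {
    stop("genes must carry turnover values", call. = FALSE)
  }
  pm <- config$peptide_model
  kvals <- seq.int(pm$min_peptides, pm$max_peptides)
  with_seed(derive_seed(config$seed, "peptides"), {
    k <- kvals[sample.int(length(kvals), nrow(genes), replace = TRUE)]
    prot <- rep(genes$gene_id, k)
    t <- rep(genes$turnover, k)
    sdv <- (pm$cv_intercept + pm$cv_slope * t) * t
    x <- stats::rnorm(length(t), t, sdv)
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), t[bad], sdv[bad])
      bad <- bad[x[bad] <= 0]
    }
    data.frame(protein_id = prot, peptide_ratio = x, stringsAsFactors = FALSE)
  })
}

#' Generate synthetic GO annotations with planted turnover shifts
#'
#' Category sizes are uniform on the configured range; members are drawn
#' without replacement with exponentially tilted weights
#' `exp(shift * (turnover - mean) / var)`, which for an approximately
#' Gaussian turnover pool shifts the expected category mean by about `shift`.
#' A shift of 0 yields a null category sampled uniformly.  Genes may belong
#' to several categories.
#'
#' @param genes Gene table carrying `turnover`.
#' @param config A [simulation_config()].
#' @return Long-format data frame with columns `category_id`, `name`,
#'   `gene_id` (one row per membership).
#' @export
generate_go_annotations <- function(genes, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!"turnover" %in% names(genes)) {
    stop("genes must carry turnover values", call. = FALSE)
  }
  gm <- config$go_model
  if (max(gm$category_size_range) > nrow(genes)) {
    stop("configuration error: category size exceeds number of genes",
         call. = FALSE)
  }
  shifts <- rep_len(gm$planted_shift_by_category, gm$n_categories)
  t <- genes$turnover
  mu <- mean(t)
  v <- stats::var(t)
  sizes_range <- seq.int(gm$category_size_range[1], gm$category_size_range[2])
  with_seed(derive_seed(config$seed, "go"), {
    sizes <- sizes_range[sample.int(length(sizes_range), gm$n_categories,
                                    replace = TRUE)]
    out <- vector("list", gm$n_categories)
    for (i in seq_len(gm$n_categories)) {
      w <- if (shifts[i] == 0) NULL else exp(shifts[i] * (t - mu) / v)
      members <- genes$gene_id[sample.int(nrow(genes), sizes[i],
                                          replace = FALSE, prob = w)]
      out[[i]] <- data.frame(category_id = sprintf("GO:%07d", i),
                             name = sprintf("synthetic_category_%03d", i),
                             gene_id = members, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate cross-species ortholog pairs
#'
#' Samples genes without replacement; mouse turnover is
#' `human * species_factor * exp(Normal(0, ratio_noise_sd))`.  Disease counts
#' are Poisson with the base rate, replaced by the extreme rate for pairs
#' whose log-ratio falls outside the central
#' `1 - 2 * extreme_quantile` empirical quantile band.
#'
#' @param genes Gene table carrying `turnover`.
#' @param config A [simulation_config()].
#' @return Data frame with columns `human_id`, `mouse_id`, `human_turnover`,
#'   `mouse_turnover`, `ratio` (human/mouse), `disease_count`.
#' @export
generate_homolog_pairs <- function(genes, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!"turnover" %in% names(genes)) {
    stop("genes must carry turnover values", call. = FALSE)
  }
  hm <- config$homolog_model
  if (hm$n_pairs > nrow(genes)) {
    stop("configuration error: n_pairs exceeds number of genes", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "homologs"), {
    idx <- sample.int(nrow(genes), hm$n_pairs, replace = FALSE)
    human <- genes$turnover[idx]
    mouse <- human * hm$species_factor *
      exp(stats::rnorm(hm$n_pairs, 0, hm$ratio_noise_sd))
    ratio <- human / mouse
    lr <- log(ratio)
    band <- stats::quantile(lr, c(hm$extreme_quantile, 1 - hm$extreme_quantile),
                            names = FALSE)
    extreme <- lr < band[1] | lr > band[2]
    disease <- stats::rpois(hm$n_pairs, hm$disease_base_rate)
    if (any(extreme)) {
      disease[extreme] <- stats::rpois(sum(extreme), hm$disease_extreme_rate)
    }
    data.frame(human_id = genes$gene_id[idx],
               mouse_id = sub("^g", "m", genes$gene_id[idx]),
               human_turnover = human,
               mouse_turnover = mouse,
               ratio = ratio,
               disease_count = disease,
               stringsAsFactors = FALSE)
  })
}

#' Generate PTM membership sets
#'
#' Assigns each gene to the methylated / acetylated / phosphorylated sets by
#' independent Bernoulli draws with group-specific probabilities.  Overlaps
#' are allowed; exclusivity is enforced downstream by
#' [exclusive_ptm_assignment()].
#'
#' @param genes Gene table with `age_rank`.
#' @param config A [simulation_config()].
#' @return List with character vectors `methylated`, `acetylated`,
#'   `phosphorylated`.
#' @export
generate_ptm_labels <- function(genes, config) {
  stopifnot(inherits(config, "simulation_config"))
  G <- length(config$group_proportions)
  gidx <- G + 1L - genes$age_rank
  tm <- config$ptm_model
  with_seed(derive_seed(config$seed, "ptm"), {
    draw <- function(p_by_group) {
      genes$gene_id[stats::runif(nrow(genes)) < p_by_group[gidx]]
    }
    list(methylated = draw(tm$p_meth_by_group),
         acetylated = draw(tm$p_acet_by_group),
         phosphorylated = draw(tm$p_phos_by_group))
  })
}

#' Simulate a complete input dataset and write it to disk
#'
#' Generates the gene/age table, one attribute table per configured
#' attribute, the peptide table, GO annotations, ortholog pairs and the
#' three PTM membership lists, and writes them as TSV/plain-text files with
#' the seed recorded in a header comment.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @param scheme An [age_group_scheme()].
#' @return Invisibly, a list with the generated objects (`genes`, `peptides`,
#'   `go`, `homologs`, `ptm`) and a named vector `paths` of written files.
#' @export
simulate_dataset <- function(config, dir, scheme = age_group_scheme()) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- generate_gene_table(config, scheme)
  peptides <- generate_peptides(genes, config)
  go <- generate_go_annotations(genes, config)
  homologs <- generate_homolog_pairs(genes, config)
  ptm <- generate_ptm_labels(genes, config)
  note <- sprintf("seed: %d", config$seed)

  paths <- c(gene_age = file.path(dir, "gene_age.tsv"))
  write_tsv(genes[, c("gene_id", "age_branch", "age_numeric")],
            paths[["gene_age"]], comments = note)
  for (nm in names(config$attribute_models)) {
    p <- file.path(dir, sprintf("attribute_%s.tsv", nm))
    paths[[paste0("attribute_", nm)]] <- p
    write_tsv(data.frame(gene_id = genes$gene_id, value = genes[[nm]]),
              p, comments = note)
  }
  paths[["peptides"]] <- file.path(dir, "peptides.tsv")
  write_tsv(peptides, paths[["peptides"]], comments = note)
  paths[["go"]] <- file.path(dir, "go.tsv")
  write_tsv(go, paths[["go"]], comments = note)
  paths[["homologs"]] <- file.path(dir, "homologs.tsv")
  write_tsv(homologs[, c("human_id", "mouse_id", "human_turnover",
                         "mouse_turnover", "disease_count")],
            paths[["homologs"]], comments = note)
  for (cls in names(ptm)) {
    p <- file.path(dir, sprintf("ptm_%s.txt", cls))
    paths[[paste0("ptm_", cls)]] <- p
    writeLines(c(paste0("# ", note), ptm[[cls]]), p)
  }
  invisible(list(genes = genes, peptides = peptides, go = go,
                 homologs = homologs, ptm = ptm, paths = paths))
}
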