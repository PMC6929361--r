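# End-to-end pipeline: simulate (or read) the six input tables, run every
# analysis stage in dependency order, and write a reproducible report
# bundle.  A single top-level seed deterministically derives per-stage
# sub-seeds, so stage order cannot change results.

#' Pipeline run configuration
#'
#' Collects every stage parameter with the published defaults: minimum age
#' group size 10, minimum peptides per protein 3, peptide variance bin 93,
#' 1000 bootstrap iterations, disease ratio bin 30, turnover-decrease bin
#' 210, minimum GO category size 50.
#'
#' @param simulation A [simulation_config()] used to generate inputs, or
#'   `NULL` when `inputs` is given.
#' @param inputs `NULL`, or a list of file paths: `gene_age`, `attributes`
#'   (named list of attribute TSVs), `peptides`, `go`, `homologs`, `ptm`
#'   (list with `methylated`, `acetylated`, `phosphorylated`).  Missing
#'   elements skip the corresponding stage.
#' @param output_dir Directory for the report bundle.
#' @param seed Top-level integer seed; per-stage sub-seeds (simulation,
#'   bootstrap) are derived from it.
#' @param min_group_size,min_peptides,peptide_bin_size,bootstrap_iterations,disease_bin_size,decrease_bin_size,go_min_size
#'   Stage parameters (see the corresponding stage functions).
#' @param group_statistic Central statistic for group summaries
#'   (`"median"`/`"mean"`).
#' @param category_statistic Category statistic for GO ranking
#'   (`"mean"`/`"median"`).
#' @param group_test `"anova"` or `"kruskal"`.
#' @param scheme An [age_group_scheme()].
#' @return List of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       inputs = NULL,
                       output_dir = tempfile("agestrat_run_"),
                       seed = 1L,
                       min_group_size = 10L,
                       min_peptides = 3L,
                       peptide_bin_size = 93L,
                       bootstrap_iterations = 1000L,
                       disease_bin_size = 30L,
                       decrease_bin_size = 210L,
                       go_min_size = 50L,
                       group_statistic = "median",
                       category_statistic = "mean",
                       group_test = "anova",
                       scheme = age_group_scheme()) {
  structure(list(simulation = simulation, inputs = inputs,
                 output_dir = output_dir, seed = seed,
                 min_group_size = min_group_size,
                 min_peptides = min_peptides,
                 peptide_bin_size = peptide_bin_size,
                 bootstrap_iterations = bootstrap_iterations,
                 disease_bin_size = disease_bin_size,
                 decrease_bin_size = decrease_bin_size,
                 go_min_size = go_min_size,
                 group_statistic = group_statistic,
                 category_statistic = category_statistic,
                 group_test = group_test,
                 scheme = scheme),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Every violation is reported with the field path of the offending
#' parameter; an invalid configuration never starts a partial run.
#'
#' @param config A [run_config()].
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$simulation) && is.null(config$inputs)) {
    add("inputs: either a simulation config or input paths are required")
  }
  if (!is.null(config$simulation)) {
    if (!inherits(config$simulation, "simulation_config")) {
      add("simulation: not a simulation_config")
    } else {
      sim_errs <- validate_simulation_config(config$simulation)
      if (length(sim_errs)) errs <- c(errs, paste0("simulation.", sim_errs))
    }
  }
  if (!is_count(config$seed, min = 0L)) add("seed: nonnegative integer required")
  if (!is_count(config$min_group_size)) {
    add("age_attributes.min_group_size: positive integer required")
  }
  if (!is_count(config$min_peptides)) {
    add("peptide_variance.min_peptides: positive integer required")
  }
  if (!is_count(config$peptide_bin_size, min = 2L)) {
    add("peptide_variance.bin_size: integer >= 2 required")
  }
  if (!is_count(config$bootstrap_iterations)) {
    add("go_ranking.iterations: positive integer required")
  }
  if (!is_count(config$disease_bin_size, min = 2L)) {
    add("interspecies.disease_bin_size: integer >= 2 required")
  }
  if (!is_count(config$decrease_bin_size, min = 2L)) {
    add("interspecies.decrease_bin_size: integer >= 2 required")
  }
  if (!is_count(config$go_min_size)) {
    add("go_ranking.min_size: positive integer required")
  }
  if (!config$group_statistic %in% c("median", "mean")) {
    add("age_attributes.statistic: must be median or mean")
  }
  if (!config$category_statistic %in% c("mean", "median")) {
    add("go_ranking.statistic: must be mean or median")
  }
  if (!config$group_test %in% c("anova", "kruskal")) {
    add("age_attributes.test: must be anova or kruskal")
  }
  if (!inherits(config$scheme, "age_group_scheme")) {
    add("scheme: not an age_group_scheme")
  }
  errs
}

#' Run the complete analysis pipeline
#'
#' Simulates (or reads) the input tables, then runs the age-attribute,
#' transcription-rate, peptide-variance, GO-ranking, ortholog and PTM stages
#' in dependency order.  Outputs are staged in a temporary directory and
#' moved into `output_dir` only on success, so a failed run never leaves a
#' partial bundle.  Rerunning with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return An object of class `agestrat_report`: list with `summary`
#'   (machine-readable stage results), `files` (written file paths),
#'   `output_dir` and `config`.
#' @export
run_full_analysis <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  scheme <- config$scheme
  scheme$min_group_size <- as.integer(config$min_group_size)
  stage_dir <- tempfile("agestrat_stage_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)

  # ---- inputs ----------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_dataset(sim_cfg, file.path(stage_dir, "inputs"), scheme)
    paths <- sim$paths
    inputs <- list(
      gene_age = paths[["gene_age"]],
      attributes = stats::setNames(
        as.list(paths[grep("^attribute_", names(paths))]),
        sub("^attribute_", "", grep("^attribute_", names(paths), value = TRUE))),
      peptides = paths[["peptides"]],
      go = paths[["go"]],
      homologs = paths[["homologs"]],
      ptm = list(methylated = paths[["ptm_methylated"]],
                 acetylated = paths[["ptm_acetylated"]],
                 phosphorylated = paths[["ptm_phosphorylated"]]))
  } else {
    inputs <- config$inputs
  }

  summary <- list()
  skipped <- character()
  files <- character()
  emit <- function(df, name) {
    p <- file.path(stage_dir, name)
    write_tsv(df, p)
    files <<- c(files, name)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  gene_age <- run_stage("read_inputs",
                        read_gene_age_table(inputs$gene_age, scheme))
  attributes <- list()
  for (nm in names(inputs$attributes)) {
    attributes[[nm]] <- run_stage("read_inputs",
                                  read_attribute_table(inputs$attributes[[nm]], nm))
  }

  # ---- age-attribute stage --------------------------------------------
  if (length(attributes)) {
    sums <- list(); pws <- list(); cors <- list()
    for (nm in names(attributes)) {
      an <- run_stage("age_attributes",
                      age_attribute_analysis(gene_age, attributes[[nm]],
                                             scheme,
                                             statistic = config$group_statistic,
                                             test = config$group_test))
      s <- an$summaries; s <- cbind(attribute = nm, s)
      pw <- an$test$pairwise; pw <- cbind(attribute = nm, pw)
      sums[[nm]] <- s; pws[[nm]] <- pw
      cors[[nm]] <- data.frame(attribute = nm, r = an$correlation$r,
                               p = an$correlation$p, n = an$correlation$n,
                               anova_p = an$test$p,
                               stringsAsFactors = FALSE)
      summary$age_attributes[[nm]] <- list(
        spearman_r = an$correlation$r, spearman_p = an$correlation$p,
        n = an$n, anova_p = an$test$p,
        group_central = stats::setNames(as.list(an$summaries$central_value),
                                        an$summaries$group),
        group_variance = stats::setNames(as.list(an$summaries$variance),
                                         an$summaries$group))
    }
    emit(do.call(rbind, sums), "group_summaries.tsv")
    emit(do.call(rbind, pws), "pairwise_tests.tsv")
    emit(do.call(rbind, cors), "correlations.tsv")
  } else {
    skipped <- c(skipped, "age_attributes (no attribute tables)")
  }

  # ---- transcription-rate stage ---------------------------------------
  if ("mrna_half_life" %in% names(attributes)) {
    tr <- run_stage("transcription_rates",
                    derive_transcription_rates(attributes$mrna_half_life))
    summary$transcription_rates <- list(mode = tr$mode,
                                        n = length(tr$rates),
                                        n_rejected = tr$n_rejected)
    if ("conservation" %in% names(attributes)) {
      cons <- attributes$conservation
      shared <- intersect(names(tr$rates), names(cons))
      cc <- run_stage("transcription_rates",
                      spearman_rank_correlation(cons[shared], tr$rates[shared]))
      summary$transcription_rates$conservation_spearman_r <- cc$r
      summary$transcription_rates$conservation_spearman_p <- cc$p
    }
  } else {
    skipped <- c(skipped, "transcription_rates (no mRNA half-life table)")
  }

  # ---- peptide-variance stage -----------------------------------------
  if (!is.null(inputs$peptides)) {
    pep <- run_stage("peptide_variance", read_peptide_table(inputs$peptides))
    ps <- run_stage("peptide_variance",
                    protein_peptide_stats(pep, config$min_peptides))
    vb <- run_stage("peptide_variance",
                    bin_by_turnover(ps, config$peptide_bin_size))
    emit(as.data.frame(ps), "protein_stats.tsv")
    emit(vb, "variance_bins.tsv")
    summary$peptide_variance <- list(
      n_proteins = nrow(ps), n_dropped = attr(ps, "n_dropped"),
      n_bins = nrow(vb),
      first_bin_value = vb$bin_value[1],
      last_full_bin_value = vb$bin_value[max(which(!vb$partial))])
  } else {
    skipped <- c(skipped, "peptide_variance (no peptide table)")
  }

  # ---- GO-ranking stage ------------------------------------------------
  turnover <- attributes[["turnover"]]
  if (!is.null(inputs$go) && !is.null(turnover)) {
    go <- run_stage("go_ranking", read_go_annotations(inputs$go))
    ranked <- run_stage("go_ranking",
                        rank_categories(go, turnover,
                                        statistic = config$category_statistic,
                                        n_iter = config$bootstrap_iterations,
                                        min_size = config$go_min_size,
                                        seed = derive_seed(config$seed,
                                                           "go_rank")))
    emit(as.data.frame(ranked), "ranked_categories.tsv")
    summary$go_ranking <- list(
      n_categories = nrow(ranked),
      n_significant = sum(ranked$p < 0.05),
      lowest = ranked$category_id[1],
      highest = ranked$category_id[nrow(ranked)])
  } else {
    skipped <- c(skipped, "go_ranking (no GO table or no turnover)")
  }

  # ---- interspecies stage ---------------------------------------------
  if (!is.null(inputs$homologs)) {
    hom <- run_stage("interspecies", read_homolog_table(inputs$homologs))
    pc <- run_stage("interspecies", pair_turnover_comparison(hom))
    db <- run_stage("interspecies",
                    disease_ratio_bins(hom, config$disease_bin_size))
    fb <- run_stage("interspecies",
                    turnover_decrease_fraction_bins(hom,
                                                    config$decrease_bin_size))
    emit(db, "disease_bins.tsv")
    emit(fb, "decrease_bins.tsv")
    summary$interspecies <- list(
      n_pairs = pc$n, mean_human = pc$mean_human, mean_mouse = pc$mean_mouse,
      mean_ratio = pc$mean_ratio,
      fraction_human_higher = pc$fraction_human_higher,
      mann_whitney_p = pc$mann_whitney_p,
      total_diseases = sum(db$disease_sum))
  } else {
    skipped <- c(skipped, "interspecies (no homolog table)")
  }

  # ---- PTM stage -------------------------------------------------------
  if (!is.null(inputs$ptm) && !is.null(turnover)) {
    sets <- run_stage("ptm", lapply(inputs$ptm, read_ptm_list))
    assign <- run_stage("ptm",
                        exclusive_ptm_assignment(sets$methylated,
                                                 sets$acetylated,
                                                 sets$phosphorylated,
                                                 names(turnover)))
    cls_counts <- table(assign$ptm_class)
    pt <- run_stage("ptm", ptm_turnover_comparison(assign, turnover))
    pf <- run_stage("ptm", ptm_age_fractions(assign, gene_age, scheme))
    emit(pf$within_group, "ptm_fractions_within_group.tsv")
    emit(pf$across_group, "ptm_fractions_across_group.tsv")
    emit(pt$medians, "ptm_turnover.tsv")
    summary$ptm <- list(
      exclusive_counts = as.list(cls_counts),
      class_medians = stats::setNames(as.list(pt$medians$median_turnover),
                                      pt$medians$class),
      acet_vs_phos_age_p = pf$mann_whitney$p)
  } else {
    skipped <- c(skipped, "ptm (no PTM lists or no turnover)")
  }

  summary$skipped_stages <- skipped
  provenance <- list(seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("agestrat")),
                     parameters = list(
                       min_group_size = config$min_group_size,
                       min_peptides = config$min_peptides,
                       peptide_bin_size = config$peptide_bin_size,
                       bootstrap_iterations = config$bootstrap_iterations,
                       disease_bin_size = config$disease_bin_size,
                       decrease_bin_size = config$decrease_bin_size,
                       go_min_size = config$go_min_size,
                       group_statistic = config$group_statistic,
                       category_statistic = config$category_statistic,
                       group_test = config$group_test),
                     simulated = !is.null(config$simulation),
                     simulation = strip_classes(config$simulation))
  write_report(list(summary = summary, provenance = provenance),
               file.path(stage_dir, "report.json"))
  files <- c(files, "report.json")

  # ---- publish atomically ---------------------------------------------
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in files) {
    file.copy(file.path(stage_dir, f), file.path(config$output_dir, f),
              overwrite = TRUE)
  }
  if (!is.null(config$simulation)) {
    inp_dir <- file.path(config$output_dir, "inputs")
    dir.create(inp_dir, showWarnings = FALSE)
    for (p in list.files(file.path(stage_dir, "inputs"), full.names = TRUE)) {
      file.copy(p, file.path(inp_dir, basename(p)), overwrite = TRUE)
    }
  }
  structure(list(summary = summary, files = files,
                 output_dir = config$output_dir, config = config),
            class = "agestrat_report")
}

#' @export
print.agestrat_report <- function(x, ...) {
  cat("agestrat report bundle:", x$output_dir, "\n")
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  if (!is.null(x$summary$age_attributes$turnover)) {
    tt <- x$summary$age_attributes$turnover
    cat(sprintf("  turnover vs age: Spearman r = %.3f (p = %.3g, n = %d)\n",
                tt$spearman_r, tt$spearman_p, tt$n))
  }
  if (!is.null(x$summary$interspecies)) {
    cat(sprintf("  orthologs: mean ratio = %.3f, fraction human > mouse = %.3f\n",
                x$summary$interspecies$mean_ratio,
                x$summary$interspecies$fraction_human_higher))
  }
  if (length(x$summary$skipped_stages)) {
    cat("  skipped:", paste(x$summary$skipped_stages, collapse = "; "), "\n")
  }
  invisible(x)
}
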