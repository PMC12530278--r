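#' Run the full threshold-analysis pipeline
#'
#' Chains every stage on one experiment (simulated by default): rarefaction,
#' Bray-Curtis dissimilarities, the sequential PERMANOVA partition
#' (treatment, loading, day) on water samples over all days, the binary
#' threshold scan at the first sampling day, NMDS with environmental vector
#' fitting, the environment-PC1 breakpoint analysis per day
#' (loading vs PC1 and PC1 vs NMDS1), community-weighted genome traits, and
#' differential pathways at the first and last day with the early/late
#' categorization.
#'
#' @param experiment A `mesocosm_experiment` (default: simulate one from
#'   `config`).
#' @param config An [experiment_config()] used when simulating.
#' @param run A [run_config()] of analysis parameters.
#' @param seed Seed for all stochastic stages (default `run$rng_seed`, or
#'   `config$rng_seed` if that is unset).
#' @param control_handling How control mesocosms enter the loading analyses:
#'   `"as_zero"` keeps them at 0 g, `"exclude"` drops them.
#' @return A `mesothresh_report` list with each stage's result and, when the
#'   experiment carries ground truth, the recovered-vs-true threshold and
#'   breakpoint.
#' @export
run_pipeline <- function(experiment = NULL, config = experiment_config(),
                         run = run_config(), seed = NULL,
                         control_handling = c("as_zero", "exclude")) {
  control_handling <- match.arg(control_handling)
  seed <- seed %||% run$rng_seed %||% config$rng_seed
  if (is.null(experiment)) {
    experiment <- simulate_experiment(config, seed = seed)
  }
  aligned <- join_metadata(experiment$counts, experiment$metadata)
  meta <- aligned$metadata
  if (control_handling == "exclude") {
    keep <- meta$treatment != "control"
    aligned$counts <- aligned$counts[keep, ]
    meta <- meta[keep, ]
  }

  water <- meta$source == "water"
  water_counts <- aligned$counts[water, ]
  water_meta <- meta[water, ]
  rare <- rarefy_counts(water_counts, depth = run$rarefaction_depth,
                        seed = seed)
  water_meta <- water_meta[match(rare$sample_id, water_meta$sample_id), ]
  d_all <- bray_curtis(rare)

  perm <- permanova(d_all, dplyr::mutate(water_meta, day = factor(.data$day)),
                    terms = c("treatment", "loading_g", "day"),
                    n_perm = run$n_permutations, seed = seed)

  days <- sort(unique(water_meta$day))
  first_day <- days[1]
  day_results <- list()
  for (dy in days) {
    in_day <- water_meta$day == dy
    counts_d <- rare[in_day, ]
    meta_d <- water_meta[in_day, ]
    d_day <- bray_curtis(counts_d)
    scan <- threshold_scan(d_day, meta_d$loading_g,
                           n_perm = run$n_permutations, seed = seed)
    nmds <- ord_nmds(d_day, k = run$ordination_dimensions)
    nmds <- orient_axes(nmds, meta_d$loading_g)
    env_d <- experiment$env[match(meta_d$sample_id,
                                  experiment$env$sample_id), ]
    ef <- env_fit(nmds, env_d, n_perm = run$n_permutations, seed = seed)
    pc1 <- environment_pc1(env_d, loading = meta_d$loading_g)
    bp_env <- breakpoint_analysis(meta_d$loading_g, pc1$pc1,
                                  alpha = run$alpha_model_selection)
    bp_micro <- breakpoint_analysis(pc1$pc1, nmds$scores[, 1],
                                    alpha = run$alpha_model_selection)
    day_results[[as.character(dy)]] <- list(
      day = dy, threshold_scan = scan, nmds = nmds, envfit = ef,
      environment_pc1 = pc1, breakpoint_loading_env = bp_env,
      breakpoint_env_microbiome = bp_micro)
  }

  plast <- genomic_plasticity(experiment$gene_dissim,
                              experiment$proteome_dissim)
  traits <- dplyr::left_join(experiment$traits, plast, by = "taxon_id")
  cwm <- community_weighted_traits(rare, traits)

  diff_days <- c(first_day, days[length(days)])
  diff_res <- list()
  for (dy in unique(diff_days)) {
    in_day <- water_meta$day == dy
    pa <- pathway_abundance(rare[in_day, ], experiment$pathways)
    diff_res[[as.character(dy)]] <- differential_pathways(
      pa, water_meta$loading_g[in_day], n_perm = run$n_permutations,
      seed = seed, p_threshold = run$pathway_p_threshold,
      min_abs_log2fc = run$pathway_min_abs_log2fc,
      min_taxa = run$pathway_min_taxa)
  }
  sig_sets <- lapply(diff_res, function(r) r$pathway_id[r$passes_filters])
  categ <- if (length(sig_sets) == 2) {
    categorize_pathways(sig_sets[[1]], sig_sets[[2]])
  } else {
    NULL
  }

  report <- list(
    permanova = perm,
    days = day_results,
    first_day = first_day,
    cwm_traits = cwm,
    plasticity = plast,
    differential_pathways = diff_res,
    pathway_categories = categ,
    metadata = water_meta,
    seed = seed)
  gt <- experiment$ground_truth
  if (!is.null(gt)) {
    fd <- day_results[[as.character(first_day)]]
    report$recovery <- tibble::tibble(
      quantity = c("threshold_g", "env_breakpoint_g"),
      truth = c(gt$true_threshold_g, gt$env_breakpoint_g),
      estimate = c(fd$threshold_scan$best_threshold,
                   fd$breakpoint_loading_env$piecewise$breakpoint))
  }
  structure(report, class = "mesothresh_report")
}

#' Summarize a pipeline report as a flat named list of key numbers
#'
#' @param report A `mesothresh_report`.
#' @return Named list of the headline quantities of the run.
#' @export
report_summary <- function(report) {
  perm <- report$permanova$table
  fd <- report$days[[as.character(report$first_day)]]
  out <- list(
    permanova_r2_treatment = perm$R2[perm$term == "treatment"],
    permanova_r2_loading = perm$R2[perm$term == "loading_g"],
    permanova_r2_day = perm$R2[perm$term == "day"],
    permanova_r2_residual = perm$R2[perm$term == "Residual"],
    best_threshold_g = fd$threshold_scan$best_threshold,
    best_threshold_r2 = fd$threshold_scan$best_r2,
    best_threshold_p = fd$threshold_scan$best_p,
    nmds_stress = fd$nmds$stress,
    envfit_max_r2 = max(fd$envfit$r2),
    env_breakpoint_g = fd$breakpoint_loading_env$piecewise$breakpoint,
    env_breakpoint_f = fd$breakpoint_loading_env$comparison$f,
    env_breakpoint_p = fd$breakpoint_loading_env$comparison$p,
    env_model_selected = fd$breakpoint_loading_env$comparison$selected,
    microbiome_model_selected =
      fd$breakpoint_env_microbiome$comparison$selected)
  if (!is.null(report$pathway_categories)) {
    counts <- attr(report$pathway_categories, "counts")
    out$pathways_only_early <- unname(counts["only_early"])
    out$pathways_only_late <- unname(counts["only_late"])
    out$pathways_both <- unname(counts["both"])
    out$pathways_total <- unname(counts["total"])
  }
  out
}

#' Write a pipeline report to a directory
#'
#' JSON for the flat summary and nested results; a PERMANOVA table as TSV
#' (Source, df, SS, R2, F, p); the threshold profile and breakpoint
#' decisions as CSV.
#'
#' @param report A `mesothresh_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tab <- report$permanova$table
  names(tab)[1] <- "Source"
  readr::write_tsv(tab, file.path(dir, "permanova.tsv"), progress = FALSE)
  fd <- report$days[[as.character(report$first_day)]]
  readr::write_csv(fd$threshold_scan$profile,
                   file.path(dir, "threshold_profile.csv"), progress = FALSE)
  bp_rows <- purrr::map_dfr(report$days, function(dres) {
    purrr::map_dfr(
      list(loading_vs_environment = dres$breakpoint_loading_env,
           environment_vs_microbiome = dres$breakpoint_env_microbiome),
      function(ba) tibble::tibble(
        model_chosen = ba$comparison$selected,
        breakpoint = ba$piecewise$breakpoint,
        f = ba$comparison$f, p = ba$comparison$p),
      .id = "relationship") |>
      dplyr::mutate(day = dres$day, .before = 1)
  })
  readr::write_csv(bp_rows, file.path(dir, "breakpoint_models.csv"),
                   progress = FALSE)
  readr::write_csv(report$cwm_traits, file.path(dir, "cwm_traits.csv"),
                   progress = FALSE)
  if (!is.null(report$recovery)) {
    readr::write_csv(report$recovery, file.path(dir, "recovery.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @export
print.mesothresh_report <- function(x, ...) {
  s <- report_summary(x)
  cat("mesothresh pipeline report\n")
  cat(sprintf("  PERMANOVA R2: treatment %.3f, loading %.3f, day %.3f\n",
              s$permanova_r2_treatment, s$permanova_r2_loading,
              s$permanova_r2_day))
  cat(sprintf("  threshold: %g g (R2 %.3f, p %.4g)\n", s$best_threshold_g,
              s$best_threshold_r2, s$best_threshold_p))
  cat(sprintf("  environment breakpoint day %s: %.4g g (%s, p %.4g)\n",
              names(x$days)[1], s$env_breakpoint_g, s$env_model_selected,
              s$env_breakpoint_p))
  invisible(x)
}
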