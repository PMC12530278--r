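#' Validate a sample-by-taxon count table
#'
#' A count table is a tibble whose first column is `sample_id` and whose
#' remaining columns are taxon abundances: non-negative integers, one column
#' per taxon. Samples are rows, matching the ecology-table convention used by
#' downstream dissimilarity and ordination functions.
#'
#' @param counts A data frame with a `sample_id` column and numeric taxon
#'   columns.
#' @param require_positive Require at least one positive count per sample.
#' @return The validated table as a tibble (invisibly unchanged).
#' @export
validate_count_table <- function(counts, require_positive = TRUE) {
  counts <- tibble::as_tibble(counts)
  if (!"sample_id" %in% names(counts)) {
    abort("count table must have a 'sample_id' first column")
  }
  ids <- as.character(counts$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  taxa <- setdiff(names(counts), "sample_id")
  if (length(taxa) == 0L) abort("count table has no taxon columns")
  if (anyDuplicated(taxa)) abort("duplicate taxon ids in count table")
  mat <- as.matrix(counts[taxa])
  if (!is.numeric(mat)) abort("taxon columns must be numeric")
  bad <- which(mat < 0 | abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "negative or non-integer count at sample '%s', taxon '%s' (value %g)",
      ids[bad[1, 1]], taxa[bad[1, 2]], mat[bad[1, 1], bad[1, 2]]))
  }
  if (require_positive && any(rowSums(mat) == 0)) {
    zero <- ids[rowSums(mat) == 0]
    abort(paste0("samples with no positive counts: ",
                 paste(zero, collapse = ", ")))
  }
  counts
}

#' Convert a count table to a sample-by-taxon integer matrix
#'
#' @param counts A count table (see [validate_count_table()]).
#' @return Integer matrix with sample ids as row names.
#' @export
count_matrix <- function(counts) {
  counts <- tibble::as_tibble(counts)
  taxa <- setdiff(names(counts), "sample_id")
  mat <- as.matrix(counts[taxa])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(counts$sample_id)
  mat
}

# inverse of count_matrix()
matrix_to_count_table <- function(mat) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(mat)),
    tibble::as_tibble(mat)
  )
}

#' Read a count table from TSV or BIOM-JSON
#'
#' TSV layout: header row of taxon ids, first column `sample_id`, one row per
#' sample. The BIOM JSON variant accepts the classic (format 1.0) dense or
#' sparse layout, in which rows are observations (taxa) and columns are
#' samples; it is transposed on read so samples are rows.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return A validated count table tibble. Row and column order are preserved
#'   from the file.
#' @export
read_count_table <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "tsv") {
    counts <- readr::read_tsv(path, show_col_types = FALSE,
                              progress = FALSE)
    names(counts)[1] <- "sample_id"
    counts$sample_id <- as.character(counts$sample_id)
  } else {
    biom <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    taxa <- vapply(biom$rows, function(r) r$id, character(1))
    samples <- vapply(biom$columns, function(r) r$id, character(1))
    mat <- matrix(0, nrow = length(samples), ncol = length(taxa),
                  dimnames = list(samples, taxa))
    if (identical(biom$matrix_type, "dense")) {
      for (i in seq_along(biom$data)) {
        mat[, i] <- unlist(biom$data[[i]])
      }
    } else {
      for (trip in biom$data) {
        # sparse triples are [row, col, value] with 0-based indices
        mat[trip[[2]] + 1L, trip[[1]] + 1L] <- trip[[3]]
      }
    }
    counts <- matrix_to_count_table(mat)
  }
  validate_count_table(counts, require_positive = FALSE)
}

#' Write a count table as TSV
#'
#' @param counts A count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts, require_positive = FALSE)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expected CSV columns: `sample_id`, `mesocosm_id`, `loading_g` (grams in
#' the configured design range), `treatment` (`burned`, `unburned` or
#' `control`), `day`, `source` (`water`, `daphnia`, `mosquito`, `sage`,
#' `willow`).
#'
#' @param path CSV path.
#' @param loading_range Allowed loading range in grams.
#' @return Tibble of metadata.
#' @export
read_sample_metadata <- function(path, loading_range = c(0, 400)) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta, loading_range)
}

#' @rdname read_sample_metadata
#' @param meta A metadata data frame to validate in place.
#' @export
validate_sample_metadata <- function(meta, loading_range = c(0, 400)) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "mesocosm_id", "loading_g", "treatment", "day",
            "source")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0L) {
    abort(paste0("metadata missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids in metadata")
  out <- meta$loading_g < loading_range[1] | meta$loading_g > loading_range[2]
  if (any(out)) {
    abort(sprintf("loading_g outside [%g, %g] for samples: %s",
                  loading_range[1], loading_range[2],
                  paste(meta$sample_id[out], collapse = ", ")))
  }
  bad_trt <- setdiff(unique(meta$treatment), c("burned", "unburned", "control"))
  if (length(bad_trt) > 0L) {
    abort(paste0("unknown treatment levels: ", paste(bad_trt, collapse = ", ")))
  }
  bad_src <- setdiff(unique(meta$source),
                     c("water", "daphnia", "mosquito", "sage", "willow"))
  if (length(bad_src) > 0L) {
    abort(paste0("unknown sources: ", paste(bad_src, collapse = ", ")))
  }
  meta
}

#' Read the environment table
#'
#' CSV with `sample_id` plus exactly the nine environmental variables of
#' [env_variables()]. Missing values are an error unless `impute = "mean"`,
#' in which case each missing cell is replaced by its variable mean and a
#' message is emitted.
#'
#' @param path CSV path.
#' @param impute `"none"` (default) or `"mean"`.
#' @return Tibble with `sample_id` and the nine variables.
#' @export
read_environment_table <- function(path, impute = c("none", "mean")) {
  env <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_environment_table(env, impute = impute)
}

#' @rdname read_environment_table
#' @param env An environment data frame to validate in place.
#' @export
validate_environment_table <- function(env, impute = c("none", "mean")) {
  impute <- match.arg(impute)
  env <- tibble::as_tibble(env)
  vars <- env_variables()
  missing <- setdiff(vars, names(env))
  if (length(missing) > 0L) {
    abort(paste0("environment table missing variables: ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(env), c("sample_id", vars))
  if (length(extra) > 0L) {
    abort(paste0("unexpected environment columns: ",
                 paste(extra, collapse = ", ")))
  }
  if (anyNA(env[vars])) {
    if (impute == "none") {
      abort("environment table has missing values; pass impute = 'mean' to fill them")
    }
    for (v in vars) {
      miss <- is.na(env[[v]])
      if (any(miss)) {
        env[[v]][miss] <- mean(env[[v]], na.rm = TRUE)
        inform(sprintf("imputed %d missing value(s) in %s with the mean",
                       sum(miss), v))
      }
    }
  }
  env[c("sample_id", vars)]
}

#' Align a count table with sample metadata (and optionally environment)
#'
#' Subsets and reorders so all tables carry the same samples in the same
#' order, the order of the count table. Every sample in the count table must
#' have exactly one metadata row; metadata rows without counts are dropped.
#'
#' @param counts A count table.
#' @param meta Sample metadata.
#' @param env Optional environment table.
#' @return A list with elements `counts`, `metadata` and (if given) `env`,
#'   aligned by sample.
#' @export
join_metadata <- function(counts, meta, env = NULL) {
  counts <- validate_count_table(counts, require_positive = FALSE)
  meta <- tibble::as_tibble(meta)
  ids <- as.character(counts$sample_id)
  orphans <- setdiff(ids, as.character(meta$sample_id))
  if (length(orphans) > 0L) {
    abort(paste0("samples missing from metadata: ",
                 paste(orphans, collapse = ", ")))
  }
  meta_aligned <- meta[match(ids, as.character(meta$sample_id)), ]
  out <- list(counts = counts, metadata = meta_aligned)
  if (!is.null(env)) {
    env <- tibble::as_tibble(env)
    env_orphans <- setdiff(ids, as.character(env$sample_id))
    if (length(env_orphans) > 0L) {
      abort(paste0("samples missing from environment table: ",
                   paste(env_orphans, collapse = ", ")))
    }
    out$env <- env[match(ids, as.character(env$sample_id)), ]
  }
  out
}

#' Run configuration for the analysis pipeline
#'
#' Bundles the tunable analysis parameters: number of permutations for all
#' permutation tests, the rarefaction depth (reads per sample), the
#' model-selection alpha for linear-vs-piecewise comparisons, the
#' differential-pathway filters, and the ordination dimensionality.
#'
#' @param n_permutations Permutations for PERMANOVA, envfit and pathway
#'   tests (default 999).
#' @param rng_seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param rarefaction_depth Reads per sample after rarefaction (default 5258).
#' @param alpha_model_selection Alpha for piecewise-vs-linear selection
#'   (default 0.01).
#' @param pathway_p_threshold,pathway_min_abs_log2fc,pathway_min_taxa The
#'   three differential-pathway filters (defaults 0.01, 2, 5).
#' @param ordination_dimensions Number of ordination axes (default 2).
#' @return A validated `run_config` list.
#' @export
run_config <- function(n_permutations = 999,
                       rng_seed = NULL,
                       rarefaction_depth = 5258,
                       alpha_model_selection = 0.01,
                       pathway_p_threshold = 0.01,
                       pathway_min_abs_log2fc = 2,
                       pathway_min_taxa = 5,
                       ordination_dimensions = 2) {
  cfg <- structure(
    list(n_permutations = n_permutations, rng_seed = rng_seed,
         rarefaction_depth = rarefaction_depth,
         alpha_model_selection = alpha_model_selection,
         pathway_p_threshold = pathway_p_threshold,
         pathway_min_abs_log2fc = pathway_min_abs_log2fc,
         pathway_min_taxa = pathway_min_taxa,
         ordination_dimensions = ordination_dimensions),
    class = "run_config")
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A `run_config` (or plain list) to validate.
#' @export
validate_run_config <- function(cfg) {
  need <- c("n_permutations", "rarefaction_depth", "alpha_model_selection",
            "pathway_p_threshold", "pathway_min_abs_log2fc",
            "pathway_min_taxa", "ordination_dimensions")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0L) {
    abort(paste0("run config missing keys: ", paste(missing, collapse = ", ")))
  }
  if (cfg$n_permutations < 1) abort("n_permutations must be >= 1")
  pos <- c("rarefaction_depth", "alpha_model_selection",
           "pathway_p_threshold", "pathway_min_abs_log2fc",
           "pathway_min_taxa", "ordination_dimensions")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      abort(paste0("run config key must be > 0: ", k))
    }
  }
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}
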