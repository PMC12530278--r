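#' Configuration of a synthetic mesocosm experiment
#'
#' Parameterizes the simulator that emulates the statistical structure of a
#' plant-loading mesocosm experiment: 30 mesocosms split evenly between
#' burned and unburned treatments, loadings spanning 0-400 g, repeated
#' sampling days, a two-state compositional mixture with a logistic switch at
#' a true loading threshold, piecewise-linear environment-loading
#' relationships whose hinge relaxes over time, genome traits optionally
#' biased by compositional state, and a binary pathway-by-taxon incidence.
#'
#' The taxon composition of each water sample is a logistic-weighted mixture
#' of two Dirichlet-drawn state compositions: with `w(loading) =
#' plogis(state_mixing_sharpness * (loading - true_threshold_g))`, the sample
#' expectation is `(1 - w) * state1 + w * state2`, perturbed by treatment and
#' day effects, then resampled through a Dirichlet (overdispersion) and a
#' multinomial (sequencing depth) stage.
#'
#' @param n_mesocosms Number of mesocosms (default 30).
#' @param n_per_treatment Mesocosms per burning treatment (default 15).
#' @param loading_grid Grams of plant material per mesocosm within one
#'   treatment; recycled across treatments. Default: a 15-point grid from 0
#'   to 400 g with 25 g steps through 200 g.
#' @param days Sampling days for water communities (default `c(10, 59, 89)`).
#' @param n_taxa Number of taxa (default 120).
#' @param depth_mean,depth_dispersion Negative-binomial sequencing-depth
#'   parameters (mean reads, size).
#' @param true_threshold_g Loading at which the compositional state switches
#'   (default 100 g); must lie strictly inside the loading range.
#' @param state_mixing_sharpness Logistic steepness per gram (default 0.08).
#' @param effect_size SD of the per-taxon log-abundance tilt separating the
#'   two states (default 1); 0 makes the states identical.
#' @param burning_effect_size SD of the burned-treatment log tilt (default
#'   0.15, a deliberately weak effect).
#' @param temporal_drift_size SD of the per-day log tilt (default 0.6); the
#'   first day is the baseline.
#' @param dirichlet_concentration Concentration of the per-sample Dirichlet
#'   resampling stage (default 200); larger = less compositional noise.
#' @param env_breakpoint_g Hinge position of the environment-loading
#'   relationships (default 100 g).
#' @param env_slopes_below,env_slopes_above Named per-variable slopes (units
#'   per 100 g) below and above the hinge at the first sampling day.
#' @param env_slope_tau Time constant (days) over which the above-hinge slope
#'   converges to the below-hinge slope, removing the hinge at later days
#'   (default 20 d).
#' @param env_noise_sd Gaussian noise SD on each environmental variable
#'   (default 0.35).
#' @param genome_size_range,doubling_time_range_h Trait ranges (bp; hours).
#' @param trait_state_bias Strength of the association between the
#'   high-loading state and smaller, faster-growing genomes (default 1; 0
#'   switches the association off).
#' @param n_pathways,pathway_prevalence Pathway incidence dimensions.
#' @param pathway_state_association SD of the per-pathway affinity linking
#'   membership probability to a taxon's compositional-state tilt (default
#'   2). Positive-affinity pathways concentrate in high-loading-state taxa,
#'   giving the pathway table loading-differential structure; 0 makes
#'   membership independent of state.
#' @param source_mixing Named per-source weight on the water composition for
#'   host/plant-associated microbiomes (convex mixture; remainder is a
#'   source-specific composition).
#' @param source_mixing_slope Named per-source change of that weight per gram
#'   of loading (default 0 for all sources).
#' @param rng_seed Default seed used by [simulate_experiment()] when no seed
#'   argument is given.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_mesocosms = 30,
                              n_per_treatment = 15,
                              loading_grid = c(0, 25, 50, 75, 100, 125, 150,
                                               175, 200, 250, 300, 325, 350,
                                               375, 400),
                              days = c(10, 59, 89),
                              n_taxa = 120,
                              depth_mean = 12000,
                              depth_dispersion = 30,
                              true_threshold_g = 100,
                              state_mixing_sharpness = 0.08,
                              effect_size = 1,
                              burning_effect_size = 0.15,
                              temporal_drift_size = 0.6,
                              dirichlet_concentration = 200,
                              env_breakpoint_g = 100,
                              env_slopes_below = c(
                                percent_DO = -1.5, DOC = 1.5, FI = -0.8,
                                BIX = 1.0, HIX = -1.0, Sr = 0.9,
                                SUVA254 = 1.2, pH = 0.7, temperature = 0.1),
                              env_slopes_above = NULL,
                              env_slope_tau = 20,
                              env_noise_sd = 0.35,
                              genome_size_range = c(2e6, 8e6),
                              doubling_time_range_h = c(1, 30),
                              trait_state_bias = 1,
                              n_pathways = 60,
                              pathway_prevalence = 0.3,
                              pathway_state_association = 2,
                              source_mixing = c(daphnia = 0.6, mosquito = 0.25,
                                                sage = 0.35, willow = 0.35),
                              source_mixing_slope = c(daphnia = 0,
                                                      mosquito = 0,
                                                      sage = 0, willow = 0),
                              rng_seed = 1L) {
  if (is.null(env_slopes_above)) {
    env_slopes_above <- 0.1 * env_slopes_below
  }
  cfg <- structure(as.list(environment()), class = "experiment_config")
  validate_experiment_config(cfg)
}

#' @rdname experiment_config
#' @param cfg Configuration to validate.
#' @export
validate_experiment_config <- function(cfg) {
  if (cfg$n_taxa < 2) abort("n_taxa must be >= 2")
  if (cfg$depth_mean <= 0) abort("sequencing depth mean must be positive")
  rng <- range(cfg$loading_grid)
  if (rng[1] < 0 || rng[2] > 400) abort("loading_grid must lie in [0, 400]")
  if (cfg$true_threshold_g <= rng[1] || cfg$true_threshold_g >= rng[2]) {
    abort("true_threshold_g must lie strictly inside the loading range")
  }
  if (cfg$effect_size < 0) abort("effect_size must be >= 0")
  if (cfg$n_mesocosms != 2 * cfg$n_per_treatment) {
    abort("n_mesocosms must equal 2 * n_per_treatment")
  }
  vars <- env_variables()
  if (!all(vars %in% names(cfg$env_slopes_below)) ||
      !all(vars %in% names(cfg$env_slopes_above))) {
    abort("env slopes must be named for all nine environmental variables")
  }
  cfg
}

# one Dirichlet draw; alpha >= 0, zeros stay structural zeros
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Simulate environmental variables along the loading gradient
#'
#' Each of the nine variables is a hinge (piecewise-linear) function of
#' loading with a breakpoint at `env_breakpoint_g`. The above-hinge slope
#' relaxes exponentially toward the below-hinge slope with day, so the first
#' sampling day carries a clear hinge and later days are close to linear.
#' Gaussian noise of SD `env_noise_sd` is added per observation.
#'
#' @param loading_g Numeric vector of loadings (grams).
#' @param day Sampling day (scalar or vector matching `loading_g`).
#' @param config An [experiment_config()].
#' @param noise_sd Override for the noise SD (e.g. 0 for deterministic
#'   values).
#' @param seed Optional seed.
#' @return Tibble with one row per observation and the nine variables.
#' @export
simulate_environment <- function(loading_g, day, config = experiment_config(),
                                 noise_sd = NULL, seed = NULL) {
  noise_sd <- noise_sd %||% config$env_noise_sd
  day <- rep_len(day, length(loading_g))
  day0 <- min(config$days)
  vars <- env_variables()
  with_seed_or_not(seed, {
    cols <- lapply(vars, function(v) {
      sb <- config$env_slopes_below[[v]]
      sa0 <- config$env_slopes_above[[v]]
      # hinge slope above the breakpoint converges to the below slope with day
      decay <- exp(-(day - day0) / config$env_slope_tau)
      sa <- sb + (sa0 - sb) * decay
      bp <- config$env_breakpoint_g
      val <- sb * pmin(loading_g, bp) / 100 +
        sa * pmax(loading_g - bp, 0) / 100
      val + rnorm(length(loading_g), 0, noise_sd)
    })
    names(cols) <- vars
    tibble::as_tibble(cols)
  })
}

#' Simulate taxon traits and gene/proteome dissimilarity matrices
#'
#' Genome sizes and doubling times are drawn log-uniformly inside the
#' configured ranges; when `trait_state_bias > 0`, taxa favoured by the
#' high-loading state (positive state tilt) are biased toward smaller
#' genomes and shorter doubling times, emulating genome streamlining under
#' disturbance. Pairwise 16S-gene and proteome dissimilarities are built
#' from latent coordinates; the proteome coordinates get per-taxon
#' displacements so taxa differ in how far their functional divergence
#' departs from their marker-gene divergence.
#'
#' @param n_taxa Number of taxa.
#' @param config An [experiment_config()].
#' @param state_tilt Optional per-taxon log tilt toward the high-loading
#'   state (the simulator passes its own; default none).
#' @param seed Optional seed.
#' @return List with `traits` (tibble: `taxon_id`, `genome_size_bp`,
#'   `n_coding_sequences`, `doubling_time_h`), `gene_dissim` and
#'   `proteome_dissim` (symmetric, zero-diagonal matrices in `[0, 1]`).
#' @export
simulate_traits <- function(n_taxa, config = experiment_config(),
                            state_tilt = NULL, seed = NULL) {
  if (n_taxa < 2) abort("n_taxa must be >= 2")
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  bias <- config$trait_state_bias
  zt <- if (is.null(state_tilt) || sd(state_tilt) == 0) {
    rep(0, n_taxa)
  } else {
    as.numeric(scale(state_tilt))
  }
  with_seed_or_not(seed, {
    lgs <- runif(n_taxa, log(config$genome_size_range[1]),
                 log(config$genome_size_range[2]))
    gs <- exp(lgs - 0.25 * bias * zt)
    gs <- pmin(pmax(gs, config$genome_size_range[1]),
               config$genome_size_range[2])
    ldt <- runif(n_taxa, log(config$doubling_time_range_h[1]),
                 log(config$doubling_time_range_h[2]))
    dt <- exp(ldt - 0.4 * bias * zt)  # state-2 taxa double faster
    dt <- pmin(pmax(dt, config$doubling_time_range_h[1]),
               config$doubling_time_range_h[2])
    cds <- round(gs / 1100 * exp(rnorm(n_taxa, 0, 0.05)))
    coords <- matrix(rnorm(n_taxa * 4), n_taxa)
    d_gene <- as.matrix(dist(coords))
    d_gene <- d_gene / max(d_gene)
    disp <- matrix(rnorm(n_taxa * 4, 0, 0.35), n_taxa)
    d_prot <- as.matrix(dist(coords + disp))
    d_prot <- d_prot / max(d_prot)
    dimnames(d_gene) <- dimnames(d_prot) <- list(taxa, taxa)
    list(
      traits = tibble::tibble(taxon_id = taxa, genome_size_bp = gs,
                              n_coding_sequences = cds, doubling_time_h = dt),
      gene_dissim = d_gene,
      proteome_dissim = d_prot
    )
  })
}

#' Simulate a complete mesocosm experiment
#'
#' Generates water-community count tables for every configured sampling day,
#' host/plant-associated communities at the final day, sample metadata, the
#' environment table, taxon traits with gene/proteome dissimilarities, a
#' pathway-by-taxon incidence, and a ground-truth record with the two state
#' compositions, the mixing weight of every sample and all parameters.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed (default `config$rng_seed`). Fixing it makes
#'   every output bit-identical across calls.
#' @return A `mesocosm_experiment` list: `counts` (count table over all
#'   samples), `metadata`, `env`, `traits`, `gene_dissim`, `proteome_dissim`,
#'   `pathways` (incidence tibble), `ground_truth`.
#' @export
simulate_experiment <- function(config = experiment_config(),
                                seed = config$rng_seed) {
  validate_experiment_config(config)
  n_mes <- config$n_mesocosms
  taxa <- sprintf("taxon_%03d", seq_len(config$n_taxa))
  with_seed_or_not(seed, {
    mes <- tibble::tibble(
      mesocosm_id = sprintf("M%02d", seq_len(n_mes)),
      treatment = rep(c("burned", "unburned"), each = config$n_per_treatment),
      loading_g = rep_len(config$loading_grid, n_mes)
    )

    # latent state compositions: shared base log-abundance, opposite tilts
    base <- rnorm(config$n_taxa, 0, 1.5)
    tilt <- rnorm(config$n_taxa, 0, 1) * config$effect_size
    state1 <- softmax(base - tilt / 2)
    state2 <- softmax(base + tilt / 2)
    burn_tilt <- rnorm(config$n_taxa, 0, 1) * config$burning_effect_size
    day_tilt <- matrix(0, length(config$days), config$n_taxa)
    if (length(config$days) > 1) {
      for (i in seq_along(config$days)[-1]) {
        day_tilt[i, ] <- rnorm(config$n_taxa, 0, 1) * config$temporal_drift_size
      }
    }

    w <- stats::plogis(config$state_mixing_sharpness *
                         (mes$loading_g - config$true_threshold_g))

    draw_sample <- function(p_expect) {
      p_expect <- p_expect / sum(p_expect)
      p <- rdirichlet1(config$dirichlet_concentration * p_expect)
      depth <- max(1L, rnbinom(1, mu = config$depth_mean,
                               size = config$depth_dispersion))
      as.integer(rmultinom(1, depth, p))
    }

    meta_rows <- list()
    count_rows <- list()
    truth_w <- list()
    water_props <- list()  # final-day water expectations, for host mixtures

    for (di in seq_along(config$days)) {
      day <- config$days[di]
      for (mi in seq_len(n_mes)) {
        p_mix <- (1 - w[mi]) * state1 + w[mi] * state2
        lt <- day_tilt[di, ] +
          if (mes$treatment[mi] == "burned") burn_tilt else 0
        p_exp <- p_mix * exp(lt)
        p_exp <- p_exp / sum(p_exp)
        sid <- sprintf("%s_water_d%02d", mes$mesocosm_id[mi], day)
        meta_rows[[sid]] <- tibble::tibble(
          sample_id = sid, mesocosm_id = mes$mesocosm_id[mi],
          loading_g = mes$loading_g[mi], treatment = mes$treatment[mi],
          day = day, source = "water")
        count_rows[[sid]] <- draw_sample(p_exp)
        truth_w[[sid]] <- w[mi]
        if (di == length(config$days)) water_props[[mi]] <- p_exp
      }
    }

    # host/plant-associated communities at the final sampling day: convex
    # mixtures of a source-specific composition and the mesocosm's water
    # composition
    final_day <- config$days[length(config$days)]
    for (src in names(config$source_mixing)) {
      q_src <- softmax(base + rnorm(config$n_taxa, 0, 2))
      for (mi in seq_len(n_mes)) {
        mix <- config$source_mixing[[src]] +
          config$source_mixing_slope[[src]] * mes$loading_g[mi]
        mix <- min(max(mix, 0), 1)
        p_exp <- mix * water_props[[mi]] + (1 - mix) * q_src
        sid <- sprintf("%s_%s_d%02d", mes$mesocosm_id[mi], src, final_day)
        meta_rows[[sid]] <- tibble::tibble(
          sample_id = sid, mesocosm_id = mes$mesocosm_id[mi],
          loading_g = mes$loading_g[mi], treatment = mes$treatment[mi],
          day = final_day, source = src)
        count_rows[[sid]] <- draw_sample(p_exp)
        truth_w[[sid]] <- w[mi]
      }
    }

    metadata <- dplyr::bind_rows(meta_rows)
    cmat <- do.call(rbind, count_rows)
    dimnames(cmat) <- list(metadata$sample_id, taxa)
    counts <- matrix_to_count_table(cmat)

    water_meta <- dplyr::filter(metadata, .data$source == "water")
    env_vals <- simulate_environment(water_meta$loading_g, water_meta$day,
                                     config)
    env <- dplyr::bind_cols(
      tibble::tibble(sample_id = water_meta$sample_id), env_vals)

    tr <- simulate_traits(config$n_taxa, config, state_tilt = tilt)

    # membership probability tilted by each taxon's state affiliation, so
    # some pathways concentrate in the high- or low-loading state
    zt <- if (sd(tilt) > 0) as.numeric(scale(tilt)) else rep(0, config$n_taxa)
    affinity <- rnorm(config$n_pathways, 0, config$pathway_state_association)
    prob <- stats::plogis(stats::qlogis(config$pathway_prevalence) +
                            outer(affinity, zt))
    inc <- matrix(rbinom(config$n_pathways * config$n_taxa, 1, prob),
                  nrow = config$n_pathways,
                  dimnames = list(sprintf("pwy_%03d",
                                          seq_len(config$n_pathways)), taxa))
    empty <- which(rowSums(inc) == 0)
    for (i in empty) inc[i, sample.int(config$n_taxa, 1)] <- 1
    pathways <- dplyr::bind_cols(
      tibble::tibble(pathway_id = rownames(inc)), tibble::as_tibble(inc))

    structure(list(
      counts = counts, metadata = metadata, env = env,
      traits = tr$traits, gene_dissim = tr$gene_dissim,
      proteome_dissim = tr$proteome_dissim, pathways = pathways,
      ground_truth = list(
        state1 = setNames(state1, taxa), state2 = setNames(state2, taxa),
        state_tilt = setNames(tilt, taxa),
        pathway_affinity = setNames(affinity, rownames(inc)),
        mixing_weight = tibble::tibble(
          sample_id = metadata$sample_id, w = unlist(truth_w)),
        true_threshold_g = config$true_threshold_g,
        env_breakpoint_g = config$env_breakpoint_g,
        config = config)
    ), class = "mesocosm_experiment")
  })
}

#' Write all tables of a simulated experiment to a directory
#'
#' Counts and pathway incidence as TSV, metadata and environment as CSV,
#' traits as TSV, dissimilarity matrices as square TSV, ground truth as JSON.
#'
#' @param experiment A `mesocosm_experiment`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(experiment$counts, file.path(dir, "counts.tsv"))
  readr::write_csv(experiment$metadata, file.path(dir, "metadata.csv"),
                   progress = FALSE)
  readr::write_csv(experiment$env, file.path(dir, "environment.csv"),
                   progress = FALSE)
  readr::write_tsv(experiment$traits, file.path(dir, "traits.tsv"),
                   progress = FALSE)
  readr::write_tsv(experiment$pathways, file.path(dir, "pathways.tsv"),
                   progress = FALSE)
  write_dissimilarity(experiment$gene_dissim,
                      file.path(dir, "gene_dissim.tsv"))
  write_dissimilarity(experiment$proteome_dissim,
                      file.path(dir, "proteome_dissim.tsv"))
  gt <- experiment$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write / read a square dissimilarity matrix as TSV with ids
#'
#' @param d A symmetric matrix or `dist`.
#' @param path File path.
#' @return `path` (write) or a symmetric matrix with dimnames (read).
#' @export
write_dissimilarity <- function(d, path) {
  m <- as.matrix(d)
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(m)),
                         tibble::as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}
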