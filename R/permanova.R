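# permutation indices: free permutation, or restricted within strata
make_permutations <- function(n, n_perm, strata = NULL) {
  if (is.null(strata)) {
    return(replicate(n_perm, sample.int(n)))
  }
  strata <- as.factor(strata)
  replicate(n_perm, {
    idx <- seq_len(n)
    for (lev in levels(strata)) {
      at <- which(strata == lev)
      idx[at] <- at[sample.int(length(at))]
    }
    idx
  })
}

# sequential projection (hat) matrices for an ordered term list;
# returns list(hats = cumulative hats incl. intercept-only, df per term)
sequential_hats <- function(data, terms) {
  n <- nrow(data)
  for (tm in terms) {
    v <- data[[tm]]
    if (is.null(v)) abort(paste0("term not found in data: ", tm))
    if ((is.character(v) || is.factor(v)) &&
        length(unique(v)) < 2) {
      abort(paste0("single-level factor: ", tm))
    }
  }
  hats <- list()
  dfs <- integer(length(terms))
  prev_rank <- 1L
  for (j in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(j)],
                                              collapse = " + ")))
    mm <- model.matrix(fml, data = data)
    qr_m <- qr(mm)
    dfs[j] <- qr_m$rank - prev_rank
    if (dfs[j] == 0L) {
      abort(paste0("term confounded with earlier terms: ", terms[j]))
    }
    q <- qr.Q(qr_m)[, seq_len(qr_m$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(q)
    prev_rank <- qr_m$rank
  }
  list(hats = hats, dfs = dfs)
}

#' PERMANOVA with sequential variance partitioning
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix. The total sum of squares is `sum(d_ij^2) / n` (the trace of the
#' Gower-centered matrix); each term's SS is the increment in explained
#' trace when its (centered) model matrix enters the design, in the given
#' order (sequential, Type-I). Pseudo-F per term is
#' `(SS_term / df_term) / (SS_resid / df_resid)`; p-values come from free
#' permutation of sample labels (rows and columns of the matrix permuted
#' jointly), with the same permutations reused across terms, as
#' `(b + 1) / (m + 1)` where `b` counts permuted pseudo-F values at or above
#' the observed one.
#'
#' Because the partition is sequential, term order is part of the declared
#' analysis; continuous covariates enter through their centered model matrix
#' with one degree of freedom, exactly like factor contrasts.
#'
#' @param d A `dist` or symmetric dissimilarity matrix with sample labels.
#' @param data Data frame of per-sample variables; if it has a `sample_id`
#'   column it is aligned to the labels of `d`.
#' @param terms Character vector of column names, in order of entry.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @param strata Optional factor restricting permutations to occur within
#'   its levels (e.g. mesocosm for repeated measures).
#' @param permutations Optional explicit permutation-index matrix (one
#'   permutation per column). When supplied it is treated as the complete
#'   null set: p is the plain proportion of its columns (which should then
#'   include the identity) with pseudo-F at or above the observed value.
#' @return A `permanova` object; `tidy()` gives the term table (term, df,
#'   SS, R2, F, p plus residual and total rows).
#' @export
permanova <- function(d, data, terms, n_perm = 999, seed = NULL,
                      strata = NULL, permutations = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  data <- tibble::as_tibble(data)
  if ("sample_id" %in% names(data) && !is.null(rownames(m))) {
    idx <- match(rownames(m), data$sample_id)
    if (anyNA(idx)) abort("data missing rows for some samples in d")
    data <- data[idx, ]
  }
  if (nrow(data) != n) abort("data rows must match samples in d")
  for (tm in terms) {
    fac <- data[[tm]]
    if (is.character(fac) || is.factor(fac)) {
      if (any(table(fac) < 2)) {
        abort(paste0("factor level with fewer than 2 samples in term: ", tm))
      }
    }
  }

  g <- gower_center(m)
  ss_total <- sum(diag(g))
  sh <- sequential_hats(data, terms)
  p_terms <- length(terms)
  df_res <- n - 1L - sum(sh$dfs)
  if (df_res < 1) abort("no residual degrees of freedom")

  term_ss_from <- function(gmat) {
    cum <- vapply(sh$hats, function(h) sum(h * gmat), numeric(1))
    ss <- diff(c(0, cum))  # hats include the intercept; G is centered
    list(ss = ss, resid = sum(diag(gmat)) - cum[p_terms])
  }
  obs <- term_ss_from(g)
  f_obs <- (obs$ss / sh$dfs) / (obs$resid / df_res)

  exhaustive <- !is.null(permutations)
  with_seed_or_not(seed, {
    if (!exhaustive) {
      permutations <- make_permutations(n, n_perm, strata)
    }
    m_perm <- ncol(permutations)
    exceed <- numeric(p_terms)
    for (i in seq_len(m_perm)) {
      idx <- permutations[, i]
      gp <- g[idx, idx]
      pp <- term_ss_from(gp)
      f_p <- (pp$ss / sh$dfs) / (pp$resid / df_res)
      exceed <- exceed + (f_p >= f_obs - 1e-12)
    }
    p_vals <- if (exhaustive) exceed / m_perm else (exceed + 1) / (m_perm + 1)

    table <- dplyr::bind_rows(
      tibble::tibble(term = terms, df = sh$dfs, SS = obs$ss,
                     R2 = obs$ss / ss_total, F = f_obs, p = p_vals),
      tibble::tibble(term = "Residual", df = df_res, SS = obs$resid,
                     R2 = obs$resid / ss_total, F = NA_real_, p = NA_real_),
      tibble::tibble(term = "Total", df = n - 1L, SS = ss_total, R2 = 1,
                     F = NA_real_, p = NA_real_))
    structure(list(table = table, n = n, n_perm = m_perm,
                   exhaustive = exhaustive),
              class = "permanova")
  })
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d samples, %d permutations%s)\n", x$n, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

# fast one-term binary PERMANOVA machinery used by the threshold scan:
# within-group SS from squared dissimilarities, vectorized over many
# group-label columns at once
binary_split_stats <- function(d2, membership) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  n1 <- colSums(membership)
  q1 <- colSums((d2 %*% membership) * membership)       # sum over g1 pairs *2
  q_all <- sum(d2)
  # complement quadratic form via inclusion-exclusion
  q0 <- q_all - 2 * colSums(d2 %*% membership) + q1
  ss_within <- q1 / (2 * n1) + q0 / (2 * (n - n1))
  ss_between <- ss_total - ss_within
  f <- (ss_between / 1) / (ss_within / (n - 2))
  list(ss_total = ss_total, r2 = ss_between / ss_total, f = f)
}

#' Binary-split threshold scan over the loading gradient
#'
#' For every candidate threshold `t` (each observed loading value with at
#' least two samples on each side), runs a one-term PERMANOVA with the
#' binary indicator `loading <= t` and records its R-squared and permutation
#' p-value. The candidate with the highest R-squared is the primary
#' compositional threshold; ties are broken toward the smaller threshold and
#' flagged. All candidates share one set of label permutations.
#'
#' The best candidate's p-value is reported raw (`best_p`); because the
#' threshold is selected as the profile maximum, that value is
#' selection-inflated. An optional max-statistic correction
#' (`correct = TRUE`) re-scans each permutation and compares the observed
#' maximum R-squared against the permutation distribution of maxima.
#'
#' @param d Dissimilarity matrix or `dist`.
#' @param loading Numeric loading per sample, aligned to `d`.
#' @param n_perm Permutations (default 999).
#' @param seed Optional seed.
#' @param correct Also compute a max-statistic-corrected p for the best
#'   threshold (default `FALSE`).
#' @return A `threshold_scan` object: `profile` tibble (`threshold`, `r2`,
#'   `f`, `p`), `best_threshold`, `best_r2`, `best_p`, `tie` flag, and
#'   `best_p_corrected` when requested.
#' @export
threshold_scan <- function(d, loading, n_perm = 999, seed = NULL,
                           correct = FALSE) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  if (length(loading) != n) abort("loading length must match samples in d")
  lv <- sort(unique(loading))
  cand <- lv[vapply(lv, function(t) {
    sum(loading <= t) >= 2 && sum(loading > t) >= 2
  }, logical(1))]
  if (length(cand) == 0) abort("no admissible threshold candidate")

  memb <- vapply(cand, function(t) as.numeric(loading <= t),
                 numeric(n))
  obs <- binary_split_stats(d2, memb)

  with_seed_or_not(seed, {
    perms <- make_permutations(n, n_perm)
    exceed <- numeric(length(cand))
    max_r2_perm <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      mp <- memb[perms[, i], , drop = FALSE]
      st <- binary_split_stats(d2, mp)
      exceed <- exceed + (st$f >= obs$f - 1e-12)
      max_r2_perm[i] <- max(st$r2)
    }
    p_vals <- (exceed + 1) / (n_perm + 1)
    best_i <- which.max(obs$r2)
    ties <- abs(obs$r2 - obs$r2[best_i]) < 1e-12
    tie <- sum(ties) > 1
    if (tie) best_i <- which(ties)[1]  # smaller threshold wins
    out <- list(
      profile = tibble::tibble(threshold = cand, r2 = obs$r2, f = obs$f,
                               p = p_vals),
      best_threshold = cand[best_i], best_r2 = obs$r2[best_i],
      best_p = p_vals[best_i], tie = tie, n_perm = n_perm)
    if (correct) {
      out$best_p_corrected <-
        (sum(max_r2_perm >= obs$r2[best_i] - 1e-12) + 1) / (n_perm + 1)
    }
    structure(out, class = "threshold_scan")
  })
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "Threshold scan: best threshold %g g (R2 = %.3f, p = %.4g%s)\n",
    x$best_threshold, x$best_r2, x$best_p,
    if (x$tie) ", tied" else ""))
  if (!is.null(x$best_p_corrected)) {
    cat(sprintf("  max-statistic corrected p = %.4g\n", x$best_p_corrected))
  }
  invisible(x)
}
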