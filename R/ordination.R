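# Gower-centered inner-product matrix of a dissimilarity matrix:
# G = -1/2 * J D2 J with J = I - 11'/n. Shared by PCoA and PERMANOVA.
gower_center <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, rm) + mean(a)
}

new_ordination <- function(scores, method, sample_ids, eigenvalues = NULL,
                           stress = NULL, stress_trace = NULL,
                           converged = NULL) {
  rownames(scores) <- sample_ids
  colnames(scores) <- paste0(toupper(method), seq_len(ncol(scores)))
  structure(list(scores = scores, method = method, sample_ids = sample_ids,
                 eigenvalues = eigenvalues, stress = stress,
                 stress_trace = stress_trace, converged = converged),
            class = "ordination")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Eigendecomposition of the Gower-centered matrix of squared
#' dissimilarities; scores are eigenvectors scaled by the square root of
#' their (positive) eigenvalues. All eigenvalues, including negative ones,
#' are reported; axes with non-positive eigenvalues carry no scores.
#'
#' @param d A `dist` or symmetric dissimilarity matrix with labels.
#' @param k Number of axes to return (default 2).
#' @return An `ordination` object (`method = "pcoa"`) with centered scores
#'   and decreasing `eigenvalues`.
#' @export
ord_pcoa <- function(d, k = 2) {
  if (k < 1) abort("k must be >= 1")
  m <- as.matrix(d)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  e <- eigen(gower_center(m), symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  n_pos <- sum(pos)
  if (k > n_pos) {
    abort(sprintf("k = %d exceeds the %d positive eigenvalues", k, n_pos))
  }
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  new_ordination(scores, "pcoa", ids, eigenvalues = e$values)
}

# Kruskal stress-1 given configuration distances and disparities
stress1 <- function(dist_y, disp) {
  sqrt(sum((dist_y - disp)^2) / sum(dist_y^2))
}

# monotone disparities: isotonic regression of configuration distances on
# the dissimilarity order; ties handled by the primary approach (within a
# tie block the current distances set the order, so tied dissimilarities
# are free to take different disparities)
monotone_disparities <- function(dvec, yvec) {
  ord <- order(dvec, yvec)
  fit <- isoreg(yvec[ord])$yf
  out <- numeric(length(yvec))
  out[ord] <- fit
  out
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1 `sqrt(sum((dist - dhat)^2) / sum(dist^2))`, where
#' `dhat` are monotone (isotonic-regression) disparities of the configuration
#' distances with respect to the input dissimilarities. The configuration is
#' initialized from PCoA and updated by a Guttman transform with a
#' step-halving line search, so recorded stress never increases across
#' iterations.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param k Dimensions (default 2); needs `n >= k + 2`.
#' @param seed Optional seed (the algorithm is deterministic from the PCoA
#'   start; the seed only matters if the start is degenerate).
#' @param max_iter,tol Iteration cap (default 500) and minimum stress
#'   improvement per iteration (default 1e-6).
#' @return An `ordination` (`method = "nmds"`) with `stress`,
#'   `stress_trace` (stress after each accepted iteration, starting at the
#'   initial configuration) and a `converged` flag; non-convergence at
#'   `max_iter` returns the best configuration with a warning.
#' @export
ord_nmds <- function(d, k = 2, seed = NULL, max_iter = 500, tol = 1e-6) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < k + 2) abort("need at least k + 2 samples for NMDS")
  ids <- rownames(m) %||% as.character(seq_len(n))
  e <- eigen(gower_center(m), symmetric = TRUE)
  n_pos <- sum(e$values > max(e$values) * 1e-10)
  x <- with_seed_or_not(seed, {
    if (n_pos >= k) {
      e$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(e$values[seq_len(k)]), k)
    } else {
      cbind(e$vectors[, seq_len(n_pos), drop = FALSE] %*%
              diag(sqrt(e$values[seq_len(n_pos)]), n_pos),
            matrix(rnorm(n * (k - n_pos), 0, 1e-4), n))
    }
  })
  upper <- upper.tri(m)
  dvec <- m[upper]

  conf_stress <- function(x) {
    yv <- as.matrix(dist(x))[upper]
    disp <- monotone_disparities(dvec, yv)
    list(stress = stress1(yv, disp), dist = yv, disp = disp)
  }

  cur <- conf_stress(x)
  trace <- cur$stress
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # Guttman transform toward the current disparities
    ym <- matrix(0, n, n)
    ym[upper] <- cur$dist
    dm <- matrix(0, n, n)
    dm[upper] <- cur$disp
    ym <- ym + t(ym); dm <- dm + t(dm)
    ratio <- ifelse(ym > 0, dm / ym, 0)
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x_prop <- b %*% x / n
    # step-halving: accept only configurations that reduce stress
    step <- 1
    accepted <- FALSE
    for (h in 1:6) {
      x_new <- x + step * (x_prop - x)
      cand <- conf_stress(x_new)
      if (cand$stress < cur$stress) {
        x <- x_new
        improved <- cur$stress - cand$stress
        cur <- cand
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    trace <- c(trace, cur$stress)
    if (improved < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("NMDS did not converge in %d iterations (stress %.4g)",
                 max_iter, cur$stress))
  }
  x <- scale(x, scale = FALSE)  # center axes
  new_ordination(x, "nmds", ids, stress = cur$stress, stress_trace = trace,
                 converged = converged)
}

#' Orient ordination axes by a covariate
#'
#' Flips the sign of each axis whose correlation with the covariate is
#' negative, so every axis correlates non-negatively with it (by default the
#' loading gradient). Flipping twice restores the original scores.
#'
#' @param ord An `ordination`.
#' @param covariate Numeric vector, one value per sample in score order.
#' @return The ordination with consistently oriented axes.
#' @export
orient_axes <- function(ord, covariate) {
  if (length(covariate) != nrow(ord$scores)) {
    abort("covariate length must match the number of samples")
  }
  if (sd(covariate) == 0) {
    warn("zero-variance covariate; axes left unchanged")
    return(ord)
  }
  for (j in seq_len(ncol(ord$scores))) {
    if (cor(ord$scores[, j], covariate) < 0) {
      ord$scores[, j] <- -ord$scores[, j]
    }
  }
  ord
}

#' Fit environmental (or trait) vectors onto an ordination
#'
#' For each variable, the centered variable is regressed on the ordination
#' scores by least squares: `r2` is the coefficient of determination, the
#' direction is the unit-normalized coefficient vector, and the p-value is
#' the proportion `(b + 1) / (n_perm + 1)` of permutations of the variable
#' whose r-squared meets or exceeds the observed one.
#'
#' @param ord An `ordination` (NMDS by default in the pipeline; any score
#'   matrix works).
#' @param variables Data frame of numeric variables aligned to the
#'   ordination's samples (a `sample_id` column, if present, is used to
#'   align).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return Tibble of class `envfit_result`: `variable`, one direction column
#'   per axis, `r2`, `p`.
#' @export
env_fit <- function(ord, variables, n_perm = 999, seed = NULL) {
  x <- ord$scores
  variables <- tibble::as_tibble(variables)
  if ("sample_id" %in% names(variables)) {
    idx <- match(ord$sample_ids, variables$sample_id)
    if (anyNA(idx)) abort("variables missing for some ordination samples")
    variables <- variables[idx, setdiff(names(variables), "sample_id")]
  }
  n <- nrow(x)
  xc <- scale(x, scale = FALSE)
  qr_x <- qr(xc)
  with_seed_or_not(seed, {
    perms <- replicate(n_perm, sample.int(n))
    rows <- purrr::map_dfr(names(variables), function(vn) {
      v <- variables[[vn]]
      if (sd(v) == 0) {
        warn(sprintf("constant variable '%s'; r2 = 0, p = 1", vn))
        dir <- rep(0, ncol(x))
        return(dplyr::bind_cols(
          tibble::tibble(variable = vn),
          tibble::as_tibble(setNames(as.list(dir), colnames(x))),
          tibble::tibble(r2 = 0, p = 1)))
      }
      vc <- v - mean(v)
      coefs <- qr.coef(qr_x, vc)
      fitted <- qr.fitted(qr_x, vc)
      r2 <- sum(fitted^2) / sum(vc^2)
      dir <- coefs / sqrt(sum(coefs^2))
      r2_perm <- vapply(seq_len(n_perm), function(i) {
        vp <- vc[perms[, i]]
        vp <- vp - mean(vp)
        sum(qr.fitted(qr_x, vp)^2) / sum(vp^2)
      }, numeric(1))
      p <- (sum(r2_perm >= r2) + 1) / (n_perm + 1)
      dplyr::bind_cols(
        tibble::tibble(variable = vn),
        tibble::as_tibble(setNames(as.list(dir), colnames(x))),
        tibble::tibble(r2 = r2, p = p))
    })
    class(rows) <- c("envfit_result", class(rows))
    rows
  })
}
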