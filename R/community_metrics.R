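#' Rarefy a count table to even depth
#'
#' Each retained sample is subsampled without replacement to exactly `depth`
#' reads (multivariate hypergeometric, via [vegan::rrarefy()]). Samples with
#' fewer than `depth` total reads are dropped with a warning. The default
#' depth is the minimum per-sample total.
#'
#' @param counts A count table.
#' @param depth Target reads per sample (default: minimum per-sample total).
#' @param seed Optional seed for the subsampling.
#' @return Rarefied count table; every row sums to exactly `depth`.
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = NULL) {
  counts <- validate_count_table(counts, require_positive = FALSE)
  mat <- count_matrix(counts)
  totals <- rowSums(mat)
  depth <- depth %||% min(totals)
  if (depth <= 0) abort("rarefaction depth must be >= 1")
  keep <- totals >= depth
  if (any(!keep)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(!keep), as.integer(depth),
                 paste(rownames(mat)[!keep], collapse = ", ")))
  }
  if (!any(keep)) abort("no sample reaches the rarefaction depth")
  mat <- mat[keep, , drop = FALSE]
  # rrarefy's advisory warning about large minimum counts does not apply:
  # integrality is already enforced by the validator
  out <- with_seed_or_not(seed, suppressWarnings(vegan::rrarefy(mat, depth)))
  matrix_to_count_table(out)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`: 0 for identical samples,
#' 1 for disjoint taxon supports. Computed on counts as given (rarefy first
#' for the standard rarefy-then-dissimilarity workflow).
#'
#' @param counts A count table; no sample may be all-zero.
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(counts) {
  counts <- validate_count_table(counts, require_positive = FALSE)
  mat <- count_matrix(counts)
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    abort(paste0("all-zero sample(s): ",
                 paste(rownames(mat)[zero], collapse = ", ")))
  }
  vegan::vegdist(mat, method = "bray")
}

#' Shannon diversity per sample (natural-log units)
#'
#' `H = -sum p_i log p_i` over taxa with positive counts; bounded by
#' `log(richness)` with equality at a uniform composition.
#'
#' @param counts A count table.
#' @return Tibble with `sample_id` and `shannon`.
#' @export
shannon_index <- function(counts) {
  counts <- validate_count_table(counts, require_positive = FALSE)
  mat <- count_matrix(counts)
  if (any(rowSums(mat) == 0)) abort("empty sample in shannon_index()")
  tibble::tibble(sample_id = rownames(mat),
                 shannon = as.numeric(vegan::diversity(mat, "shannon")))
}

# exact two-sided rank-sum p by complete enumeration of group assignments;
# handles ties through average ranks. Two-sided p doubles the smaller tail
# and caps at 1 (the convention of the exact test).
wilcox_exact_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(n, n1)
  w_all <- colSums(matrix(r[sets], nrow = n1))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# normal approximation with tie-corrected variance (no continuity correction)
wilcox_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  2 * pnorm(-abs(w - mu) / sqrt(sigma2))
}

# insert-and-absorb compact letter display from a logical "not significantly
# different" pair matrix
letter_groups <- function(groups, ns_pairs) {
  k <- length(groups)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (ns_pairs[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (all(c(i, j) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_sets[[a]] %in% new_sets[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  letters_out <- rep("", k)
  for (s in seq_along(sets)) {
    idx <- sets[[s]]
    letters_out[idx] <- paste0(letters_out[idx], letters[s])
  }
  setNames(letters_out, groups)
}

#' Pairwise Wilcoxon rank-sum tests with significance letters
#'
#' For every pair of groups, a two-sided rank-sum p-value: exact (complete
#' enumeration of assignments, tie-aware) when both groups have at most 10
#' values, a normal approximation with tie-corrected variance otherwise.
#' Groups sharing a letter are not significantly different at `alpha`.
#'
#' @param data Data frame with a value and a group column.
#' @param value,group Column names (strings).
#' @param alpha Significance threshold for the letter display (default 0.01).
#' @param p_adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   default `"none"` (raw p-values).
#' @return List of class `pairwise_wilcoxon`: `pairs` tibble
#'   (`group1`, `group2`, `p`, `method`), `letters` (named character).
#' @export
pairwise_wilcoxon <- function(data, value, group, alpha = 0.01,
                              p_adjust = "none") {
  vals <- data[[value]]
  grp <- as.character(data[[group]])
  groups <- unique(grp)
  if (length(groups) < 2) abort("need at least 2 groups")
  sizes <- table(grp)
  if (any(sizes < 2)) abort("every group needs at least 2 values")
  if (length(unique(vals)) == 1) {
    warn("all pooled values identical; p = 1 for every pair")
  }
  pairs <- combn(groups, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- vals[grp == g1]; y <- vals[grp == g2]
    if (length(unique(c(x, y))) == 1) {
      tibble::tibble(group1 = g1, group2 = g2, p = 1, method = "degenerate")
    } else if (length(x) <= 10 && length(y) <= 10) {
      tibble::tibble(group1 = g1, group2 = g2, p = wilcox_exact_p(x, y),
                     method = "exact")
    } else {
      tibble::tibble(group1 = g1, group2 = g2, p = wilcox_normal_p(x, y),
                     method = "normal")
    }
  })
  res$p <- stats::p.adjust(res$p, method = p_adjust)
  ns <- matrix(TRUE, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_len(nrow(res))) {
    sig <- res$p[i] < alpha
    ns[res$group1[i], res$group2[i]] <- !sig
    ns[res$group2[i], res$group1[i]] <- !sig
  }
  structure(list(pairs = res, letters = letter_groups(groups, ns),
                 alpha = alpha),
            class = "pairwise_wilcoxon")
}

#' Cross-microbiome similarity along the loading gradient
#'
#' Pairs every sample of source `source_a` with every sample of source
#' `source_b` *at the same loading level*, computes similarity as 1 minus
#' Bray-Curtis dissimilarity, and models similarity against loading with
#' (i) ordinary least squares and (ii) a penalized cubic-regression-spline
#' smoother ([mgcv::gam()], GCV-selected smoothness), plus an F-type test of
#' the smooth against the linear model.
#'
#' @param counts Count table holding both sources.
#' @param meta Sample metadata (provides `source`, `loading_g`, `treatment`).
#' @param source_a,source_b Source labels to pair.
#' @param within_treatment If `TRUE`, only pair samples with identical
#'   treatment.
#' @return List of class `similarity_fit`: `pairs` tibble (`loading_g`,
#'   `source_pair`, `similarity`, `treatment_pair`), `slope`, `r_squared`,
#'   `smooth_edf`, `f_smooth_vs_linear`, `p_smooth_vs_linear`, and the two
#'   fitted models.
#' @export
similarity_vs_loading <- function(counts, meta, source_a, source_b,
                                  within_treatment = FALSE) {
  aligned <- join_metadata(counts, meta)
  m <- aligned$metadata
  ia <- which(m$source == source_a)
  ib <- which(m$source == source_b)
  shared <- intersect(unique(m$loading_g[ia]), unique(m$loading_g[ib]))
  if (length(shared) < 3) {
    abort("sources share fewer than 3 loading levels")
  }
  d <- as.matrix(bray_curtis(aligned$counts))
  rows <- list()
  for (i in ia) {
    for (j in ib) {
      if (m$loading_g[i] != m$loading_g[j]) next
      if (within_treatment && m$treatment[i] != m$treatment[j]) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        loading_g = m$loading_g[i],
        source_pair = paste(source_a, source_b, sep = "-"),
        similarity = 1 - d[m$sample_id[i], m$sample_id[j]],
        treatment_pair = paste(sort(c(m$treatment[i], m$treatment[j])),
                               collapse = "-"))
    }
  }
  pairs <- dplyr::bind_rows(rows)
  fit_lin <- mgcv::gam(similarity ~ loading_g, data = pairs)
  k_basis <- min(10, length(unique(pairs$loading_g)))
  fit_sm <- mgcv::gam(similarity ~ s(loading_g, bs = "cr", k = k_basis),
                      data = pairs)
  cmp <- stats::anova(fit_lin, fit_sm, test = "F")
  f_stat <- cmp$F[2]
  p_sm <- cmp$`Pr(>F)`[2]
  structure(list(
    pairs = pairs,
    slope = unname(stats::coef(fit_lin)["loading_g"]),
    r_squared = summary(fit_lin)$r.sq,
    smooth_edf = sum(fit_sm$edf) - 1,
    f_smooth_vs_linear = if (is.null(f_stat)) NA_real_ else f_stat,
    p_smooth_vs_linear = if (is.null(p_sm)) NA_real_ else p_sm,
    linear_model = fit_lin, smooth_model = fit_sm
  ), class = "similarity_fit")
}
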