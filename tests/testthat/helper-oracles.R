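# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# random sample-by-taxon count table
random_count_table <- function(n_samples, n_taxa, seed, max_count = 50) {
  withr::with_seed(seed, {
    mat <- matrix(rpois(n_samples * n_taxa, lambda = max_count / 5),
                  nrow = n_samples,
                  dimnames = list(paste0("s", seq_len(n_samples)),
                                  paste0("t", seq_len(n_taxa))))
    mat[1, ] <- mat[1, ] + 1  # guarantee positive rows
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(mat)),
                     tibble::as_tibble(mat))
  })
}

# two-group PERMANOVA pseudo-F from within-group pair sums (textbook
# within/between decomposition, no projection matrices)
bf_two_group_f <- function(d, groups) {
  m <- as.matrix(d)^2
  n <- nrow(m)
  ss_total <- sum(m[upper.tri(m)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- m[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  k <- length(unique(groups))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# exhaustive two-group permutation p: enumerate every assignment of group-1
# membership and count pseudo-F values at or above the observed one
bf_two_group_p <- function(d, groups) {
  n <- length(groups)
  g1 <- unique(groups)[1]
  n1 <- sum(groups == g1)
  f_obs <- bf_two_group_f(d, groups)
  sets <- utils::combn(n, n1)
  f_all <- apply(sets, 2, function(idx) {
    g <- rep("b", n)
    g[idx] <- "a"
    bf_two_group_f(d, g)
  })
  list(f = f_obs, p = mean(f_all >= f_obs - 1e-12))
}

# all n! permutations of 1:n as an index matrix (for exhaustive PERMANOVA)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  cols <- vector("list", n * ncol(sub))
  k <- 1
  for (j in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      cols[[k]] <- append(sub[, j], n, after = pos - 1)
      k <- k + 1
    }
  }
  do.call(cbind, cols)
}

# OLS R^2 by explicit normal equations (independent of qr-based env_fit)
ols_r2_oracle <- function(scores, v) {
  x <- cbind(1, scores)
  beta <- solve(t(x) %*% x, t(x) %*% v)
  fitted <- x %*% beta
  1 - sum((v - fitted)^2) / sum((v - mean(v))^2)
}

# Procrustes error after optimal rotation/reflection + translation
procrustes_error <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(t(yc) %*% xc)
  rot <- s$u %*% t(s$v)
  sqrt(sum((xc - yc %*% rot)^2))
}
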