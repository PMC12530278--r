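sym01 <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    m
  })
}

test_that("plasticity is zero when gene and proteome dissimilarities agree", {
  d <- sym01(6, 1)
  expect_true(all(genomic_plasticity(d, d)$plasticity == 0))
})

test_that("plasticity matches the hand-worked 3-taxon case and is linear", {
  dg <- matrix(c(0, 0.2, 0.4,
                 0.2, 0, 0.3,
                 0.4, 0.3, 0), 3, dimnames = list(paste0("t", 1:3),
                                                  paste0("t", 1:3)))
  dp <- matrix(c(0, 0.1, 0.1,
                 0.1, 0, 0.3,
                 0.1, 0.3, 0), 3, dimnames = dimnames(dg))
  pl <- genomic_plasticity(dg, dp)
  expect_equal(pl$plasticity[1], mean(c(0.2 - 0.1, 0.4 - 0.1)))  # 0.2
  # scaling both matrices scales every plasticity by the same factor
  pl3 <- genomic_plasticity(3 * dg, 3 * dp)
  expect_equal(pl3$plasticity, 3 * pl$plasticity, tolerance = 1e-12)
  # sign flip and absolute-value variants
  expect_equal(genomic_plasticity(dg, dp, sign = "proteome_minus_gene")$plasticity,
               -pl$plasticity)
  expect_equal(genomic_plasticity(dp, dg, absolute = TRUE)$plasticity,
               genomic_plasticity(dg, dp, absolute = TRUE)$plasticity)
})

test_that("vectorized plasticity equals a per-pair loop oracle", {
  dg <- sym01(9, 2)
  dp <- sym01(9, 3)
  pl <- genomic_plasticity(dg, dp)$plasticity
  loop <- vapply(1:9, function(i) {
    acc <- 0
    for (j in setdiff(1:9, i)) acc <- acc + (dg[i, j] - dp[i, j])
    acc / 8
  }, numeric(1))
  expect_equal(pl, loop, tolerance = 1e-12)
  expect_error(genomic_plasticity(dg, sym01(5, 4)), "differ in size")
})

test_that("community-weighted means interpolate member traits", {
  traits <- tibble::tibble(taxon_id = c("t1", "t2", "t3"),
                           genome_size_bp = c(2e6, 4e6, 6e6),
                           n_coding_sequences = c(2000, 4000, 6000),
                           doubling_time_h = c(2, 4, 8))
  tab <- tibble::tibble(sample_id = c("only_t1", "even_12", "mix"),
                        t1 = c(10, 5, 1), t2 = c(0, 5, 2), t3 = c(0, 0, 7))
  cwm <- community_weighted_traits(tab, traits)
  expect_equal(cwm$cwm_genome_size_bp, c(2e6, 3e6, (2 + 8 + 42) / 10 * 1e6))
  expect_equal(cwm$cwm_growth_rate[1], log(2) / 2)
  expect_equal(cwm$coverage_genome_size_bp, c(1, 1, 1))
  # bounded by member extremes
  for (col in c("cwm_genome_size_bp", "cwm_growth_rate")) {
    expect_true(all(cwm[[col]] >= min(cwm[[col]]) - 1e-12))
  }
  expect_true(all(cwm$cwm_genome_size_bp >= 2e6 &
                    cwm$cwm_genome_size_bp <= 6e6))
})

test_that("CWM renormalizes over trait-complete taxa and reports coverage", {
  traits <- tibble::tibble(taxon_id = c("t1", "t2", "t3"),
                           genome_size_bp = c(2e6, NA, 6e6))
  tab <- tibble::tibble(sample_id = c("a", "b"),
                        t1 = c(3, 0), t2 = c(1, 4), t3 = c(0, 4))
  cwm <- community_weighted_traits(tab, traits)
  expect_equal(cwm$cwm_genome_size_bp, c(2e6, 6e6))
  expect_equal(cwm$coverage_genome_size_bp, c(3 / 4, 4 / 8))
  only_na <- tibble::tibble(sample_id = "x", t2 = 5)
  expect_warning(out <- community_weighted_traits(only_na, traits),
                 "no counts on trait-complete taxa|no taxon")
  expect_true(is.na(out$cwm_genome_size_bp))
})

test_that("CWM lies within member trait extremes on random instances", {
  withr::with_seed(43, {
    for (i in 1:5) {
      tab <- random_count_table(6, 10, seed = i + 70)
      traits <- tibble::tibble(taxon_id = paste0("t", 1:10),
                               genome_size_bp = runif(10, 2e6, 8e6))
      cwm <- community_weighted_traits(tab, traits)
      expect_true(all(cwm$cwm_genome_size_bp >= min(traits$genome_size_bp)))
      expect_true(all(cwm$cwm_genome_size_bp <= max(traits$genome_size_bp)))
    }
  })
})

test_that("pathway abundance equals the brute-force double loop", {
  tab <- random_count_table(5, 8, seed = 80)
  inc <- withr::with_seed(81, matrix(rbinom(6 * 8, 1, 0.4), 6,
                                     dimnames = list(paste0("p", 1:6),
                                                     paste0("t", 1:8))))
  inc[1, ] <- 1  # one universal pathway
  inc[2, ] <- c(1, rep(0, 7))
  if (any(rowSums(inc) == 0)) inc[rowSums(inc) == 0, 1] <- 1
  pa <- pathway_abundance(tab, inc)
  mat <- count_matrix(tab)
  for (p in rownames(inc)) {
    for (s in rownames(mat)) {
      acc <- 0
      for (t in colnames(mat)) acc <- acc + inc[p, t] * mat[s, t]
      expect_equal(pa[[s]][pa$pathway_id == p], acc)
    }
  }
  # universal pathway equals sample depth
  expect_equal(unlist(pa[pa$pathway_id == "p1", rownames(mat)]),
               rowSums(mat), ignore_attr = TRUE)
  # empty pathway excluded with warning
  inc0 <- rbind(inc, p_empty = 0)
  expect_warning(pa0 <- pathway_abundance(tab, inc0), "p_empty")
  expect_false("p_empty" %in% pa0$pathway_id)
})

test_that("differential pathways recover a constructed log2 slope", {
  n <- 30
  loading <- rep(seq(0, 400, length.out = 15), 2)
  xs <- as.numeric(scale(loading))
  withr::with_seed(47, {
    signal <- 2^(3 * xs + rnorm(n, 0, 0.05)) * 500
    flat <- 2^(rnorm(n, 0, 0.05)) * 300
    down <- 2^(-2.5 * xs + rnorm(n, 0, 0.05)) * 400
  })
  pw <- dplyr::bind_cols(
    tibble::tibble(pathway_id = c("up", "flat", "down"),
                   n_member_taxa = c(8L, 9L, 4L)),
    tibble::as_tibble(matrix(round(rbind(signal, flat, down)), 3,
                             dimnames = list(NULL, paste0("s", 1:n)))))
  res <- differential_pathways(pw, loading, n_perm = 199, seed = 1)
  expect_equal(res$log2fc[res$pathway_id == "up"], 3, tolerance = 0.5)
  expect_lt(res$p[res$pathway_id == "up"], 0.01)
  expect_true(res$passes_filters[res$pathway_id == "up"])
  expect_false(res$passes_filters[res$pathway_id == "flat"])
  # strong signal but only 4 member taxa: fails the >= 5 taxa filter
  expect_lt(res$p[res$pathway_id == "down"], 0.01)
  expect_gt(abs(res$log2fc[res$pathway_id == "down"]), 2)
  expect_false(res$passes_filters[res$pathway_id == "down"])
})

test_that("the filter flag matches a brute-force three-clause check", {
  withr::with_seed(53, {
    pw <- dplyr::bind_cols(
      tibble::tibble(pathway_id = paste0("p", 1:40),
                     n_member_taxa = sample(1:12, 40, replace = TRUE)),
      tibble::as_tibble(matrix(rpois(40 * 12, 60), 40,
                               dimnames = list(NULL, paste0("s", 1:12)))))
  })
  loading <- rep(c(0, 50, 100, 200, 300, 400), 2)
  res <- differential_pathways(pw, loading, n_perm = 99, seed = 2)
  manual <- !res$skipped & res$p < 0.01 & abs(res$log2fc) > 2 &
    res$n_member_taxa >= 5
  manual[is.na(manual)] <- FALSE
  expect_equal(res$passes_filters, manual)
  # constant rows are skipped, not tested
  pw$s1[1] <- pw$s2[1]
  pwc <- pw
  pwc[1, paste0("s", 1:12)] <- as.list(rep(100, 12))
  resc <- differential_pathways(pwc, loading, n_perm = 19, seed = 3)
  expect_true(resc$skipped[1])
  expect_true(is.na(resc$p[1]))
})

test_that("early/late categorization partitions the union", {
  early <- paste0("p", 1:19)
  late <- c(paste0("p", 15:19), paste0("q", 1:6))  # overlap of 5
  cat <- categorize_pathways(early, late)
  counts <- attr(cat, "counts")
  expect_equal(unname(counts["only_early"]), 14L)
  expect_equal(unname(counts["only_late"]), 6L)
  expect_equal(unname(counts["both"]), 5L)
  expect_equal(unname(counts["total"]), 25L)
  expect_equal(sum(counts[c("only_early", "only_late", "both")]),
               length(union(early, late)))
})
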