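test_that("Bray-Curtis hand cases and metric properties hold", {
  tab <- tibble::tibble(sample_id = c("same1", "same2", "disj1", "disj2",
                                      "half1", "half2"),
                        t1 = c(3, 3, 4, 0, 2, 0),
                        t2 = c(1, 1, 2, 0, 2, 2),
                        t3 = c(0, 0, 0, 5, 0, 2))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["same1", "same2"], 0)
  expect_equal(d["disj1", "disj2"], 1)
  expect_equal(d["half1", "half2"], 0.5)  # sum|x-y| / sum(x+y) = 4/8
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("Bray-Curtis on proportions is invariant to common scaling", {
  tab <- random_count_table(5, 8, seed = 2)
  props <- count_matrix(tab) / rowSums(count_matrix(tab))
  d1 <- vegan::vegdist(props, "bray")
  d2 <- vegan::vegdist(props * 1000, "bray")
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
  zero <- tibble::tibble(sample_id = c("a", "b"), t1 = c(1, 0), t2 = c(1, 0))
  expect_error(bray_curtis(zero), "all-zero sample\\(s\\): b")
})

test_that("Shannon matches closed forms and its richness bound", {
  tab <- tibble::tibble(sample_id = c("uniform", "single", "mix"),
                        !!!setNames(as.list(rep(1, 10)), paste0("t", 1:10)))
  tab[2, 2:11] <- as.list(c(7, rep(0, 9)))
  tab[3, 2:11] <- as.list(c(1, 2, 3, rep(0, 7)))
  h <- shannon_index(tab)
  expect_equal(h$shannon[1], log(10), tolerance = 1e-12)
  expect_equal(h$shannon[2], 0)
  expect_equal(h$shannon[3],
               -sum((1:3) / 6 * log((1:3) / 6)), tolerance = 1e-12)
  for (seed in 1:3) {
    rt <- random_count_table(4, 12, seed = seed)
    hs <- shannon_index(rt)$shannon
    rich <- rowSums(count_matrix(rt) > 0)
    expect_true(all(hs <= log(rich) + 1e-12))
  }
})

test_that("rarefaction hits the target depth exactly and never inflates", {
  tab <- random_count_table(6, 10, seed = 4, max_count = 100)
  rare <- rarefy_counts(tab, depth = 40, seed = 1)
  expect_true(all(rowSums(count_matrix(rare)) == 40))
  expect_true(all(count_matrix(rare) <=
                    count_matrix(tab)[rownames(count_matrix(rare)), ]))
  single <- tibble::tibble(sample_id = "s", t1 = 10, t2 = 0, t3 = 0)
  expect_equal(unname(count_matrix(rarefy_counts(single, 5))[1, ]),
               c(5, 0, 0))
  at_depth <- tibble::tibble(sample_id = "s", t1 = 30, t2 = 20)
  expect_equal(count_matrix(rarefy_counts(at_depth, 50)),
               count_matrix(at_depth))
  expect_error(suppressWarnings(rarefy_counts(tab, depth = 1e6)),
               "no sample")
  expect_warning(rarefy_counts(tab, depth = 200, seed = 1), "dropping")
  expect_error(rarefy_counts(tab, depth = 0), "depth")
})

test_that("rarefaction subsampling matches the hypergeometric mean", {
  tab <- tibble::tibble(sample_id = "s", t1 = 60, t2 = 40)
  reps <- 2000
  firsts <- withr::with_seed(99, {
    vapply(seq_len(reps), function(i) {
      count_matrix(rarefy_counts(tab, depth = 50))[1, 1]
    }, numeric(1))
  })
  # draws of 50 from 60/40 without replacement: mean 30, finite-population SE
  se_draw <- sqrt(50 * 0.6 * 0.4 * (100 - 50) / (100 - 1))
  expect_lt(abs(mean(firsts) - 30), 4 * se_draw / sqrt(reps))
})

test_that("exact Wilcoxon matches the reference test on untied data", {
  expect_equal(pairwise_wilcoxon(
    tibble::tibble(v = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3)),
    "v", "g")$pairs$p, 0.1)
  withr::with_seed(31, {
    for (i in 1:20) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      vals <- sample(1000, n1 + n2)  # untied across the pooled sample
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      df <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), c(n1, n2)))
      got <- pairwise_wilcoxon(df, "v", "g")$pairs
      expect_equal(got$method, "exact")
      ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
      expect_equal(got$p, ref, tolerance = 1e-12)
    }
  })
})

test_that("Wilcoxon handles ties, identical groups, and letter grouping", {
  same <- tibble::tibble(v = rep(c(5, 5, 5), 2), g = rep(c("a", "b"), each = 3))
  expect_warning(res <- pairwise_wilcoxon(same, "v", "g"), "identical")
  expect_equal(res$pairs$p, 1)
  expect_equal(unname(res$letters), c("a", "a"))

  three <- tibble::tibble(
    v = c(1, 2, 3, 4, 2, 3, 4, 5, 3, 4, 5, 6),
    g = rep(c("a", "b", "c"), each = 4))
  res3 <- pairwise_wilcoxon(three, "v", "g", alpha = 0.01)
  expect_true(all(res3$pairs$p > 0.01))
  expect_equal(length(unique(res3$letters)), 1)  # one shared letter

  far <- tibble::tibble(
    v = c(rnorm(8), rnorm(8) + 100), g = rep(c("a", "b"), each = 8))
  resf <- pairwise_wilcoxon(far, "v", "g", alpha = 0.01)
  expect_lt(resf$pairs$p, 0.01)
  expect_false(resf$letters[["a"]] == resf$letters[["b"]])
})

test_that("large-sample Wilcoxon uses the tie-corrected normal approximation", {
  withr::with_seed(5, {
    x <- sample(1:5, 30, replace = TRUE)
    y <- sample(3:8, 25, replace = TRUE)
  })
  df <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), c(30, 25)))
  got <- pairwise_wilcoxon(df, "v", "g")$pairs
  expect_equal(got$method, "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(got$p, ref, tolerance = 1e-10)
})

test_that("similarity pairs only form at shared loadings and recover slopes", {
  cfg <- experiment_config(
    n_taxa = 40, depth_mean = 3000, days = 10,
    source_mixing = c(daphnia = 0.15), source_mixing_slope = c(daphnia = 0.002))
  exp <- simulate_experiment(cfg, seed = 21)
  fit <- similarity_vs_loading(exp$counts, exp$metadata, "water", "daphnia")
  meta <- exp$metadata
  loadings_a <- meta$loading_g[meta$source == "water"]
  expect_true(all(fit$pairs$loading_g %in%
                    intersect(loadings_a, meta$loading_g)))
  # mixing weight on water rises with loading -> similarity rises with loading
  expect_gt(fit$slope, 0)
  # each of the 15 loadings occurs twice per source: 15 * 2 * 2 pairs
  expect_equal(nrow(fit$pairs), 60)
})

test_that("constant similarity yields zero slope and no smooth preference", {
  tab <- tibble::tibble(
    sample_id = c(paste0("w", 1:6), paste0("h", 1:6)),
    t1 = rep(c(5, 5), each = 6), t2 = rep(c(3, 3), each = 6))
  meta <- tibble::tibble(
    sample_id = tab$sample_id,
    mesocosm_id = rep(paste0("M", 1:6), 2),
    loading_g = rep(c(0, 50, 100, 200, 300, 400), 2),
    treatment = "unburned", day = 89,
    source = rep(c("water", "daphnia"), each = 6))
  fit <- similarity_vs_loading(tab, meta, "water", "daphnia")
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_true(all(fit$pairs$similarity == 1))
})
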