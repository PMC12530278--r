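test_that("two-group PERMANOVA matches exhaustive enumeration exactly", {
  withr::with_seed(3, {
    for (trial in 1:3) {
      n <- 6
      tab <- random_count_table(n, 9, seed = trial + 50)
      d <- bray_curtis(tab)
      groups <- rep(c("a", "b"), each = 3)
      oracle <- bf_two_group_p(d, groups)
      res <- permanova(d, tibble::tibble(g = groups), terms = "g",
                       permutations = all_permutations(n))
      row <- res$table[res$table$term == "g", ]
      expect_equal(row$F, oracle$f, tolerance = 1e-10)
      expect_equal(row$p, oracle$p, tolerance = 1e-12)
    }
  })
})

test_that("sequential partition conserves sums of squares and R2", {
  withr::with_seed(7, {
    for (trial in 1:4) {
      n <- 24
      tab <- random_count_table(n, 20, seed = trial + 60)
      d <- bray_curtis(tab)
      data <- tibble::tibble(
        f1 = sample(rep(c("x", "y"), length.out = n)),
        f2 = sample(rep(c("p", "q", "r"), length.out = n)),
        cov = rnorm(n))
      res <- permanova(d, data, terms = c("f1", "f2", "cov"), n_perm = 19)
      tab_r <- res$table
      total <- tab_r$SS[tab_r$term == "Total"]
      expect_equal(sum(tab_r$SS[tab_r$term != "Total"]), total,
                   tolerance = 1e-8 * total)
      expect_equal(sum(tab_r$R2[tab_r$term != "Total"]), 1,
                   tolerance = 1e-8)
      expect_equal(tab_r$df[tab_r$term == "f2"], 2)
      expect_equal(tab_r$df[tab_r$term == "cov"], 1)
    }
  })
})

test_that("one-term R2 equals 1 - SSresid/SStotal and p is bounded", {
  tab <- random_count_table(12, 15, seed = 71)
  d <- bray_curtis(tab)
  g <- rep(c("a", "b"), each = 6)
  res <- permanova(d, tibble::tibble(g = g), "g", n_perm = 99, seed = 2)
  t <- res$table
  r2 <- t$R2[t$term == "g"]
  expect_equal(r2, 1 - t$SS[t$term == "Residual"] / t$SS[t$term == "Total"],
               tolerance = 1e-10)
  expect_gte(t$p[t$term == "g"], 1 / 100)
  expect_lte(t$p[t$term == "g"], 1)
})

test_that("sequential SS, R2 and F agree with the vegan reference", {
  tab <- random_count_table(18, 25, seed = 81)
  d <- bray_curtis(tab)
  data <- withr::with_seed(9, tibble::tibble(
    trt = sample(rep(c("u", "v"), 9)),
    load = runif(18, 0, 400),
    day = sample(rep(c("d1", "d2", "d3"), 6))))
  mine <- permanova(d, data, c("trt", "load", "day"), n_perm = 49, seed = 1)
  ref <- vegan::adonis2(d ~ trt + load + day, data = data, by = "terms",
                        permutations = 49)
  expect_equal(mine$table$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(mine$table$R2[1:3], ref$R2[1:3], tolerance = 1e-8)
  expect_equal(mine$table$F[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(mine$table$df[1:3], ref$Df[1:3])
})

test_that("total SS is invariant under sample relabelling", {
  tab <- random_count_table(10, 12, seed = 91)
  d2 <- as.matrix(bray_curtis(tab))^2
  total <- sum(d2[upper.tri(d2)]) / 10
  withr::with_seed(11, {
    for (i in 1:5) {
      idx <- sample(10)
      dp <- d2[idx, idx]
      expect_identical(sum(dp[upper.tri(dp)]) / 10, total)
    }
  })
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- random_count_table(8, 10, seed = 95)
  d <- bray_curtis(tab)
  expect_error(permanova(d, tibble::tibble(g = rep("a", 8)), "g"),
               "single-level")
  dat <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                        g2 = rep(c("a", "b"), each = 4))
  expect_error(permanova(d, dat, c("g", "g2")), "confounded")
  expect_error(permanova(d, tibble::tibble(g = c("a", rep("b", 7))), "g"),
               "fewer than 2")
})

test_that("threshold scan finds the argmax and breaks ties downward", {
  # three clusters along loading; the true split is between 100 and 200
  withr::with_seed(13, {
    base <- matrix(rpois(4 * 12, 20), 4)
    shift <- matrix(rpois(8 * 12, 20), 8)
    shift[, 1:6] <- shift[, 1:6] + 40
    mat <- rbind(base, shift)
    rownames(mat) <- paste0("s", 1:12)
    colnames(mat) <- paste0("t", 1:12)
  })
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(mat)),
                          tibble::as_tibble(mat))
  loading <- c(rep(c(0, 100), each = 2), rep(c(200, 400), each = 4))
  scan <- threshold_scan(bray_curtis(tab), loading, n_perm = 99, seed = 3)
  expect_equal(scan$best_threshold, 100)
  expect_equal(scan$best_r2, max(scan$profile$r2))
  expect_true(all(scan$profile$threshold < max(loading)))
  # exact ties: duplicated samples at two loadings produce identical splits
  d_tie <- matrix(c(0, 0, 1, 1,
                    0, 0, 1, 1,
                    1, 1, 0, 0,
                    1, 1, 0, 0), 4)
  scan_tie <- threshold_scan(d_tie, c(10, 10, 20, 20), n_perm = 19, seed = 1)
  expect_equal(scan_tie$best_threshold, 10)
})

test_that("threshold-scan profile ignores sample order", {
  tab <- random_count_table(12, 10, seed = 101)
  loading <- rep(c(0, 50, 100, 200, 300, 400), each = 2)
  d <- as.matrix(bray_curtis(tab))
  s1 <- threshold_scan(d, loading, n_perm = 19, seed = 5)
  idx <- withr::with_seed(6, sample(12))
  s2 <- threshold_scan(d[idx, idx], loading[idx], n_perm = 19, seed = 5)
  expect_equal(s1$profile$r2, s2$profile$r2, tolerance = 1e-12)
  expect_equal(s1$best_threshold, s2$best_threshold)
})

test_that("threshold-scan one-split statistics equal the full PERMANOVA", {
  tab <- random_count_table(10, 12, seed = 111)
  d <- bray_curtis(tab)
  loading <- rep(c(0, 100, 200, 300, 400), each = 2)
  scan <- threshold_scan(d, loading, n_perm = 199, seed = 7)
  for (t in scan$profile$threshold) {
    g <- ifelse(loading <= t, "low", "high")
    full <- permanova(d, tibble::tibble(g = g), "g", n_perm = 199, seed = 7)
    expect_equal(scan$profile$r2[scan$profile$threshold == t],
                 full$table$R2[1], tolerance = 1e-10)
    expect_equal(scan$profile$f[scan$profile$threshold == t],
                 full$table$F[1], tolerance = 1e-10)
  }
})

test_that("strata restrict permutations to within-mesocosm relabelling", {
  tab <- random_count_table(12, 10, seed = 121)
  d <- bray_curtis(tab)
  strata <- rep(paste0("M", 1:4), each = 3)
  g <- rep(c("a", "b", "c"), 4)
  res <- permanova(d, tibble::tibble(g = g), "g", n_perm = 49, seed = 9,
                   strata = strata)
  expect_s3_class(res, "permanova")
  expect_true(res$table$p[1] >= 1 / 50 && res$table$p[1] <= 1)
})
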