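#' First principal coordinate of the environment
#'
#' Standardizes the nine environmental variables (mean 0, SD 1; zero-variance
#' variables are dropped with a warning), computes Euclidean distances
#' between samples, and returns the first principal-coordinate axis --
#' equivalent to the first principal component of the standardized data. If
#' a loading vector is given, the axis is oriented so its correlation with
#' loading is non-negative.
#'
#' @param env Environment table (`sample_id` + the nine variables).
#' @param loading Optional loading per sample, used to orient the axis.
#' @return Tibble with `sample_id` and `pc1`; the attribute
#'   `"variance_explained"` holds the fraction of total variance on the axis.
#' @export
environment_pc1 <- function(env, loading = NULL) {
  env <- tibble::as_tibble(env)
  vars <- intersect(env_variables(), names(env))
  if (length(vars) == 0) abort("no environmental variables found")
  x <- as.matrix(env[vars])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping zero-variance variable(s): ",
                paste(vars[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  d <- dist(z)
  attr(d, "Labels") <- as.character(env$sample_id)
  ord <- ord_pcoa(d, k = 1)
  if (!is.null(loading)) ord <- orient_axes(ord, loading)
  out <- tibble::tibble(sample_id = as.character(env$sample_id),
                        pc1 = unname(ord$scores[, 1]))
  pos <- ord$eigenvalues[ord$eigenvalues > 0]
  attr(out, "variance_explained") <- pos[1] / sum(pos)
  out
}

#' Ordinary least-squares linear fit
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must not be constant.
#' @return A `linear_fit`: `intercept`, `slope`, `rss`, `df_residual`
#'   (`n - 2`), `fitted`, and the data.
#' @export
fit_linear <- function(x, y) {
  if (length(x) < 3) abort("need at least 3 points")
  if (sd(x) == 0) abort("constant x in fit_linear()")
  fit <- lm.fit(cbind(`(Intercept)` = 1, x = x), y)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 rss = sum(fit$residuals^2),
                 df_residual = length(x) - 2L,
                 fitted = fit$fitted.values, x = x, y = y),
            class = "linear_fit")
}

# RSS of the hinge basis {1, x, (x - c)+} at candidate c
hinge_rss <- function(x, y, c) {
  fit <- lm.fit(cbind(1, x, pmax(x - c, 0)), y)
  sum(fit$residuals^2)
}

# golden-section minimization of f on [lo, hi]
golden_section <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol * max(1, abs(a) + abs(b))) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Single-breakpoint piecewise-linear fit
#'
#' Fits `y ~ 1 + x + (x - c)+` over a grid of candidate breakpoints (by
#' default every interior observed `x` with at least two points strictly on
#' each side), then refines the best candidate by golden-section search
#' between its neighboring grid points. The estimate is the global RSS
#' minimizer over the searched interval -- a deterministic, derivative-free
#' alternative to iterative-linearization breakpoint estimators. The
#' breakpoint counts as a consumed parameter, so the residual degrees of
#' freedom are `n - 4`.
#'
#' @param x,y Numeric vectors, `n >= 5`.
#' @param grid Optional candidate breakpoints; defaults to the admissible
#'   interior observed values.
#' @return A `breakpoint_fit`: `intercept`, `slope_below`, `slope_above`,
#'   `breakpoint`, `rss`, `df_residual` (`n - 4`), `fitted`, data.
#' @export
fit_breakpoint <- function(x, y, grid = NULL) {
  n <- length(x)
  if (n < 5) abort("need at least 5 points for a breakpoint fit")
  if (is.null(grid)) {
    ux <- sort(unique(x))
    grid <- ux[vapply(ux, function(c) {
      sum(x < c) >= 2 && sum(x > c) >= 2
    }, logical(1))]
  } else {
    grid <- sort(grid)
    ok <- vapply(grid, function(c) sum(x < c) >= 2 && sum(x > c) >= 2,
                 logical(1))
    grid <- grid[ok]
  }
  if (length(grid) == 0) abort("no admissible breakpoint candidate")
  rss_grid <- vapply(grid, function(c) hinge_rss(x, y, c), numeric(1))
  i <- which.min(rss_grid)
  lo <- if (i > 1) grid[i - 1] else grid[i]
  hi <- if (i < length(grid)) grid[i + 1] else grid[i]
  bp <- if (lo < hi) {
    golden_section(function(c) hinge_rss(x, y, c), lo, hi)
  } else {
    grid[i]
  }
  # keep whichever of the refined and grid optimum is better
  if (hinge_rss(x, y, grid[i]) < hinge_rss(x, y, bp)) bp <- grid[i]
  fit <- lm.fit(cbind(1, x, pmax(x - bp, 0)), y)
  cf <- fit$coefficients
  structure(list(intercept = unname(cf[1]),
                 slope_below = unname(cf[2]),
                 slope_above = unname(cf[2] + cf[3]),
                 breakpoint = bp,
                 rss = sum(fit$residuals^2),
                 df_residual = n - 4L,
                 fitted = fit$fitted.values, x = x, y = y),
            class = "breakpoint_fit")
}

#' Compare a linear and a piecewise-linear fit by ANOVA
#'
#' `F = ((RSS_linear - RSS_piecewise) / 2) / (RSS_piecewise / (n - 4))`,
#' referred to an F(2, n - 4) distribution: the piecewise model spends two
#' extra parameters (the slope change and the breakpoint position). The
#' piecewise model is selected when `p < alpha`. Because the breakpoint is
#' profiled out, the F reference is approximate and mildly liberal; the
#' selection rate under a truly linear null is therefore a reported
#' diagnostic, not an exact size.
#'
#' @param linear A `linear_fit`.
#' @param piecewise A `breakpoint_fit` on the same data.
#' @param alpha Selection threshold (default 0.01).
#' @return A `model_comparison`: `f`, `df1` (2), `df2`, `p`, `selected`.
#' @export
compare_models <- function(linear, piecewise, alpha = 0.01) {
  if (!isTRUE(all.equal(linear$x, piecewise$x)) ||
      !isTRUE(all.equal(linear$y, piecewise$y))) {
    abort("fits must be on identical data")
  }
  if (piecewise$rss > linear$rss + 1e-8 * max(1, linear$rss)) {
    abort("internal error: piecewise RSS exceeds linear RSS")
  }
  df2 <- piecewise$df_residual
  # RSS differences at rounding-noise scale (relative to the response's
  # total variation) carry no evidence for the extra parameters
  tss <- sum((linear$y - mean(linear$y))^2)
  tol <- 1e-12 * max(tss, .Machine$double.xmin)
  num <- max(0, (linear$rss - piecewise$rss) / 2)
  if (num < tol) num <- 0
  den <- piecewise$rss / df2
  f <- if (num == 0) 0 else if (den == 0) Inf else num / den
  p <- pf(f, 2, df2, lower.tail = FALSE)
  structure(list(f = f, df1 = 2L, df2 = df2, p = p,
                 selected = if (p < alpha) "piecewise" else "linear",
                 alpha = alpha),
            class = "model_comparison")
}

#' Linear-vs-piecewise breakpoint analysis of a response along a gradient
#'
#' Convenience wrapper fitting both models and running the selection rule.
#'
#' @param x,y Numeric vectors.
#' @param alpha Selection threshold (default 0.01).
#' @return List of class `breakpoint_analysis`: `linear`, `piecewise`,
#'   `comparison`.
#' @export
breakpoint_analysis <- function(x, y, alpha = 0.01) {
  lin <- fit_linear(x, y)
  pw <- fit_breakpoint(x, y)
  structure(list(linear = lin, piecewise = pw,
                 comparison = compare_models(lin, pw, alpha)),
            class = "breakpoint_analysis")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g -> %s (alpha = %g)\n",
              x$df1, x$df2, x$f, x$p, x$selected, x$alpha))
  invisible(x)
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "Piecewise fit: breakpoint %.4g, slopes %.4g / %.4g, RSS %.4g (df %d)\n",
    x$breakpoint, x$slope_below, x$slope_above, x$rss, x$df_residual))
  invisible(x)
}
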