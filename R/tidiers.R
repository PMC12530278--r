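#' Tidy a PERMANOVA result
#'
#' @param x A `permanova` object.
#' @param ... Unused.
#' @return Tibble with `term`, `df`, `SS`, `R2`, `F`, `p` including the
#'   residual and total rows.
#' @method tidy permanova
#' @export
tidy.permanova <- function(x, ...) x$table

#' @rdname tidy.permanova
#' @method glance permanova
#' @export
glance.permanova <- function(x, ...) {
  tot <- x$table[x$table$term == "Total", ]
  tibble::tibble(n = x$n, total_SS = tot$SS, n_perm = x$n_perm,
                 exhaustive = x$exhaustive)
}

#' Tidy a threshold scan
#'
#' @param x A `threshold_scan`.
#' @param ... Unused.
#' @return The full R-squared/p profile over candidate thresholds.
#' @method tidy threshold_scan
#' @export
tidy.threshold_scan <- function(x, ...) x$profile

#' @rdname tidy.threshold_scan
#' @method glance threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble::tibble(best_threshold = x$best_threshold, best_r2 = x$best_r2,
                 best_p = x$best_p, tie = x$tie,
                 best_p_corrected = x$best_p_corrected %||% NA_real_)
}

#' Tidy an ordination
#'
#' @param x An `ordination`.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per axis.
#' @method tidy ordination
#' @export
tidy.ordination <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids),
                   tibble::as_tibble(x$scores))
}

#' @rdname tidy.ordination
#' @method glance ordination
#' @export
glance.ordination <- function(x, ...) {
  if (x$method == "pcoa") {
    pos <- x$eigenvalues[x$eigenvalues > 0]
    k <- ncol(x$scores)
    tibble::tibble(method = "pcoa", k = k,
                   prop_explained = sum(x$eigenvalues[seq_len(k)]) / sum(pos),
                   n_negative_eigenvalues = sum(x$eigenvalues < 0))
  } else {
    tibble::tibble(method = "nmds", k = ncol(x$scores), stress = x$stress,
                   iterations = length(x$stress_trace) - 1L,
                   converged = isTRUE(x$converged))
  }
}

#' Tidy a breakpoint fit
#'
#' @param x A `breakpoint_fit`.
#' @param ... Unused.
#' @return One-row tibble of the fitted parameters.
#' @method tidy breakpoint_fit
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope_below = x$slope_below,
                 slope_above = x$slope_above, breakpoint = x$breakpoint,
                 rss = x$rss, df_residual = x$df_residual)
}

#' Tidy a linear-vs-piecewise model comparison
#'
#' @param x A `model_comparison` or `breakpoint_analysis`.
#' @param ... Unused.
#' @return One-row tibble with the F statistic, degrees of freedom, p and
#'   the selected model.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::tibble(f = x$f, df1 = x$df1, df2 = x$df2, p = x$p,
                 selected = x$selected, alpha = x$alpha)
}

#' @rdname tidy.model_comparison
#' @method glance breakpoint_analysis
#' @export
glance.breakpoint_analysis <- function(x, ...) {
  dplyr::bind_cols(tidy(x$comparison),
                   tibble::tibble(breakpoint = x$piecewise$breakpoint,
                                  rss_linear = x$linear$rss,
                                  rss_piecewise = x$piecewise$rss))
}

#' Plot the R-squared profile of a threshold scan
#'
#' @param object A `threshold_scan`.
#' @param ... Unused.
#' @return A ggplot: R-squared against candidate threshold with the best
#'   threshold marked.
#' @method autoplot threshold_scan
#' @export
autoplot.threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$threshold, y = .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "loading threshold (g)",
                  y = expression(PERMANOVA ~ R^2),
                  title = sprintf("Best threshold: %g g",
                                  object$best_threshold)) +
    ggplot2::theme_minimal()
}

#' Plot ordination scores
#'
#' @param object An `ordination`.
#' @param colour Optional vector (one value per sample) mapped to colour,
#'   e.g. loading.
#' @param ... Unused.
#' @return A ggplot of the first two axes.
#' @method autoplot ordination
#' @export
autoplot.ordination <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  axes <- setdiff(names(df), "sample_id")[1:2]
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                        y = .data[[axes[2]]])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = "loading (g)")
  }
}

#' Plot a breakpoint analysis
#'
#' @param object A `breakpoint_analysis`.
#' @param ... Unused.
#' @return A ggplot of the data with the linear and piecewise fits.
#' @method autoplot breakpoint_analysis
#' @export
autoplot.breakpoint_analysis <- function(object, ...) {
  pw <- object$piecewise
  df <- tibble::tibble(x = pw$x, y = pw$y, fitted_pw = pw$fitted,
                       fitted_lin = object$linear$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_lin),
                       colour = "grey50", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_pw),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = pw$breakpoint, linetype = "dotted") +
    ggplot2::labs(title = sprintf("%s selected (p = %.3g)",
                                  object$comparison$selected,
                                  object$comparison$p)) +
    ggplot2::theme_minimal()
}

#' Plot differential pathway results
#'
#' @param object A `differential_pathways` tibble.
#' @param ... Unused.
#' @return A ggplot of log2 fold change per pathway, passing pathways
#'   highlighted.
#' @method autoplot differential_pathways
#' @export
autoplot.differential_pathways <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$skipped)
  df <- dplyr::arrange(df, .data$log2fc)
  df$pathway_id <- factor(df$pathway_id, levels = df$pathway_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$pathway_id,
                                   colour = .data$passes_filters)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change per SD loading", y = NULL,
                  colour = "passes filters") +
    ggplot2::theme_minimal()
}
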