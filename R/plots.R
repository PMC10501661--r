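#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the rank-similarity statistics and fitted thresholds
#'
#' Histogram of the per-taxon statistics M_j with the candidate-set threshold
#' gamma (dashed) and the fitted misclassification-controlled threshold T-hat
#' (solid); taxa to the right of T-hat form the reference set.
#'
#' @param object A `rsim_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rsim_fit <- function(object, ...) {
  ggplot2::ggplot(object$stats, ggplot2::aes(x = .data$m)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$gamma, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$t_hat) +
    ggplot2::labs(
      x = "median pairwise Spearman correlation (M)",
      y = "taxa",
      title = sprintf("Reference selection: |ref| = %d, T = %.3f, pi0 = %.2f",
                      length(object$reference_set), object$t_hat, object$pi0_hat)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of estimated size factors against planted sampling fractions
#'
#' @param comparison Output of [compare_size_factors()].
#' @return A ggplot with the identity line; points coloured by group when
#'   group labels were supplied.
#' @export
plot_size_factor_recovery <- function(comparison) {
  df <- comparison$per_sample
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$estimate))
  p <- if (all(is.na(df$group))) p + ggplot2::geom_point(alpha = 0.7)
       else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::labs(x = "true sampling fraction", y = "estimated size factor",
                  title = sprintf("RMSE of relative error = %.3f", comparison$rmse)) +
    ggplot2::theme_minimal()
}

#' Ordination plot from PCoA coordinates
#'
#' @param pcoa Output of [pcoa_coordinates()].
#' @param groups Optional per-sample labels (aligned to the coordinate rows).
#' @return A ggplot of the first two axes.
#' @export
plot_pcoa <- function(pcoa, groups = NULL) {
  df <- pcoa$coordinates
  if (ncol(df) < 3) stop("need at least two coordinate axes", call. = FALSE)
  pos <- pcoa$eigenvalues[pcoa$eigenvalues > 0]
  pct <- 100 * pos[1:2] / sum(pos)
  if (!is.null(groups)) df$group <- as.factor(groups)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis_1, y = .data$axis_2))
  p <- if (is.null(groups)) p + ggplot2::geom_point(alpha = 0.7)
       else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  p +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pct[1]),
                  y = sprintf("PCo2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}
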