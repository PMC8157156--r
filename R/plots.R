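# ggplot2 figures for the result types.

#' Plot a random-forest learning curve
#'
#' Cross-validated accuracy against the number of trees, with the selected
#' count marked.
#'
#' @param curve Tibble with `n_trees` and `cv_accuracy` (from
#'   [tune_n_trees()]).
#' @param selected Optional tree count to highlight.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve, selected = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_trees, y = .data$cv_accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of trees", y = "Cross-validated accuracy") +
    ggplot2::theme_minimal()
  if (!is.null(selected)) {
    p <- p + ggplot2::geom_vline(xintercept = selected, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot a confusion matrix as a shaded tile grid
#'
#' Tiles show counts, shaded by the within-actual-level ratio, actual level
#' on rows.
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- confusion_ratios(object)
  df$actual <- factor(df$actual, levels = rev(severity_levels()))
  df$predicted <- factor(df$predicted, levels = severity_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$ratio)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey90", limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted", y = "Actual", fill = "Row ratio") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot random-coefficient distributions of a fitted model
#'
#' Normal density of each random coefficient at its estimated mean and
#' (absolute) standard deviation, with the negative share annotated — the
#' standard visual for interpreting a random parameter's sign split.
#'
#' @param object A `severity_fit` with at least one random term.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.severity_fit <- function(object, ...) {
  td <- tidy(object)
  means <- td[td$kind == "mean", ]
  sds <- td[td$kind == "sd", ]
  if (nrow(means) == 0) abort("Fit has no random coefficients to plot.")
  dfs <- purrr::map2_dfr(seq_len(nrow(means)), means$term, function(i, tm) {
    m <- means$estimate[i]
    s <- sds$estimate[i]
    x <- seq(m - 4 * s, m + 4 * s, length.out = 300)
    tibble::tibble(
      term = sprintf("%s  (%.1f%% negative)", tm, 100 * share_negative(m, s)),
      x = x, density = stats::dnorm(x, m, s)
    )
  })
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "Coefficient value", y = "Density") +
    ggplot2::theme_minimal()
}
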