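#' Plot a block-wise learning curve
#'
#' Group mean success rate per block with SEM ribbons, colored by feedback
#' condition.
#'
#' @param object A [block_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.block_curve <- function(object, ...) {
  g <- group_curve(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$block, y = .data$mean,
                                  color = .data$condition,
                                  fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Block", y = "Mean success rate",
                  color = "Condition", fill = "Condition") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a ROC selectivity curve
#'
#' @param object A [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object with the chance diagonal and the AUC in the
#'   subtitle.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tibble::tibble(fpr = 1 - object$specificity,
                       tpr = object$sensitivity)
  df <- dplyr::bind_rows(tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))[1, ],
                         df[order(df$fpr, df$tpr), ],
                         tibble::tibble(fpr = 1, tpr = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a run's design matrix
#'
#' Regressors as columns, volumes as rows; censored volumes are marked.
#'
#' @param d A `design_matrix`.
#' @return A ggplot object.
#' @export
plot_design <- function(d) {
  long <- as_tibble(d)
  long$regressor <- factor(long$regressor, levels = d$labels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$regressor, y = .data$volume,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = "Volume", fill = "Value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
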