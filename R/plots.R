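#' @import ggplot2
NULL

#' Plot an ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    geom_path(color = "#2166AC", linewidth = 0.8) +
    coord_equal() +
    labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%s ROC, AUC = %.3f, length = %.3f",
                      object$estimator, roc_auc(object), roc_length(object))
    ) +
    theme_minimal()
}

#' Plot the stage counts of a filter trace
#'
#' @param object A `filter_trace`.
#' @param ... Unused.
#' @return A ggplot: surviving protein counts along the cascade.
#' @export
autoplot.filter_trace <- function(object, ...) {
  df <- tidy(object)
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot(df, aes(x = .data$stage, y = .data$n_out)) +
    geom_col(fill = "#2166AC") +
    geom_text(aes(label = .data$n_out), vjust = -0.4, size = 3) +
    labs(x = NULL, y = "Proteins remaining",
         title = "Candidate-selection cascade") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Marker-wise intensity distributions by class
#'
#' Log-scale boxplots of each marker's intensities split by label, the
#' standard first look at a chip panel.
#'
#' @param panel Marker-panel tibble.
#' @param label_col Label column name.
#' @param markers Markers to plot (default: all).
#' @return A ggplot.
#' @export
plot_marker_panel <- function(panel, label_col = "label", markers = NULL) {
  markers <- validate_marker_panel(panel, label_col, markers)
  long <- pivot_longer(panel, all_of(markers),
                       names_to = "marker", values_to = "intensity")
  ggplot(long, aes(x = .data[[label_col]], y = .data$intensity,
                   fill = .data[[label_col]])) +
    geom_boxplot(outlier.size = 0.6, alpha = 0.8) +
    geom_jitter(width = 0.15, size = 0.5, alpha = 0.5) +
    scale_y_log10() +
    facet_wrap(~marker, scales = "free_y") +
    labs(x = NULL, y = "Fluorescence intensity (log scale)") +
    theme_minimal() +
    theme(legend.position = "none")
}
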