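# ggplot2 displays for the main result types.

#' Box plots of multiscale entropy by class
#'
#' One panel per entropy method, scale on the x axis, one box per class —
#' the standard display for comparing multiscale entropy between two
#' groups.
#'
#' @param entropy_feats A feature tibble containing the
#'   `<method>_s<scale>` entropy columns.
#' @return A ggplot object.
#' @export
plot_entropy_profiles <- function(entropy_feats) {
  fn <- feature_names(entropy_feats)
  ent <- fn[grepl("_s[0-9]+$", fn)]
  long <- tidyr::pivot_longer(
    entropy_feats, dplyr::all_of(ent),
    names_to = c("method", "scale"), names_sep = "_s")
  long$scale <- as.integer(long$scale)
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$scale), .data$value,
                                     fill = .data$class_label)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "scale factor s", y = "entropy", fill = "class")
}

#' Importance bar chart of a selection result
#'
#' @param object A `selection_result`.
#' @param top_n Number of features displayed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_result <- function(object, top_n = object$k, ...) {
  td <- utils::head(tidy(object), top_n)
  ggplot2::ggplot(td, ggplot2::aes(.data$importance,
                                   stats::reorder(.data$feature,
                                                  .data$importance),
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance (sums to 1)", y = NULL, fill = "family")
}

#' Per-fold metric display of a cross-validation report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidy(object)
  keep <- c("accuracy", "precision", "recall", "f1", "auc")
  long <- dplyr::filter(long, .data$metric %in% keep)
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$fold))) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "per-fold value", color = "fold")
}

#' Heatmap of the experiment grid
#'
#' Mean metric value per cell of the image-type x feature-set x classifier
#' factorial, one panel per metric; the best image type per feature set
#' and classifier is outlined.
#'
#' @param object An `experiment_result`.
#' @param metrics Metrics to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object,
                                       metrics = c("accuracy", "auc"), ...) {
  g <- dplyr::filter(object$grid, .data$metric %in% metrics)
  ggplot2::ggplot(g, ggplot2::aes(.data$image_type,
                                  paste(.data$feature_set, .data$classifier,
                                        sep = " / "),
                                  fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(g, .data$is_max), fill = NA,
                       color = "black", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean)),
                       size = 3) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "image type", y = NULL, fill = "mean")
}
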