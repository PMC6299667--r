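#' Plot a confusion matrix as a heatmap
#'
#' @param object A `cap_confusion` matrix.
#' @param percent Show column-normalised percentages (default) or raw
#'   counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cap_confusion
#' @export
autoplot.cap_confusion <- function(object, percent = TRUE, ...) {
  df <- tidy.cap_confusion(object)
  df$value <- if (percent) df$percent else df$n
  lab <- if (percent) "% of true class" else "seconds"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$value)),
                       colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "True class", y = "Predicted class", fill = lab) +
    ggplot2::theme_minimal()
}

#' Plot per-fold weighted accuracy of a LOSO evaluation
#'
#' @param object A `cap_loso` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cap_loso
#' @export
autoplot.cap_loso <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy.cap_loso(object), c("wac", "ac"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$mean_wac, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Held-out subject", y = "Accuracy",
                  title = sprintf("Leave-one-subject-out (%s, %s)",
                                  object$task, object$classifier)) +
    ggplot2::theme_minimal()
}

#' Plot the grid-search WAC surface
#'
#' @param object A `cap_grid_search` object (outer protocol).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cap_grid_search
#' @export
autoplot.cap_grid_search <- function(object, ...) {
  df <- object$grid
  ggplot2::ggplot(df, ggplot2::aes(x = factor(log2(.data$C)),
                                   y = factor(log2(.data$gamma)),
                                   fill = .data$wac)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "log2 C", y = "log2 gamma", fill = "WAC") +
    ggplot2::theme_minimal()
}

#' Plot selected feature series over the labelled timeline
#'
#' @param features Tibble from [extract_features()] or
#'   [condition_features()] for one subject.
#' @param labels Matching per-second label tibble (optional; shades
#'   A-phase seconds).
#' @param feature_names Character vector of feature columns to show.
#' @return A ggplot object.
#' @export
plot_feature_timeline <- function(features, labels = NULL,
                                  feature_names = c("MMSD_delta", "ZCR_BB")) {
  df <- tidyr::pivot_longer(
    features[c("second", intersect(feature_names, names(features)))],
    -"second", names_to = "feature", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$second, y = .data$value))
  if (!is.null(labels)) {
    ev <- labels[labels$label != "B", ]
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_rect(
        data = ev,
        ggplot2::aes(xmin = .data$second, xmax = .data$second + 1,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "orange", alpha = 0.25)
    }
  }
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
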