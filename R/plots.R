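#' Plot a recording's six channels
#'
#' Time-series panel per channel (accelerometer in G, gyroscope in dps).
#'
#' @param object A `pd_recording`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot pd_recording
autoplot.pd_recording <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                            names_to = "channel", values_to = "value")
  df$channel <- factor(df$channel, levels = CHANNELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 3, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (G / dps)",
                  title = sprintf("%s - %s (%s)", attr(object, "subject_id"),
                                  attr(object, "task"),
                                  attr(object, "class_label")))
}

#' Plot a Welch PSD estimate
#'
#' @param object A `pd_spectral_estimate`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot pd_spectral_estimate
autoplot.pd_spectral_estimate <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frequency, y = .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (power/Hz)")
}

#' Plot the normalized ANOVA importance scores
#'
#' @param object A `pd_anova_ranking`.
#' @param top_n Show only the `top_n` best-ranked features.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot pd_anova_ranking
autoplot.pd_anova_ranking <- function(object, top_n = 30, ...) {
  df <- head(dplyr::arrange(tibble::as_tibble(object), .data$rank), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$normalized_score,
                                   y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized ANOVA score (F / max F)", y = NULL)
}

#' One-vs-rest ROC curves of an evaluation report
#'
#' @param object A `pd_eval_report` with ROC points.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot pd_eval_report
autoplot.pd_eval_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                           colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}

#' SOM sample-hit counts per neuron
#'
#' @param object A `pd_som_model`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot pd_som_model
autoplot.pd_som_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$neuron),
                                   y = .data$sample_hits,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "neuron", y = "sample hits", fill = "majority class")
}

#' Per-class feature histograms
#'
#' Class-overlap diagnostic: well-separated distributions mean a feature
#' discriminates the groups.
#'
#' @param table A feature table.
#' @param features Character vector of feature names to show.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_feature_histograms <- function(table, features, bins = 15) {
  check_feature_table(table)
  df <- tidyr::pivot_longer(table[c("class_label", features)],
                            -"class_label", names_to = "feature")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   fill = .data$class_label)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, fill = "class")
}
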