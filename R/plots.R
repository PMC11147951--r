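#' Plot a mean profile
#'
#' Line plot of the per-offset mean with the number of contributing intervals
#' as a secondary ribbon of transparency.
#'
#' @param object A [mean_profile][mean_profile].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mean_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from anchor (bp, 5'→3')",
                  y = "mean score") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A [power_spectrum][smoothed_periodogram].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_index, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("frequency (cycles per %d positions)",
                              attr(object, "n_used")),
                  y = "power") +
    ggplot2::theme_minimal()
}

#' Plot per-channel spectral features of one sequence
#'
#' @param object An [nf_features][featurize] tibble.
#' @param ... Unused.
#' @return A ggplot, one panel per DNA shape channel.
#' @export
autoplot.nf_features <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_index, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~shape, scales = "free_y") +
    ggplot2::labs(x = "frequency (cycles per 147 bp)", y = "power") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation metrics
#'
#' Mean with one-SD error bars over folds for the six reported metrics.
#'
#' @param object An [nf_cv][cross_validate].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nf_cv <- function(object, ...) {
  s <- object$summary
  s$metric <- factor(s$metric, levels = s$metric)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "metric (mean ± SD over folds)") +
    ggplot2::theme_minimal()
}

#' Plot the top Gini importances of a model
#'
#' @param model An [nf_model][nf_train].
#' @param top_n Number of features shown.
#' @return A ggplot.
#' @export
plot_importance <- function(model, top_n = 20) {
  imp <- utils::head(feature_importance(model), top_n)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$feature,
                                    fill = .data$shape)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean decrease in Gini impurity", y = NULL,
                  fill = "shape") +
    ggplot2::theme_minimal()
}
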