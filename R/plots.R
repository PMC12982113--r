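#' Plot microstate template topographies
#'
#' Draws each template map as a colour-coded electrode scatter over the
#' montage (a lightweight topographic view: no interpolation, one panel per
#' class).
#'
#' @param object an [ms_templates].
#' @param montage montage tibble with `name`, `x`, `y` (default the built-in
#'   26-channel layout).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ms_templates
#' @export
autoplot.ms_templates <- function(object, montage = montage_1020(), ...) {
  df <- tidy(object) |>
    dplyr::left_join(montage, by = c(channel = "name"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_point(shape = 21, size = 4, colour = "grey30") +
    ggplot2::facet_wrap(~label, nrow = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("%s-level microstate templates",
                                  object$level),
                  fill = "amplitude")
}

#' Plot per-class temporal metrics
#'
#' @param object an `ms_metrics` object from [compute_metrics()].
#' @param ... unused.
#' @return a ggplot object (one panel per metric).
#' @method autoplot ms_metrics
#' @export
autoplot.ms_metrics <- function(object, ...) {
  df <- object$per_class |>
    tidyr::pivot_longer(-"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "microstate class", y = NULL)
}

#' ROC curves with percentile bands across evaluation repetitions
#'
#' Builds per-model ROC curves from the pooled out-of-fold scores of an
#' evaluation report.
#'
#' @param report an `ms_eval_report` from [evaluate_models()].
#' @param models subset of model names (default all).
#' @return a ggplot object.
#' @export
plot_roc <- function(report, models = names(report$scores)) {
  df <- purrr::map_dfr(models, function(m) {
    roc_points(report$scores[[m]], report$labels) |>
      dplyr::mutate(model = m)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tibble::tibble(
    fpr = c(0, cumsum(lab == 0) / sum(lab == 0)),
    tpr = c(0, cumsum(lab == 1) / sum(lab == 1))
  )
}

#' Violin plot of per-subject Shapley values
#'
#' @param object an `ms_shap` from [shap_summary()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ms_shap
#' @export
autoplot.ms_shap <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(feature = factor(.data$feature,
                                   levels = rev(object$ranking$feature)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shap_value, y = .data$feature)) +
    ggplot2::geom_violin(fill = "thistle") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Shapley value (probability scale)", y = NULL)
}
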