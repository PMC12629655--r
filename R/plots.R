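#' ROC curves for a cross-validated fit
#'
#' @param object An `af_cv` object.
#' @param ... Unused.
#' @return A ggplot: ROC curves at the segment and recording level.
#' @export
autoplot.af_cv <- function(object, ...) {
  roc_points <- function(preds, level) {
    ord <- order(preds$prob, decreasing = TRUE)
    y <- preds$y[ord]
    tibble::tibble(
      fpr = c(0, cumsum(y == 0) / sum(y == 0)),
      tpr = c(0, cumsum(y == 1) / sum(y == 1)),
      level = level
    )
  }
  df <- dplyr::bind_rows(
    roc_points(object$predictions, "segment"),
    roc_points(aggregate_to_recording(object), "recording")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$level)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      colour = "Evaluation level", title = "Pre-AF vs NSR discrimination"
    ) +
    ggplot2::theme_minimal()
}

#' Point-range plot of a metric report
#'
#' @param object An `af_metrics` tibble (or stacked reports from
#'   [stratified_report()]).
#' @param ... Unused.
#' @return A ggplot of metric estimates with their bootstrap CIs.
#' @export
autoplot.af_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(.data$estimate, .data$metric,
      xmin = .data$conf_low, xmax = .data$conf_high, colour = .data$level
    )
  ) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Estimate (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(df$stratum) > 1) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' Beeswarm-style summary of Shapley attributions
#'
#' The classic SHAP summary: one jittered row per feature (most important on
#' top), horizontal position the attribution on the margin scale, colour the
#' (within-feature rank-scaled) feature value.
#'
#' @param object An `af_attribution` object.
#' @param top_n Number of features to display (default 10).
#' @param max_points Per-feature subsample cap for plotting (default 1000).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.af_attribution <- function(object, top_n = 10, max_points = 1000, ...) {
  feats <- utils::head(object$summary$feature, top_n)
  dfs <- purrr::map_dfr(feats, function(f) {
    v <- object$values[, f]
    x <- object$feature_values[, f]
    n <- length(v)
    idx <- if (n > max_points) seq(1, n, length.out = max_points) else seq_len(n)
    tibble::tibble(
      feature = f, shap = v[idx],
      value_scaled = (rank(x) / length(x))[idx]
    )
  })
  dfs$feature <- factor(dfs$feature, levels = rev(feats))
  ggplot2::ggplot(
    dfs,
    ggplot2::aes(.data$shap, .data$feature, colour = .data$value_scaled)
  ) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_jitter(height = 0.25, width = 0, alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_gradient(
      low = "#3b4cc0", high = "#b40426", breaks = c(0, 1),
      labels = c("low", "high")
    ) +
    ggplot2::labs(
      x = "Shapley value (margin scale)", y = NULL, colour = "Feature value"
    ) +
    ggplot2::theme_minimal()
}
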