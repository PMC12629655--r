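#' Tidy a cross-validated fit
#'
#' @param x An `af_cv` object.
#' @param level `"segment"` (default), `"window"` or `"recording"`.
#' @param ... Unused.
#' @return A tibble of out-of-fold predictions at the requested level.
#' @export
tidy.af_cv <- function(x, level = c("segment", "window", "recording"), ...) {
  level <- match.arg(level)
  if (level == "segment") {
    return(x$predictions)
  }
  aggregate_to_recording(x, level = level)
}

#' One-row summary of a cross-validated fit
#'
#' @param x An `af_cv` object.
#' @param ... Unused.
#' @return One-row tibble: engine, fold count, segment/recording counts and
#'   AUROC/AUPRC at both evaluation levels.
#' @export
glance.af_cv <- function(x, ...) {
  seg <- x$predictions
  rec <- aggregate_to_recording(x)
  tibble::tibble(
    engine = x$model$engine,
    n_folds = attr(x$plan, "n_folds"),
    n_segments = nrow(seg),
    n_recordings = nrow(rec),
    auroc_segment = auroc_rank(seg$prob, seg$y),
    auprc_segment = auprc_step(seg$prob, seg$y),
    auroc_recording = auroc_rank(rec$prob, rec$y),
    auprc_recording = auprc_step(rec$prob, rec$y)
  )
}

#' Tidy a Shapley attribution
#'
#' @param x An `af_attribution` object.
#' @param ... Unused.
#' @return The per-feature summary tibble (`feature`, `mean_abs_shap`,
#'   `rank`).
#' @export
tidy.af_attribution <- function(x, ...) {
  x$summary
}

#' Tidy an analysis result
#'
#' @param x An `af_analysis` object.
#' @param ... Unused.
#' @return The stacked metric reports at both evaluation levels.
#' @export
tidy.af_analysis <- function(x, ...) {
  dplyr::bind_rows(x$metrics_segment, x$metrics_recording)
}

#' @rdname glance.af_cv
#' @export
glance.af_analysis <- function(x, ...) {
  glance(x$cv)
}
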