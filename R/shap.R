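#' Shapley-value feature attribution
#'
#' Exact per-sample Shapley values for gradient-boosted tree models, via the
#' path-dependent TreeSHAP algorithm (cover-weighted conditional
#' expectations), on the model's margin (log-odds) scale: for every sample
#' the attributions plus the base value reproduce the margin output exactly.
#' Features are ranked by mean absolute attribution.
#'
#' For a cross-validated `af_cv` object, each fold's model attributes its own
#' test segments (with that fold's training-median imputation), so every
#' segment in the cohort is explained exactly once, out of fold.
#'
#' @param object An `af_cv` fitted with the `"gbt"` engine, or an
#'   `xgb.Booster`.
#' @param ds For the `af_cv` method: the `af_dataset` the CV was fitted on.
#'   For a raw booster: a numeric feature matrix.
#' @param ... Unused.
#' @return An `af_attribution` object: list with `summary` (tibble `feature`,
#'   `mean_abs_shap`, `rank`), `values` (samples x features attribution
#'   matrix), `base` (per-sample base value), and `feature_values` (the
#'   matrix the model saw, for beeswarm colouring).
#' @export
shapley_attribution <- function(object, ds, ...) {
  UseMethod("shapley_attribution")
}

xgb_contrib <- function(fit, x) {
  dm <- xgboost::xgb.DMatrix(x, nthread = 1)
  contrib <- predict(fit, dm, predcontrib = TRUE)
  colnames(contrib) <- c(colnames(x), "BIAS")
  contrib
}

finish_attribution <- function(values, base, feature_values) {
  msum <- colMeans(abs(values))
  summary <- tibble::tibble(
    feature = colnames(values), mean_abs_shap = unname(msum)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(
    list(
      summary = summary, values = values, base = base,
      feature_values = feature_values
    ),
    class = "af_attribution"
  )
}

#' @rdname shapley_attribution
#' @export
shapley_attribution.xgb.Booster <- function(object, ds, ...) {
  x <- as.matrix(ds)
  contrib <- xgb_contrib(object, x)
  p <- ncol(contrib) - 1L
  finish_attribution(contrib[, seq_len(p), drop = FALSE], contrib[, p + 1L], x)
}

#' @rdname shapley_attribution
#' @export
shapley_attribution.af_cv <- function(object, ds, ...) {
  if (object$model$engine != "gbt") {
    abort(paste0(
      "Exact Shapley attribution is only available for the 'gbt' engine; ",
      "'", object$model$engine, "' models are unsupported."
    ), class = "afonset_unsupported_model")
  }
  stopifnot(inherits(ds, "af_dataset"))
  x_all <- dataset_feature_matrix(ds, object$model$include_age_sex)
  fold_of <- stats::setNames(object$plan$fold, object$plan$recording_id)
  row_fold <- unname(fold_of[ds$recording_id])
  values <- matrix(NA_real_, nrow(x_all), ncol(x_all),
    dimnames = list(NULL, colnames(x_all))
  )
  base <- rep(NA_real_, nrow(x_all))
  fv <- x_all
  for (m in object$models) {
    test <- which(row_fold == m$fold)
    if (length(test) == 0) next
    xte <- apply_imputer(x_all[test, , drop = FALSE], m$medians)
    contrib <- xgb_contrib(m$fit, xte)
    p <- ncol(contrib) - 1L
    values[test, ] <- contrib[, seq_len(p), drop = FALSE]
    base[test] <- contrib[, p + 1L]
    fv[test, ] <- xte
  }
  finish_attribution(values, base, fv)
}

#' @export
print.af_attribution <- function(x, ...) {
  cat(sprintf(
    "<af_attribution> %d samples x %d features; top features:\n",
    nrow(x$values), ncol(x$values)
  ))
  print(utils::head(x$summary, 5))
  invisible(x)
}
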