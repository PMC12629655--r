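# median imputation: medians learned on training rows only, applied to both;
# a column with no observed training value falls back to 0.
fit_imputer <- function(x) {
  meds <- apply(x, 2, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  meds
}

apply_imputer <- function(x, meds) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- meds[j]
  }
  x
}

dataset_feature_matrix <- function(ds, include_age_sex = FALSE) {
  x <- as.matrix(as.data.frame(ds)[, af_feature_names()])
  if (include_age_sex) {
    x <- cbind(x, age = ds$age, sex_male = as.numeric(ds$sex == "M"))
  }
  storage.mode(x) <- "double"
  x
}

fit_learner <- function(x, y, model, seed) {
  if (model$engine == "gbt") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", max_depth = model$max_depth,
        eta = model$eta, nthread = 1, seed = seed
      ),
      data = dtrain, nrounds = model$nrounds, verbose = 0
    )
  } else {
    df <- as.data.frame(x)
    df$.y <- factor(y, levels = c(0, 1))
    ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = model$num_trees, seed = seed, num.threads = 1
    )
  }
}

predict_prob <- function(fit, x, model) {
  if (model$engine == "gbt") {
    as.double(predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  } else {
    as.double(predict(fit, data = as.data.frame(x), num.threads = 1)$predictions[, "1"])
  }
}

#' Cross-validated fit and prediction
#'
#' For each fold of the plan, fits the learner on the remaining folds and
#' predicts the pre-AF class probability for every test segment, so each
#' recording is predicted exactly once across folds. Missing-flagged features
#' are median-imputed with medians fitted on the training folds only (no
#' test-fold leakage). Patient-level train/test disjointness is asserted on
#' every fold.
#'
#' @param ds An `af_dataset` from [build_dataset()].
#' @param plan A `fold_plan` from [make_temporal_folds()]; must cover exactly
#'   the recordings in `ds`.
#' @param model A [model_spec()].
#' @param seed Integer seed passed to the learner (default 1).
#' @return An `af_cv` object: list with `predictions` (segment-level tibble:
#'   provenance columns, `fold`, `prob`, `label`, `y`), `models` (per-fold
#'   fitted learners and imputation medians), `plan`, `model`, and
#'   `feature_names`.
#' @export
fit_predict_cv <- function(ds, plan, model = model_spec("gbt"), seed = 1) {
  stopifnot(inherits(ds, "af_dataset"), inherits(plan, "fold_plan"))
  if (!setequal(unique(ds$recording_id), plan$recording_id)) {
    abort("Fold plan and dataset must cover identical recordings.",
      class = "afonset_contract_error"
    )
  }
  fold_of <- stats::setNames(plan$fold, plan$recording_id)
  pat_of <- stats::setNames(plan$patient_id, plan$recording_id)
  row_fold <- unname(fold_of[ds$recording_id])
  x_all <- dataset_feature_matrix(ds, model$include_age_sex)
  y_all <- ds$y

  folds <- sort(unique(plan$fold))
  prob <- rep(NA_real_, nrow(ds))
  models <- vector("list", length(folds))
  for (f in folds) {
    test <- row_fold == f
    train <- !test
    train_pat <- unique(pat_of[ds$recording_id[train]])
    test_pat <- unique(pat_of[ds$recording_id[test]])
    if (length(intersect(train_pat, test_pat)) > 0) {
      abort(sprintf("Leakage: patient(s) straddle fold %d.", f))
    }
    if (dplyr::n_distinct(y_all[train]) < 2) {
      abort(sprintf(
        "Training folds for test fold %d contain a single class; temporal folds are unusable for this cohort.", f
      ), class = "afonset_contract_error")
    }
    meds <- fit_imputer(x_all[train, , drop = FALSE])
    xtr <- apply_imputer(x_all[train, , drop = FALSE], meds)
    xte <- apply_imputer(x_all[test, , drop = FALSE], meds)
    fit <- fit_learner(xtr, y_all[train], model, seed)
    p <- predict_prob(fit, xte, model)
    if (any(!is.finite(p))) {
      abort(sprintf(
        "Non-finite probability from %s model in fold %d.", model$engine, f
      ))
    }
    prob[test] <- p
    models[[f]] <- list(fit = fit, medians = meds, fold = f)
  }
  if (anyNA(prob)) abort("Some segments received no prediction.")

  preds <- ds |>
    dplyr::select(
      "recording_id", "patient_id", "window_id", "label", "y",
      "age_group", "segment_start_s"
    ) |>
    dplyr::mutate(fold = row_fold, prob = prob)
  structure(
    list(
      predictions = preds, models = models, plan = plan, model = model,
      feature_names = colnames(x_all)
    ),
    class = "af_cv"
  )
}

#' @export
print.af_cv <- function(x, ...) {
  cat(sprintf(
    "<af_cv> %s, %d folds, %d segments from %d recordings\n",
    x$model$engine, attr(x$plan, "n_folds"), nrow(x$predictions),
    dplyr::n_distinct(x$predictions$recording_id)
  ))
  invisible(x)
}

#' Aggregate segment predictions to window and recording level
#'
#' A window's probability is the arithmetic mean of its segments'
#' probabilities; a recording's probability is the mean of its window means.
#' Labels are inherited (windows of one recording share a label by
#' construction).
#'
#' @param preds An `af_cv` object or its segment-level `predictions` tibble.
#' @param level `"recording"` (default) or `"window"`.
#' @return Tibble with one row per recording (or window): provenance columns,
#'   `prob`, `y`, `label`, `n_segments` (and `n_windows` at recording level).
#' @export
aggregate_to_recording <- function(preds, level = c("recording", "window")) {
  level <- match.arg(level)
  if (inherits(preds, "af_cv")) preds <- preds$predictions
  win <- preds |>
    dplyr::group_by(
      .data$recording_id, .data$patient_id, .data$window_id, .data$label,
      .data$y, .data$age_group
    ) |>
    dplyr::summarise(
      prob = mean(.data$prob), n_segments = dplyr::n(), .groups = "drop"
    )
  if (level == "window") {
    return(win)
  }
  win |>
    dplyr::group_by(
      .data$recording_id, .data$patient_id, .data$label, .data$y,
      .data$age_group
    ) |>
    dplyr::summarise(
      prob = mean(.data$prob),
      n_segments = sum(.data$n_segments),
      n_windows = dplyr::n(), .groups = "drop"
    )
}
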