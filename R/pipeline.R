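#' Run the full AF-onset analysis pipeline
#'
#' Convenience wrapper for the whole study loop on one cohort: build the
#' segment-level dataset, form temporal patient-grouped folds, cross-validate
#' the classifier, aggregate to recording level, compute the metric suite at
#' both levels, and (for the `"gbt"` engine) the Shapley feature ranking.
#'
#' @param cohort An `af_cohort` (from [generate_cohort()] or
#'   [read_cohort()]), or a list of [af_recording()] plus a `metas` data
#'   frame.
#' @param crit,spec,cfg Stage configurations ([selection_criteria()],
#'   [segment_spec()], [spectral_config()]).
#' @param model A [model_spec()].
#' @param n_folds Folds for [make_temporal_folds()] (default 10).
#' @param threshold Decision threshold (default 0.5).
#' @param n_boot Bootstrap resamples for the CIs (default 1000).
#' @param seed Seed for learner and bootstrap (default 1).
#' @param metas Recording metadata (required when `cohort` is a bare list of
#'   recordings).
#' @param attribution Compute Shapley attribution (default `TRUE` for the
#'   gbt engine).
#' @return An `af_analysis` list: `dataset`, `plan`, `cv`,
#'   `predictions_recording`, `metrics_segment`, `metrics_recording`,
#'   `attribution` (or `NULL`).
#' @export
run_af_pipeline <- function(cohort, crit = selection_criteria(),
                            spec = segment_spec(), cfg = spectral_config(),
                            model = model_spec("gbt"), n_folds = 10,
                            threshold = 0.5, n_boot = 1000, seed = 1,
                            metas = NULL,
                            attribution = model$engine == "gbt") {
  if (inherits(cohort, "af_cohort")) {
    recordings <- cohort$recordings
    metas <- cohort$manifest
  } else {
    recordings <- cohort
    if (is.null(metas)) {
      metas <- purrr::map_dfr(recordings, function(r) {
        tibble::as_tibble(r$meta[c("recording_id", "patient_id", "recording_date")])
      })
    }
  }
  ds <- build_dataset(recordings, crit, spec, cfg)
  metas_used <- metas[metas$recording_id %in% unique(ds$recording_id), ]
  plan <- make_temporal_folds(metas_used, n_folds = n_folds)
  cv <- fit_predict_cv(ds, plan, model = model, seed = seed)
  rec <- aggregate_to_recording(cv)
  structure(
    list(
      dataset = ds, plan = plan, cv = cv,
      predictions_recording = rec,
      metrics_segment = classification_metrics(
        cv,
        threshold = threshold, n_boot = n_boot, seed = seed, level = "segment"
      ),
      metrics_recording = classification_metrics(
        rec,
        threshold = threshold, n_boot = n_boot, seed = seed, level = "recording"
      ),
      attribution = if (attribution) shapley_attribution(cv, ds) else NULL
    ),
    class = "af_analysis"
  )
}

#' @export
print.af_analysis <- function(x, ...) {
  g <- glance(x$cv)
  cat(sprintf(
    "<af_analysis> %s | segment AUROC %.3f | recording AUROC %.3f\n",
    x$cv$model$engine, g$auroc_segment, g$auroc_recording
  ))
  if (!is.null(x$attribution)) {
    cat(
      "top features:",
      paste(utils::head(x$attribution$summary$feature, 5), collapse = ", "), "\n"
    )
  }
  invisible(x)
}
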