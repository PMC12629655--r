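#' Temporal patient-grouped fold plan
#'
#' Orders patients by the date of their earliest recording (deterministic
#' tie-break on patient id) and cuts the ordered list into `n_folds`
#' contiguous blocks, so folds are temporally coherent and every recording of
#' a patient shares one fold — the leakage guard for repeated-recording
#' patients. Block sizes differ by at most one patient.
#'
#' @param metas Data frame with columns `recording_id`, `patient_id`,
#'   `recording_date` (one row per recording), e.g. a cohort manifest.
#' @param n_folds Number of folds (default 10); must not exceed the number of
#'   distinct patients.
#' @return A `fold_plan` tibble: `recording_id`, `patient_id`, `fold`.
#' @export
make_temporal_folds <- function(metas, n_folds = 10) {
  metas <- tibble::as_tibble(metas)
  stopifnot(all(c("recording_id", "patient_id", "recording_date") %in% names(metas)))
  patients <- metas |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ref_date = min(as.Date(.data$recording_date)), .groups = "drop") |>
    dplyr::arrange(.data$ref_date, .data$patient_id)
  np <- nrow(patients)
  if (np < n_folds) {
    abort(sprintf("Need at least %d distinct patients, got %d.", n_folds, np),
      class = "afonset_contract_error"
    )
  }
  base <- np %/% n_folds
  extra <- np %% n_folds
  sizes <- rep(base, n_folds) + c(rep(1L, extra), rep(0L, n_folds - extra))
  patients$fold <- rep(seq_len(n_folds), times = sizes)
  out <- metas |>
    dplyr::select("recording_id", "patient_id") |>
    dplyr::left_join(patients[, c("patient_id", "fold")], by = "patient_id") |>
    dplyr::arrange(.data$fold, .data$patient_id, .data$recording_id)
  structure(out, class = c("fold_plan", class(out)), n_folds = as.integer(n_folds))
}
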