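#' Assign the study age stratum
#'
#' Strata are half-open on the right: `<60`, `[60, 70)` -> `60-70`,
#' `[70, 80)` -> `70-80`, `>= 80` -> `>80`.
#'
#' @param age Age in years (vectorized, non-negative).
#' @return Character vector of stratum labels.
#' @export
assign_age_group <- function(age) {
  if (any(age < 0, na.rm = TRUE)) {
    abort("`age` must be non-negative.", class = "afonset_validation_error")
  }
  cut(age,
    breaks = c(-Inf, 60, 70, 80, Inf), right = FALSE,
    labels = c("<60", "60-70", "70-80", ">80")
  ) |> as.character()
}

# TRUE when the beat series covers [start_s, end_s) without dropout:
# a beat within `max_gap_s` of the window start, one at/after the end (or
# within max_gap_s of it at recording end), and no inter-beat gap > max_gap_s.
covers_interval <- function(time_s, start_s, end_s, max_gap_s) {
  inside <- time_s[time_s >= start_s & time_s <= end_s]
  if (length(inside) < 2) return(FALSE)
  if (inside[1] - start_s > max_gap_s) return(FALSE)
  if (end_s - inside[length(inside)] > max_gap_s) return(FALSE)
  all(diff(inside) <= max_gap_s)
}

empty_window_tibble <- function() {
  tibble::tibble(
    recording_id = character(), patient_id = character(), label = character(),
    start_s = double(), end_s = double(), source_episode = integer(),
    age_group = character()
  )
}

window_tibble <- function(rec, label, start_s, end_s, source_episode = NA_integer_) {
  tibble::tibble(
    recording_id = rec$meta$recording_id,
    patient_id = rec$meta$patient_id,
    label = label,
    start_s = start_s,
    end_s = end_s,
    source_episode = source_episode,
    age_group = assign_age_group(rec$meta$age)
  )
}

#' Select pre-AF analysis windows
#'
#' One window per eligible AF episode. An episode is eligible iff (a) its
#' onset is at least `min_onset_from_start_s` into the recording, (b) the
#' `min_nsr_before_s` seconds before onset contain no AF and no beat gap
#' longer than `max_gap_s`, and (c) at least `max(min_af_after_s,
#' af_duration_tier)` seconds of AF follow the onset. The returned window is
#' `[onset - min_nsr_before_s, onset - min_nsr_before_s + input_segment_s)` —
#' the start of the pre-onset sinus hour, leaving a silent gap before onset
#' when `input_segment_s < min_nsr_before_s`.
#'
#' @param rec An [af_recording()].
#' @param crit A [selection_criteria()].
#' @return Tibble of windows (possibly zero rows) with columns
#'   `recording_id`, `patient_id`, `label` (`"pre_AF"`), `start_s`, `end_s`,
#'   `source_episode`, `age_group`.
#' @export
select_preaf_windows <- function(rec, crit = selection_criteria()) {
  stopifnot(inherits(rec, "af_recording"), inherits(crit, "selection_criteria"))
  ep <- rec$episodes
  out <- list()
  for (i in seq_len(nrow(ep))) {
    onset <- ep$onset_s[i]
    dur <- ep$offset_s[i] - onset
    if (onset < crit$min_onset_from_start_s) next
    if (dur < max(crit$min_af_after_s, crit$af_duration_tier)) next
    nsr_start <- onset - crit$min_nsr_before_s
    if (nsr_start < 0) next
    other <- ep[-i, , drop = FALSE]
    af_overlap <- any(other$onset_s < onset & other$offset_s > nsr_start)
    if (af_overlap) next
    if (!covers_interval(rec$beats$time_s, nsr_start, onset, crit$max_gap_s)) next
    out[[length(out) + 1L]] <- window_tibble(
      rec, "pre_AF", nsr_start, nsr_start + crit$input_segment_s, i
    )
  }
  if (length(out) == 0) return(empty_window_tibble())
  dplyr::bind_rows(out)
}

#' Select normal-sinus-rhythm analysis windows
#'
#' For an arrhythmia-free recording, up to two windows of length
#' `input_segment_s`: one starting at the first beat, and one starting at
#' hour 12 (43200 s, the middle of a 24-h recording). A window is emitted only
#' when the beat series fully covers it (no gap longer than `max_gap_s`).
#'
#' @inheritParams select_preaf_windows
#' @return Tibble of windows (0-2 rows), `label = "NSR"`.
#' @export
select_nsr_windows <- function(rec, crit = selection_criteria()) {
  stopifnot(inherits(rec, "af_recording"), inherits(crit, "selection_criteria"))
  if (nrow(rec$episodes) > 0) {
    abort("NSR windows require a recording with no AF episode.",
      class = "afonset_contract_error"
    )
  }
  starts <- unique(c(rec$beats$time_s[1], 43200))
  out <- list()
  for (s in starts) {
    e <- s + crit$input_segment_s
    if (e > rec$meta$duration_s) next
    if (!covers_interval(rec$beats$time_s, s, e, crit$max_gap_s)) next
    out[[length(out) + 1L]] <- window_tibble(rec, "NSR", s, e)
  }
  if (length(out) == 0) return(empty_window_tibble())
  dplyr::bind_rows(out)
}

#' Select analysis windows for any recording
#'
#' Dispatches on rhythm content: recordings with AF episodes yield pre-AF
#' windows, arrhythmia-free recordings yield NSR windows.
#'
#' @inheritParams select_preaf_windows
#' @return Tibble of labelled windows.
#' @export
select_windows <- function(rec, crit = selection_criteria()) {
  if (nrow(rec$episodes) > 0) {
    select_preaf_windows(rec, crit)
  } else {
    select_nsr_windows(rec, crit)
  }
}
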