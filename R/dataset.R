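#' Build the model-ready segment-level dataset
#'
#' Runs the full featurization pipeline over a cohort: selects labelled
#' analysis windows per recording ([select_windows()]), divides each window
#' into overlapping segments ([segment_window()]), extracts the clean NN
#' series and spline tachogram per segment, and computes the 45-feature HRV
#' battery ([featurize()]). Segments with fewer than
#' `spec$min_nn_per_segment` retained NN intervals are dropped (the count is
#' reported in the `dropped_segments` attribute). Row order is fixed by
#' recording id, window start and segment start, so the build is
#' deterministic.
#'
#' @param recordings A list of [af_recording()] objects, or a directory path
#'   containing beat CSVs (read via [read_beats()]).
#' @param crit A [selection_criteria()].
#' @param spec A [segment_spec()].
#' @param cfg A [spectral_config()].
#' @return An `af_dataset` tibble: one row per analyzable segment, with
#'   provenance columns (`recording_id`, `patient_id`, `window_id`, `label`,
#'   `y`, `age_group`, `age`, `sex`, `window_start_s`, `segment_start_s`),
#'   the 45 feature columns, and `n_nn`.
#' @export
build_dataset <- function(recordings, crit = selection_criteria(),
                          spec = segment_spec(), cfg = spectral_config()) {
  if (is.character(recordings)) {
    paths <- sort(list.files(recordings, pattern = "\\.csv$", full.names = TRUE))
    recordings <- lapply(paths, read_beats)
  }
  stopifnot(length(recordings) >= 1)
  ord <- order(vapply(recordings, function(r) r$meta$recording_id, ""))
  recordings <- recordings[ord]

  meta_rows <- list()
  feat_rows <- list()
  dropped <- 0L
  for (rec in recordings) {
    windows <- select_windows(rec, crit)
    if (nrow(windows) == 0) next
    windows <- dplyr::arrange(windows, .data$start_s)
    bt <- rec$beats$time_s
    for (wi in seq_len(nrow(windows))) {
      w <- windows[wi, ]
      # per-window NN extraction once; segments then subset by time
      lo <- max(1L, findInterval(w$start_s - 1e-9, bt) + 1L)
      hi <- findInterval(w$end_s - 1e-9, bt)
      if (hi - lo < 1) next
      t_w <- bt[lo:hi]
      lab_w <- rec$beats$label[lo:hi]
      nw <- length(t_w)
      int_rr <- (t_w[-1] - t_w[-nw]) * 1000
      keep_int <- lab_w[-1] == "N" & lab_w[-nw] == "N" &
        int_rr >= 200 & int_rr <= 4000
      nn_t <- t_w[-1][keep_int]
      nn_v <- int_rr[keep_int]
      nn_t0 <- nn_t - nn_v / 1000 # interval start times
      segs <- segment_window(w, spec)
      for (si in seq_len(nrow(segs))) {
        s0 <- segs$start_s[si]
        s1 <- segs$end_s[si]
        sel_lo <- findInterval(s0 - 1e-9, nn_t0) + 1L
        sel_hi <- findInterval(s1 - 1e-9, nn_t)
        if (sel_hi - sel_lo + 1L < spec$min_nn_per_segment) {
          dropped <- dropped + 1L
          next
        }
        v <- nn_v[sel_lo:sel_hi]
        tt <- nn_t[sel_lo:sel_hi]
        tach <- if (length(v) >= 4) {
          spline_tachogram_values(v, tt, s0, s1, cfg$sample_rate_hz)
        } else {
          NULL
        }
        feat_rows[[length(feat_rows) + 1L]] <- featurize_vector(v, tach, cfg)
        meta_rows[[length(meta_rows) + 1L]] <- list(
          recording_id = w$recording_id,
          patient_id = w$patient_id,
          window_id = paste0(w$recording_id, ":w", wi),
          label = w$label,
          y = as.integer(w$label == "pre_AF"),
          age_group = w$age_group,
          age = rec$meta$age,
          sex = rec$meta$sex,
          window_start_s = w$start_s,
          segment_index = segs$segment_index[si],
          segment_start_s = s0,
          n_nn = length(v)
        )
      }
    }
  }
  if (length(feat_rows) == 0) {
    abort("No analyzable segments in the cohort.", class = "afonset_nonanalyzable")
  }
  meta <- dplyr::bind_rows(lapply(meta_rows, tibble::new_tibble, nrow = 1L))
  feats <- tibble::as_tibble(as.data.frame(do.call(rbind, feat_rows)))
  out <- dplyr::bind_cols(meta, feats)
  out <- dplyr::arrange(
    out, .data$recording_id, .data$window_start_s, .data$segment_start_s
  )
  if (dplyr::n_distinct(out$label) < 2) {
    abort(sprintf(
      "Single-class cohort (all windows are %s); need both pre_AF and NSR.",
      out$label[1]
    ), class = "afonset_contract_error")
  }
  all_na <- vapply(out[af_feature_names()], function(x) all(is.na(x)), TRUE)
  if (any(all_na)) {
    warn(paste0(
      "Feature column(s) entirely missing: ",
      paste(names(all_na)[all_na], collapse = ", ")
    ))
  }
  structure(out,
    class = c("af_dataset", class(out)),
    dropped_segments = dropped, crit = crit, spec = spec, cfg = cfg
  )
}
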