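#' Extract the clean NN-interval series for a window
#'
#' An interval is retained as normal-to-normal (NN) only when both of its
#' endpoint beats are labelled `N`: intervals into and out of a premature
#' atrial contraction or artifact beat are excluded, because ectopy distorts
#' every autonomic HRV statistic. Retained intervals outside the
#' physiological range 200-4000 ms are also dropped (R-wave double counts and
#' missed beats).
#'
#' @param rec An [af_recording()], or a beat tibble with columns
#'   `time_s`, `rr_ms`, `label`.
#' @param start_s,end_s Window bounds in seconds; intervals are kept when both
#'   endpoint beats lie in `[start_s, end_s)`.
#' @return An `nn_series` tibble with columns `nn_ms` and `time_s` (time of
#'   the terminating beat), plus attributes `n_excluded` (intervals dropped by
#'   the ectopy and range rules), `n_beats`, and `analyzable` (`FALSE` when
#'   fewer than 30 NN intervals remain).
#' @export
extract_nn <- function(rec, start_s = -Inf, end_s = Inf) {
  beats <- if (inherits(rec, "af_recording")) rec$beats else tibble::as_tibble(rec)
  keep <- beats$time_s >= start_s & beats$time_s < end_s
  b <- beats[keep, , drop = FALSE]
  n <- nrow(b)
  if (n < 2) {
    return(new_nn_series(double(), double(), 0L, n))
  }
  rr <- b$rr_ms[-1]
  t_end <- b$time_s[-1]
  lab_from <- b$label[-n]
  lab_to <- b$label[-1]
  # the first interval of the window joins a beat outside [start_s, end_s):
  # its rr_ms is recomputed from the in-window predecessor, so no NA survives
  rr <- ifelse(is.na(rr), diff(b$time_s) * 1000, rr)
  is_nn <- lab_from == "N" & lab_to == "N"
  in_range <- rr >= 200 & rr <= 4000
  keep_int <- is_nn & in_range
  n_excluded <- sum(!keep_int)
  new_nn_series(rr[keep_int], t_end[keep_int], n_excluded, n)
}

new_nn_series <- function(nn_ms, time_s, n_excluded, n_beats) {
  out <- tibble::tibble(nn_ms = as.double(nn_ms), time_s = as.double(time_s))
  structure(out,
    class = c("nn_series", class(out)),
    n_excluded = as.integer(n_excluded),
    n_beats = as.integer(n_beats),
    analyzable = length(nn_ms) >= 30
  )
}

#' Build an evenly sampled tachogram
#'
#' Cubic-spline interpolation of the NN series (interval value against the
#' time of its terminating beat) evaluated on a uniform grid, the standard
#' preparation for spectral HRV analysis. A natural spline is used, so
#' extrapolation beyond the first/last NN point is linear; interpolated values
#' are clamped to the physiological range 200-4000 ms.
#'
#' @param nn An `nn_series` from [extract_nn()] (at least 4 points).
#' @param start_s,end_s Grid span in seconds.
#' @param sample_rate_hz Grid rate in Hz (default 4).
#' @return A `tachogram` tibble with columns `time_s` and `rr_ms`, attributes
#'   `sample_rate_hz` and `t0_s`. Length is
#'   `floor((end_s - start_s) * sample_rate_hz)`.
#' @export
build_tachogram <- function(nn, start_s, end_s, sample_rate_hz = 4) {
  stopifnot(end_s > start_s, sample_rate_hz > 0)
  if (nrow(nn) < 4) {
    abort("Cubic-spline tachogram needs at least 4 NN points.",
      class = "afonset_nonanalyzable"
    )
  }
  n <- floor((end_s - start_s) * sample_rate_hz)
  grid <- start_s + (seq_len(n) - 1) / sample_rate_hz
  vals <- spline_tachogram_values(nn$nn_ms, nn$time_s, start_s, end_s, sample_rate_hz)
  out <- tibble::tibble(time_s = grid, rr_ms = vals)
  structure(out,
    class = c("tachogram", class(out)),
    sample_rate_hz = sample_rate_hz, t0_s = start_s
  )
}

# hot path shared with build_dataset: natural cubic spline of the NN series
# on the uniform grid, clamped to the physiological range
spline_tachogram_values <- function(nn_ms, time_s, start_s, end_s, sample_rate_hz) {
  n <- floor((end_s - start_s) * sample_rate_hz)
  grid <- start_s + (seq_len(n) - 1) / sample_rate_hz
  f <- stats::splinefun(time_s, nn_ms, method = "natural")
  pmin(pmax(f(grid), 200), 4000)
}
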