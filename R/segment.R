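#' Divide an analysis window into overlapping segments
#'
#' Segments start at the window start and step by `stride_s`; only segments
#' lying fully inside the window are returned, so the count is
#' `floor((window_len - segment_len) / stride) + 1`.
#'
#' @param window One window (a one-row tibble or list with `start_s`,
#'   `end_s`), or explicit `start_s`/`end_s` via a two-element numeric vector
#'   `c(start_s, end_s)`.
#' @param spec A [segment_spec()].
#' @return Tibble with columns `segment_index`, `start_s`, `end_s`; zero rows
#'   (with a warning) when the window is shorter than one segment.
#' @export
segment_window <- function(window, spec = segment_spec()) {
  if (is.numeric(window) && length(window) == 2) {
    start_s <- window[1]
    end_s <- window[2]
  } else {
    start_s <- window$start_s[1]
    end_s <- window$end_s[1]
  }
  len <- end_s - start_s
  if (len < spec$segment_len_s) {
    warn("Window shorter than one segment; returning no segments.")
    return(tibble::tibble(
      segment_index = integer(), start_s = double(), end_s = double()
    ))
  }
  k <- floor((len - spec$segment_len_s) / spec$stride_s) + 1
  starts <- start_s + (seq_len(k) - 1) * spec$stride_s
  tibble::tibble(
    segment_index = seq_len(k),
    start_s = starts,
    end_s = starts + spec$segment_len_s
  )
}
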