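#' Frequency-domain HRV features
#'
#' Power spectral analysis of the evenly sampled tachogram: total power and
#' the powers in the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands, the
#' normalized powers `lf_nu = LF / (LF + HF)` and `hf_nu = HF / (LF + HF)`,
#' and the LF/HF ratio. The spectrum is a Welch-style averaged periodogram
#' (Hann taper, 50% overlap, per-segment mean and linear-trend removal) and
#' band powers are obtained by trapezoidal integration, so the integral of
#' the full spectrum approximates the tachogram variance (Parseval).
#'
#' @param tach A `tachogram` from [build_tachogram()], covering at least
#'   120 s.
#' @param cfg A [spectral_config()].
#' @return Named list: `total_power`, `lf_power`, `hf_power` (ms^2), `lf_nu`,
#'   `hf_nu`, `lf_hf_ratio`. When `hf_power` is exactly 0 the ratio is
#'   reported as the finite sentinel `1e6`, never `Inf`.
#' @export
frequency_features <- function(tach, cfg = spectral_config()) {
  x <- if (is.numeric(tach)) as.double(tach) else as.double(tach$rr_ms)
  fs <- if (is.numeric(tach)) cfg$sample_rate_hz else attr(tach, "sample_rate_hz")
  if (length(x) / fs < 120) {
    abort("Tachogram must cover at least 120 s for spectral analysis.",
      class = "afonset_nonanalyzable"
    )
  }
  ps <- welch_psd(x, fs, cfg$seg_len_samples, cfg$overlap)
  total <- band_power(ps, cfg$total_band)
  lf <- band_power(ps, cfg$lf_band)
  hf <- band_power(ps, cfg$hf_band)
  denom <- lf + hf
  lf_nu <- if (denom > 0) lf / denom else NA_real_
  ratio <- if (hf > 0) lf / hf else if (lf > 0) 1e6 else NA_real_
  list(
    total_power = total, lf_power = lf, hf_power = hf,
    lf_nu = lf_nu, hf_nu = if (denom > 0) hf / denom else NA_real_,
    lf_hf_ratio = ratio
  )
}

# Welch averaged periodogram, one-sided, density scaling:
# integrating the result over frequency recovers the signal variance.
welch_psd <- function(x, fs, nperseg, overlap) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  step <- max(1L, as.integer(floor(nperseg * (1 - overlap))))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  norm <- fs * sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  tt <- seq_len(nperseg) - (nperseg + 1) / 2
  sxx <- sum(tt^2)
  for (s in starts) {
    y <- x[s:(s + nperseg - 1L)]
    y <- y - mean(y) - tt * (sum(tt * y) / sxx) # mean + linear detrend
    p <- Mod(fft(y * w))^2 / norm
    p <- p[seq_len(nfreq)]
    # one-sided: double everything except DC and (for even nperseg) Nyquist
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(
    freq = (seq_len(nfreq) - 1) * fs / nperseg,
    psd = acc / length(starts)
  )
}

# trapezoidal band power over [band[1], band[2]]
band_power <- function(ps, band) {
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  f <- ps$freq[sel]
  p <- ps$psd[sel]
  if (length(f) < 2) {
    return(0)
  }
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}
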