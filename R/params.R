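#' Window-eligibility criteria
#'
#' Rules that decide which parts of a recording become labelled analysis
#' windows. Defaults follow the usual Holter study design: at least 60 min of
#' uninterrupted sinus rhythm must precede an AF onset, at least 5 min of AF
#' must follow it, and onsets in the first 2 h of the recording are discarded
#' (early onsets leave no clean baseline). The analysis window itself is the
#' first `input_segment_s` seconds of the pre-onset sinus hour.
#'
#' @param min_nsr_before_s Seconds of AF-free, gap-free sinus rhythm required
#'   immediately before an AF onset. Default 3600.
#' @param min_af_after_s Seconds of AF that must follow the onset. Default 300.
#' @param min_onset_from_start_s Earliest admissible onset time, seconds from
#'   recording start. Default 7200.
#' @param input_segment_s Length of the analysis window in seconds. Default
#'   1800 (a 30-min window at the start of the pre-onset hour); 3600 gives the
#'   full-hour variant.
#' @param af_duration_tier Minimum AF episode duration in seconds; one of 30,
#'   300 or 600. Default 300.
#' @param max_gap_s Any inter-beat interval longer than this (seconds) inside a
#'   candidate window marks it non-analyzable (lead-off dropout). Default 5.
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(min_nsr_before_s = 3600,
                               min_af_after_s = 300,
                               min_onset_from_start_s = 7200,
                               input_segment_s = 1800,
                               af_duration_tier = 300,
                               max_gap_s = 5) {
  stopifnot(
    min_nsr_before_s > 0, min_af_after_s > 0, min_onset_from_start_s > 0,
    input_segment_s > 0, max_gap_s > 0
  )
  if (input_segment_s > min_nsr_before_s) {
    abort("`input_segment_s` must not exceed `min_nsr_before_s`.")
  }
  if (!af_duration_tier %in% c(30, 300, 600)) {
    abort("`af_duration_tier` must be one of 30, 300 or 600 seconds.")
  }
  structure(
    list(
      min_nsr_before_s = min_nsr_before_s,
      min_af_after_s = min_af_after_s,
      min_onset_from_start_s = min_onset_from_start_s,
      input_segment_s = input_segment_s,
      af_duration_tier = af_duration_tier,
      max_gap_s = max_gap_s
    ),
    class = "selection_criteria"
  )
}

#' Overlapping segmentation parameters
#'
#' @param segment_len_s Segment length in seconds (default 300, the 5-min
#'   input the classifiers consume).
#' @param stride_s Step between consecutive segment starts, seconds (default
#'   60; must not exceed `segment_len_s`, so segments overlap).
#' @param min_nn_per_segment Minimum retained NN intervals for a segment to be
#'   featurized (default 30).
#' @return A `segment_spec` list.
#' @export
segment_spec <- function(segment_len_s = 300, stride_s = 60,
                         min_nn_per_segment = 30) {
  stopifnot(segment_len_s > 0, stride_s > 0, min_nn_per_segment > 0)
  if (stride_s > segment_len_s) {
    abort("`stride_s` must not exceed `segment_len_s` (segments must overlap).")
  }
  structure(
    list(
      segment_len_s = segment_len_s, stride_s = stride_s,
      min_nn_per_segment = min_nn_per_segment
    ),
    class = "segment_spec"
  )
}

#' Spectral-estimation configuration
#'
#' Band edges and averaged-periodogram (Welch) parameters for the
#' frequency-domain HRV features. Bands are the conventional short-term HRV
#' bands: LF 0.04-0.15 Hz, HF 0.15-0.4 Hz, total 0.0033-0.4 Hz.
#'
#' @param lf_band,hf_band,total_band Two-element numeric band edges in Hz.
#' @param sample_rate_hz Tachogram resampling rate (default 4; Nyquist 2 Hz
#'   comfortably covers the HF band).
#' @param seg_len_samples Welch segment length in samples (default 512, i.e.
#'   128 s at 4 Hz; shorter tachograms fall back to a single segment).
#' @param overlap Fractional overlap between Welch segments (default 0.5).
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.4),
                            total_band = c(0.0033, 0.4),
                            sample_rate_hz = 4,
                            seg_len_samples = 512L,
                            overlap = 0.5) {
  for (b in list(lf_band, hf_band, total_band)) {
    stopifnot(length(b) == 2, b[1] < b[2], all(b > 0))
  }
  if (lf_band[2] > hf_band[1] + 1e-12) {
    abort("LF and HF bands must not overlap in their interiors.")
  }
  stopifnot(sample_rate_hz > 0, seg_len_samples >= 8, overlap >= 0, overlap < 1)
  structure(
    list(
      lf_band = lf_band, hf_band = hf_band, total_band = total_band,
      sample_rate_hz = sample_rate_hz,
      seg_len_samples = as.integer(seg_len_samples), overlap = overlap
    ),
    class = "spectral_config"
  )
}

#' Tree-ensemble learner specification
#'
#' Both engines are used with their libraries' default hyperparameters (the
#' study design tunes nothing); depth and ensemble size are exposed for
#' sensitivity checks.
#'
#' @param engine `"gbt"` (gradient-boosted trees via xgboost) or `"rf"`
#'   (probability random forest via ranger).
#' @param nrounds Boosting rounds for `"gbt"` (default 100).
#' @param max_depth Tree depth for `"gbt"` (default 6).
#' @param eta Learning rate for `"gbt"` (default 0.3).
#' @param num_trees Forest size for `"rf"` (default 500).
#' @param include_age_sex Add age (years) and sex as extra predictors
#'   (default `FALSE`; kept as a switch for the covariate-benefit comparison).
#' @return A `model_spec` list.
#' @export
model_spec <- function(engine = c("gbt", "rf"), nrounds = 100, max_depth = 6,
                       eta = 0.3, num_trees = 500, include_age_sex = FALSE) {
  engine <- match.arg(engine)
  structure(
    list(
      engine = engine, nrounds = nrounds, max_depth = max_depth, eta = eta,
      num_trees = num_trees, include_age_sex = include_age_sex
    ),
    class = "model_spec"
  )
}

#' RR-interval generator parameters
#'
#' Parameters of the synthetic sinus-rhythm RR model
#' `rr(t) = mean_rr + lf_amp sin(2 pi lf_freq t) + hf_amp sin(2 pi hf_freq t) + noise`,
#' with isolated premature atrial contractions (PACs) injected as Poisson
#' events, plus the pre-onset perturbations (vagal HF boost, alternans bursts,
#' PAC-rate ramp) and the AF-regime marginal (serially uncorrelated Gamma RR).
#'
#' @param mean_rr_ms Mean sinus RR interval, ms (default 800).
#' @param hf_amp_ms,hf_freq_hz Respiratory (HF-band) modulation amplitude (ms)
#'   and frequency (Hz); defaults 20 and 0.25.
#' @param lf_amp_ms,lf_freq_hz Mayer-wave (LF-band) modulation; defaults 15
#'   and 0.095.
#' @param noise_sd_ms Marginal SD of the beat-to-beat Gaussian noise, ms
#'   (default 10).
#' @param noise_phi Lag-1 autocorrelation of the noise (AR(1), default 0.8).
#'   Healthy RR fluctuations are serially correlated; white noise would make
#'   normal sinus rhythm look pathologically fragmented.
#' @param pac_rate_per_min Baseline PAC rate, events/min (default 0.2).
#' @param hf_amp_boost Multiplicative HF-amplitude boost inside the pre-onset
#'   hour (default 1.8).
#' @param alternation_prob Expected fraction of pre-onset beats inside
#'   alternans bursts (default 0.25).
#' @param alternation_amp_ms Alternating RR offset inside a burst, ms
#'   (default 12). Inside a burst the respiratory modulation is suspended
#'   and the offset alternates around the local mean, so bursts are
#'   low-amplitude fragmentation (frequent sign reversals), not large RR
#'   swings.
#' @param alternation_mean_len Mean burst length in beats (geometric;
#'   default 8).
#' @param pac_rate_ramp PAC-rate multiplier reached at onset, ramped linearly
#'   over the final 2 h before onset (default 5).
#' @param af_cv Coefficient of variation of the i.i.d. Gamma RR marginal
#'   during AF (default 0.2); the AF mean RR is `0.75 * mean_rr_ms`.
#' @return An `rr_params` list.
#' @export
rr_params <- function(mean_rr_ms = 800, hf_amp_ms = 20, hf_freq_hz = 0.25,
                      lf_amp_ms = 15, lf_freq_hz = 0.095, noise_sd_ms = 10,
                      noise_phi = 0.8, pac_rate_per_min = 0.2, hf_amp_boost = 1.8,
                      alternation_prob = 0.25, alternation_amp_ms = 12,
                      alternation_mean_len = 8, pac_rate_ramp = 5,
                      af_cv = 0.2) {
  stopifnot(
    mean_rr_ms >= 400, mean_rr_ms <= 1500,
    hf_amp_ms >= 0, lf_amp_ms >= 0, noise_sd_ms >= 0,
    hf_freq_hz > 0.15, hf_freq_hz < 0.4,
    lf_freq_hz > 0.04, lf_freq_hz < 0.15,
    noise_phi >= 0, noise_phi < 1,
    pac_rate_per_min >= 0, hf_amp_boost > 0,
    alternation_prob >= 0, alternation_prob < 1,
    alternation_amp_ms >= 0, alternation_mean_len >= 1,
    pac_rate_ramp > 0, af_cv > 0
  )
  structure(
    list(
      mean_rr_ms = mean_rr_ms, hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
      lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz, noise_sd_ms = noise_sd_ms,
      noise_phi = noise_phi, pac_rate_per_min = pac_rate_per_min, hf_amp_boost = hf_amp_boost,
      alternation_prob = alternation_prob,
      alternation_amp_ms = alternation_amp_ms,
      alternation_mean_len = alternation_mean_len,
      pac_rate_ramp = pac_rate_ramp, af_cv = af_cv
    ),
    class = "rr_params"
  )
}

#' Synthetic cohort configuration
#'
#' @param n_af,n_nsr Number of AF and arrhythmia-free recordings (each >= 1).
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @param duration_s Recording duration in seconds (default 86400, a 24-h
#'   Holter).
#' @param params Shared [rr_params()] for all recordings.
#' @param age_probs Length-4 probability vector over the age strata
#'   `<60, 60-70, 70-80, >80` (default uniform).
#' @param repeat_patient_frac Fraction of patients given a second recording
#'   (default 0.1), to exercise the patient-grouped fold rule.
#' @param mean_rr_between_sd_ms Between-patient SD of the mean RR interval
#'   (normal jitter around `params$mean_rr_ms`, default 60 ms; clamped to
#'   500-1400 ms). Real cohorts differ widely in resting heart rate; a
#'   single shared mean would make the classes separable by accident.
#' @param amp_between_sdlog Between-patient log-SD of the HF and LF
#'   modulation amplitudes (lognormal multiplier, default 0.3).
#' @param noise_between_sdlog Between-patient log-SD of the beat-to-beat
#'   noise SD (default 0.25).
#' @param boost_between_sdlog Between-patient log-SD of the pre-onset HF
#'   boost excess (`hf_amp_boost - 1`), mean-preserving lognormal (default
#'   0.35). Pre-AF phenotypes are heterogeneous: some patients show a strong
#'   vagal surge, others barely any.
#' @param alternation_between_conc Beta concentration of the per-patient
#'   alternans fraction around `alternation_prob` (default 8; smaller =
#'   more heterogeneous, so some pre-AF patients are alternans-dominant and
#'   others alternans-free).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_af = 120, n_nsr = 120, seed,
                          duration_s = 86400, params = rr_params(),
                          age_probs = c(0.25, 0.25, 0.25, 0.25),
                          repeat_patient_frac = 0.1,
                          mean_rr_between_sd_ms = 60,
                          amp_between_sdlog = 0.3,
                          noise_between_sdlog = 0.25,
                          boost_between_sdlog = 0.35,
                          alternation_between_conc = 8) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  stopifnot(
    n_af >= 1, n_nsr >= 1, duration_s > 0,
    length(age_probs) == 4, all(age_probs >= 0), sum(age_probs) > 0,
    repeat_patient_frac >= 0, repeat_patient_frac < 1
  )
  structure(
    list(
      n_af = as.integer(n_af), n_nsr = as.integer(n_nsr),
      seed = as.integer(seed), duration_s = duration_s, params = params,
      age_probs = age_probs / sum(age_probs),
      repeat_patient_frac = repeat_patient_frac,
      mean_rr_between_sd_ms = mean_rr_between_sd_ms,
      amp_between_sdlog = amp_between_sdlog,
      noise_between_sdlog = noise_between_sdlog,
      boost_between_sdlog = boost_between_sdlog,
      alternation_between_conc = alternation_between_conc
    ),
    class = "cohort_config"
  )
}
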