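#' Feature schema
#'
#' Names of the 45 HRV features, in schema order: 16 time-domain (including
#' the two geometric measures), 6 frequency-domain, 6 Poincare, 7 SODP, 6
#' PRSA, 4 fragmentation.
#'
#' @return Character vector of feature names.
#' @export
af_feature_names <- function() {
  c(
    "mean_hr", "sdnn", "rmssd", "sdsd", "cvnn", "cvsd",
    "pnn10", "pnn20", "pnn50", "min_nn", "max_nn", "median_nn",
    "prc20_nn", "prc80_nn", "tinn", "hrvi",
    "total_power", "lf_power", "hf_power", "lf_nu", "hf_nu", "lf_hf_ratio",
    "sd1", "sd2", "sd1_sd2", "csi", "cvi", "cvi_modified",
    "sodp_q1", "sodp_q2", "sodp_q3", "sodp_q4", "ctm20", "ctm50", "ctm100",
    "ac", "dc", "ac_modified", "dc_modified", "ack", "ddck",
    "pip", "ials", "pss", "pas"
  )
}

# fast path: named double vector of all 45 features; tach may be NULL
# (frequency features NA) and individual families degrade to NA rather than
# aborting, so one degenerate segment never kills a cohort build.
featurize_vector <- function(nn, tach = NULL, cfg = spectral_config()) {
  freq <- if (is.null(tach)) {
    list(
      total_power = NA_real_, lf_power = NA_real_, hf_power = NA_real_,
      lf_nu = NA_real_, hf_nu = NA_real_, lf_hf_ratio = NA_real_
    )
  } else {
    frequency_features(tach, cfg)
  }
  vals <- c(
    time_domain_features(nn),
    freq,
    poincare_features(nn),
    sodp_features(nn),
    prsa_features(nn),
    fragmentation_features(nn)
  )
  out <- unlist(vals, use.names = TRUE)
  out[af_feature_names()]
}

#' Compute the full feature vector for one segment
#'
#' Composes every feature family into one row. Discrete, beat-to-beat
#' families (time-domain, geometric, Poincare, SODP, PRSA, fragmentation) are
#' computed on the cleaned NN sequence; only the frequency-domain family uses
#' the spline-resampled tachogram. Families whose preconditions fail (e.g.
#' PRSA on a constant series, spectra without a tachogram) are missing-flagged
#' as `NA` rather than aborting.
#'
#' @param nn An `nn_series` (or numeric NN vector, ms).
#' @param tach Optional `tachogram` for the same span; when `NULL` the six
#'   frequency features are `NA`.
#' @param cfg A [spectral_config()].
#' @return One-row tibble with the 45 columns of [af_feature_names()] plus
#'   `n_nn` and `n_missing` (count of missing-flagged features).
#' @export
featurize <- function(nn, tach = NULL, cfg = spectral_config()) {
  v <- featurize_vector(nn, tach, cfg)
  out <- tibble::as_tibble(as.list(v))
  out$n_nn <- length(nn_values(nn))
  out$n_missing <- sum(is.na(v))
  out
}
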