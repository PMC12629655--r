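# --- synthetic RR model -----------------------------------------------------
# Sinus rhythm: rr(t) = mean + lf sin + hf sin + AR(1) noise, integrated into
# beat times; AF: serially uncorrelated Gamma RR at 0.75 x mean; pre-onset:
# HF-amplitude boost + alternans bursts over the final hour, PAC-rate ramp
# over the final 2 h. All of this is a deliberately minimal stand-in for real
# Holter data with the discriminative structure the analysis assumes.

# burst membership over a beat-index grid: alternating-run state machine with
# geometric gaps and lengths; returns +/-1 inside bursts, 0 outside.
burst_pattern <- function(n, prob, mean_len) {
  if (prob <= 0 || n == 0) {
    return(numeric(n))
  }
  hazard <- prob / (mean_len * (1 - prob))
  out <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    gap <- rgeom(1, min(hazard, 0.999)) + 1L
    pos <- pos + gap
    if (pos > n) break
    len <- rgeom(1, 1 / mean_len) + 1L
    idx <- pos:min(pos + len - 1L, n)
    out[idx] <- (-1)^(seq_along(idx) - 1)
    pos <- pos + len
  }
  out
}

# beat times over a sinus-rhythm span [t0, t1) by chunked fixed-point
# integration of t_i = t_{i-1} + rr(t_{i-1}) / 1000 (3 vectorized passes;
# modulation is a small fraction of the mean RR, so convergence is fast).
synth_sinus_block <- function(t0, t1, p, onset = NA_real_) {
  span <- t1 - t0
  if (span <= 0) {
    return(tibble::tibble(time_s = double(), label = character()))
  }
  n_est <- ceiling(span / (p$mean_rr_ms / 1000) * 1.25) + 60
  # AR(1) noise with the requested marginal SD
  innov <- rnorm(n_est, 0, p$noise_sd_ms * sqrt(1 - p$noise_phi^2))
  noise <- as.numeric(stats::filter(innov, p$noise_phi, method = "recursive"))
  alt <- if (!is.na(onset) && p$alternation_prob > 0) {
    burst_pattern(n_est, p$alternation_prob, p$alternation_mean_len) *
      p$alternation_amp_ms
  } else {
    numeric(n_est)
  }
  t_prev <- t0 + (seq_len(n_est) - 1) * p$mean_rr_ms / 1000
  for (pass in 1:3) {
    in_pre <- if (is.na(onset)) {
      FALSE
    } else {
      t_prev >= onset - 3600 & t_prev < onset
    }
    hf_amp <- p$hf_amp_ms * (1 + (p$hf_amp_boost - 1) * in_pre)
    # inside an alternans burst the sinus node alternates instead of being
    # smoothly modulated: respiratory modulation and most of the noise are
    # suspended and replaced by the small alternating offset, so bursts are
    # genuine low-amplitude fragmentation rather than large RR swings
    in_burst <- (alt != 0) & in_pre
    rr <- p$mean_rr_ms +
      p$lf_amp_ms * sin(2 * pi * p$lf_freq_hz * t_prev + p$lf_phase) +
      hf_amp * sin(2 * pi * p$hf_freq_hz * t_prev + p$hf_phase) * (1 - in_burst) +
      noise * (1 - 0.7 * in_burst) + alt * in_pre
    rr <- pmin(pmax(rr, 300), 2000)
    tt <- t0 + cumsum(rr) / 1000
    t_prev <- c(t0, tt[-n_est])
  }
  keep <- tt < t1
  times <- tt[keep]
  rr_keep <- rr[keep]
  labels <- rep("N", length(times))

  # PAC injection: Poisson per beat, rate ramped linearly over the final 2 h
  # before onset; the premature beat lands at 0.7 rr after its predecessor and
  # the following sinus beat keeps its time (compensatory pause, phase kept).
  if (p$pac_rate_per_min > 0 && length(times) > 3) {
    rate <- rep(p$pac_rate_per_min, length(times))
    if (!is.na(onset)) {
      frac <- pmax(0, pmin(1, 1 - (onset - times) / 7200))
      rate <- rate * (1 + (p$pac_rate_ramp - 1) * frac)
    }
    p_beat <- rate / 60 * rr_keep / 1000
    u <- runif(length(times))
    cand <- which(u < p_beat)
    cand <- cand[cand >= 2 & cand <= length(times) - 1]
    if (length(cand) > 1) { # no two adjacent PACs
      keep_c <- c(TRUE, diff(cand) > 1)
      cand <- cand[keep_c]
    }
    if (length(cand) > 0) {
      times[cand] <- times[cand - 1] + 0.7 * rr_keep[cand] / 1000
      labels[cand] <- "PAC"
    }
  }
  tibble::tibble(time_s = times, label = labels)
}

#' Generate one synthetic beat-annotated recording
#'
#' Simulates a 24-h Holter-style recording under the package's RR model: see
#' [rr_params()] for the mechanism. Class `"nsr"` recordings contain no AF;
#' class `"af"` recordings contain exactly one AF episode with onset drawn
#' uniformly in `[3 h, duration - 1 h]`, the pre-onset perturbations applied
#' over the final pre-onset hour, and i.i.d. Gamma RR during the episode.
#' Bit-for-bit reproducible given `seed`.
#'
#' @param class `"nsr"` or `"af"`.
#' @param params An [rr_params()].
#' @param duration_s Recording duration, seconds (default 86400). For class
#'   `"af"` it must be at least 14400 s to honour the onset placement rule.
#' @param seed Integer seed (mandatory).
#' @param recording_id,patient_id Identifiers (defaults `"R001"`, `"P001"`).
#' @param age,sex,recording_date Optional metadata; drawn when `NULL`
#'   (age uniform in 40-90, date in 2015-2019).
#' @return A validated [af_recording()].
#' @export
generate_recording <- function(class = c("nsr", "af"), params = rr_params(),
                               duration_s = 86400, seed,
                               recording_id = "R001", patient_id = "P001",
                               age = NULL, sex = NULL, recording_date = NULL) {
  class <- match.arg(class)
  if (missing(seed)) abort("`seed` is mandatory.")
  if (class == "af" && duration_s < 14400) {
    abort("`duration_s` too short to place an AF onset at >= 3 h with >= 1 h after.",
      class = "afonset_validation_error"
    )
  }
  withr::with_seed(seed, {
    if (is.null(age)) age <- runif(1, 40, 90)
    if (is.null(sex)) sex <- sample(c("M", "F"), 1)
    if (is.null(recording_date)) {
      recording_date <- as.Date("2015-01-01") + sample.int(1825, 1) - 1
    }
    p <- params
    # modulation phases are arbitrary per recording (no phase-locking of
    # respiration or Mayer waves to the recorder start)
    p$lf_phase <- runif(1, 0, 2 * pi)
    p$hf_phase <- runif(1, 0, 2 * pi)
    episodes <- NULL
    if (class == "nsr") {
      blocks <- list(synth_sinus_block(0, duration_s, p))
    } else {
      onset <- runif(1, 10800, duration_s - 3600)
      af_dur <- runif(1, 900, min(3600, duration_s - 60 - onset))
      offset <- onset + af_dur
      # AF block: serially uncorrelated Gamma marginal, mean 0.75 x sinus RR
      af_mean <- 0.75 * p$mean_rr_ms
      shape <- 1 / p$af_cv^2
      m_est <- ceiling(af_dur / (af_mean / 1000) * 1.4) + 60
      rr_af <- rgamma(m_est, shape = shape, rate = shape / af_mean)
      t_af <- onset + cumsum(rr_af) / 1000
      af_block <- tibble::tibble(
        time_s = t_af[t_af < offset],
        label = "N"
      )
      blocks <- list(
        synth_sinus_block(0, onset, p, onset = onset),
        af_block,
        synth_sinus_block(offset, duration_s, p)
      )
      episodes <- tibble::tibble(rhythm = "AF", onset_s = onset, offset_s = offset)
    }
    beats <- dplyr::bind_rows(blocks)
    beats <- tibble::tibble(
      time_s = beats$time_s,
      rr_ms = c(NA_real_, diff(beats$time_s) * 1000),
      label = beats$label
    )
    af_recording(
      beats, episodes,
      meta = list(
        recording_id = recording_id, patient_id = patient_id,
        recording_date = recording_date, age = age, sex = sex,
        duration_s = duration_s
      )
    )
  })
}

#' Generate a synthetic cohort
#'
#' Generates `n_af + n_nsr` recordings under one [cohort_config()]. A
#' configurable fraction of patients receives two recordings (to exercise the
#' patient-grouped fold rule); per-recording seeds, ages, sexes and dates all
#' derive from the cohort seed, so the cohort is byte-identical across runs.
#' Optionally writes the cohort to disk in the beat-CSV dialect plus a
#' `manifest.json` with the per-recording ground truth.
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Optional output directory; must be empty (or absent) unless
#'   `force = TRUE`.
#' @param force Overwrite a non-empty `out_dir`.
#' @return An `af_cohort`: list with `recordings` (list of
#'   [af_recording()]) and `manifest` (tibble: `recording_id`, `patient_id`,
#'   `class`, `recording_date`, `age`, `sex`, `onset_s`, `offset_s`).
#' @export
generate_cohort <- function(cfg, out_dir = NULL, force = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_af + cfg$n_nsr
  classes <- c(rep("af", cfg$n_af), rep("nsr", cfg$n_nsr))
  rec_ids <- sprintf("R%04d", seq_len(n))

  plan <- withr::with_seed(cfg$seed, {
    # pair recordings into two-recording patients, within class
    k_target <- round(cfg$repeat_patient_frac * n / (1 + cfg$repeat_patient_frac))
    k_af <- min(k_target, cfg$n_af %/% 2)
    k_nsr <- min(k_target - k_af, cfg$n_nsr %/% 2)
    pat_idx <- integer(n)
    nxt <- 1L
    assign_pairs <- function(first, count, k, pat_idx, nxt) {
      i <- first
      for (j in seq_len(k)) {
        pat_idx[c(i, i + 1L)] <- nxt
        nxt <- nxt + 1L
        i <- i + 2L
      }
      while (i < first + count) {
        pat_idx[i] <- nxt
        nxt <- nxt + 1L
        i <- i + 1L
      }
      list(pat_idx = pat_idx, nxt = nxt)
    }
    r <- assign_pairs(1L, cfg$n_af, k_af, pat_idx, nxt)
    r <- assign_pairs(cfg$n_af + 1L, cfg$n_nsr, k_nsr, r$pat_idx, r$nxt)
    pat_idx <- r$pat_idx
    pat_ids <- sprintf("P%04d", pat_idx)

    n_pat <- max(pat_idx)
    stratum <- sample.int(4, n_pat, replace = TRUE, prob = cfg$age_probs)
    lo <- c(40, 60, 70, 80)[stratum]
    hi <- c(60, 70, 80, 92)[stratum]
    pat_age <- lo + runif(n_pat) * (hi - lo)
    pat_sex <- sample(c("M", "F"), n_pat, replace = TRUE)
    first_date <- as.Date("2015-01-01") + sample.int(1825, n_pat, replace = TRUE) - 1

    # between-patient physiology: each patient gets their own resting RR and
    # modulation/noise scales around the population values, shared by both
    # recordings of a two-recording patient
    pat_mean_rr <- pmin(pmax(
      cfg$params$mean_rr_ms + rnorm(n_pat, 0, cfg$mean_rr_between_sd_ms),
      500
    ), 1400)
    pat_amp_mult <- exp(rnorm(n_pat, 0, cfg$amp_between_sdlog))
    pat_lf_mult <- exp(rnorm(n_pat, 0, cfg$amp_between_sdlog))
    pat_noise_mult <- exp(rnorm(n_pat, 0, cfg$noise_between_sdlog))
    # heterogeneous pre-AF phenotype: per-patient vagal-surge strength
    # (mean-preserving lognormal on the boost excess) and alternans burden
    # (Beta around the population fraction)
    s2 <- cfg$boost_between_sdlog
    pat_boost <- 1 + (cfg$params$hf_amp_boost - 1) *
      exp(rnorm(n_pat, -s2^2 / 2, s2))
    cc <- cfg$alternation_between_conc
    p0 <- cfg$params$alternation_prob
    pat_alt_prob <- if (p0 > 0) {
      pmin(rbeta(n_pat, p0 * cc, (1 - p0) * cc), 0.8)
    } else {
      rep(0, n_pat)
    }

    date <- first_date[pat_idx]
    second <- duplicated(pat_idx)
    date[second] <- date[second] + sample.int(370, sum(second), replace = TRUE) + 29

    tibble::tibble(
      recording_id = rec_ids, patient_id = pat_ids, class = classes,
      recording_date = date, age = pat_age[pat_idx], sex = pat_sex[pat_idx],
      mean_rr_ms = pat_mean_rr[pat_idx],
      amp_mult = pat_amp_mult[pat_idx],
      lf_mult = pat_lf_mult[pat_idx],
      noise_mult = pat_noise_mult[pat_idx],
      hf_amp_boost = pat_boost[pat_idx],
      alternation_prob = pat_alt_prob[pat_idx],
      rec_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })

  recordings <- vector("list", n)
  onset <- offset <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p_i <- cfg$params
    p_i$mean_rr_ms <- plan$mean_rr_ms[i]
    p_i$hf_amp_ms <- cfg$params$hf_amp_ms * plan$amp_mult[i]
    p_i$lf_amp_ms <- cfg$params$lf_amp_ms * plan$lf_mult[i]
    p_i$noise_sd_ms <- cfg$params$noise_sd_ms * plan$noise_mult[i]
    p_i$hf_amp_boost <- plan$hf_amp_boost[i]
    p_i$alternation_prob <- plan$alternation_prob[i]
    rec <- generate_recording(
      class = plan$class[i], params = p_i, duration_s = cfg$duration_s,
      seed = plan$rec_seed[i], recording_id = plan$recording_id[i],
      patient_id = plan$patient_id[i], age = plan$age[i], sex = plan$sex[i],
      recording_date = plan$recording_date[i]
    )
    recordings[[i]] <- rec
    if (nrow(rec$episodes) > 0) {
      onset[i] <- rec$episodes$onset_s[1]
      offset[i] <- rec$episodes$offset_s[1]
    }
  }
  manifest <- dplyr::mutate(
    dplyr::select(plan, -"rec_seed"),
    onset_s = onset, offset_s = offset
  )

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
      abort(sprintf("Output directory %s is non-empty; use force = TRUE.", out_dir))
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      write_beats(recordings[[i]], file.path(out_dir, paste0(rec_ids[i], ".csv")))
    }
    mf <- manifest
    mf$recording_date <- format(mf$recording_date)
    jsonlite::write_json(
      mf, file.path(out_dir, "manifest.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  structure(list(recordings = recordings, manifest = manifest),
    class = "af_cohort"
  )
}

#' @export
print.af_cohort <- function(x, ...) {
  cat(sprintf(
    "<af_cohort> %d recordings (%d AF, %d NSR) from %d patients\n",
    nrow(x$manifest), sum(x$manifest$class == "af"),
    sum(x$manifest$class == "nsr"), dplyr::n_distinct(x$manifest$patient_id)
  ))
  invisible(x)
}

#' Read a cohort written by [generate_cohort()]
#'
#' @param dir Directory containing the beat CSVs and `manifest.json`.
#' @return An `af_cohort` (recordings + manifest).
#' @export
read_cohort <- function(dir) {
  mf <- tibble::as_tibble(
    jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  )
  mf$recording_date <- as.Date(mf$recording_date)
  recordings <- lapply(
    mf$recording_id,
    function(id) read_beats(file.path(dir, paste0(id, ".csv")))
  )
  structure(list(recordings = recordings, manifest = mf), class = "af_cohort")
}

#' Standardized feature separation between classes
#'
#' For every feature, the standardized mean difference (SMD) between pre-AF
#' and NSR segments: `(mean_preAF - mean_NSR) / sd_pooled` with the pooled SD
#' `sqrt((var_preAF + var_NSR) / 2)`. A generator-calibration diagnostic: the
#' default parameters are expected to induce SMD > 0.5 for the short-term
#' vagal features (rmssd) and the alternans feature (pas).
#'
#' @param ds An `af_dataset` from [build_dataset()].
#' @return Tibble: `feature`, `smd`, `mean_pre_af`, `mean_nsr`, sorted by
#'   `|smd|` descending.
#' @export
effect_size_report <- function(ds) {
  stopifnot(inherits(ds, "af_dataset"))
  out <- purrr::map_dfr(af_feature_names(), function(f) {
    x1 <- ds[[f]][ds$y == 1]
    x0 <- ds[[f]][ds$y == 0]
    m1 <- mean(x1, na.rm = TRUE)
    m0 <- mean(x0, na.rm = TRUE)
    sp <- sqrt((stats::var(x1, na.rm = TRUE) + stats::var(x0, na.rm = TRUE)) / 2)
    tibble::tibble(
      feature = f,
      smd = if (is.na(sp) || sp == 0) NA_real_ else (m1 - m0) / sp,
      mean_pre_af = m1, mean_nsr = m0
    )
  })
  dplyr::arrange(out, dplyr::desc(abs(.data$smd)))
}
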