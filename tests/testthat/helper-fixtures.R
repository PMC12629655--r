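# Fixture builders: tiny beat-annotated recordings constructed in code.

# beats from an RR sequence (ms); first beat at t0 + rr[1]/1000
beats_from_rr <- function(rr_ms, labels = rep("N", length(rr_ms)), t0 = 0) {
  times <- t0 + cumsum(rr_ms) / 1000
  tibble::tibble(
    time_s = times,
    rr_ms = c(NA_real_, rr_ms[-1]),
    label = labels
  )
}

# constant-RR recording with optional AF episodes; episode spans get the same
# steady beats (rhythm is marked by the annotation, not the beat labels)
make_recording <- function(id = "R001", patient = "P001", duration_s = 86400,
                           rr_ms = 800, episodes = NULL, age = 65,
                           sex = "M", date = "2017-06-01",
                           gap = NULL) {
  n <- floor(duration_s / (rr_ms / 1000)) - 1
  beats <- beats_from_rr(rep(rr_ms, n))
  if (!is.null(gap)) { # remove beats inside [gap[1], gap[2]) to fake dropout
    keep <- beats$time_s < gap[1] | beats$time_s >= gap[2]
    beats <- beats[keep, ]
    beats$rr_ms <- c(NA_real_, diff(beats$time_s) * 1000)
  }
  af_recording(
    beats,
    episodes = episodes,
    meta = list(
      recording_id = id, patient_id = patient, recording_date = date,
      age = age, sex = sex, duration_s = duration_s
    )
  )
}

episode <- function(onset, offset) {
  tibble::tibble(rhythm = "AF", onset_s = onset, offset_s = offset)
}

# noisy sinus recording for feature-bearing fixtures (seeded)
make_noisy_recording <- function(id = "R001", patient = "P001",
                                 duration_s = 50000, seed = 1, class = "nsr",
                                 params = rr_params(), age = 65) {
  generate_recording(
    class = class, params = params, duration_s = duration_s, seed = seed,
    recording_id = id, patient_id = patient, age = age, sex = "F",
    recording_date = as.Date("2016-01-01") + seed
  )
}

# random plausible NN series for property suites
random_nn <- function(n, seed) {
  withr::with_seed(seed, {
    base <- runif(1, 600, 1100)
    x <- base + cumsum(rnorm(n, 0, 8))
    x <- x + rnorm(n, 0, runif(1, 2, 40))
    pmin(pmax(x, 300), 1800)
  })
}
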