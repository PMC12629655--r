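worked_nn <- c(800, 810, 790, 800)

test_that("worked micro-example matches the hand-derived values exactly", {
  td <- time_domain_features(worked_nn)
  expect_equal(td$rmssd, sqrt(200))
  expect_equal(td$sdsd, sqrt(300))
  expect_equal(td$pnn10, 1 / 3)
  expect_equal(td$pnn50, 0)
  expect_equal(td$mean_hr, 75)

  pc <- poincare_features(worked_nn)
  expect_equal(pc$sd1, 10)

  so <- sodp_features(worked_nn)
  expect_equal(so$sodp_q2, 1)
  expect_equal(so$sodp_q4, 1)
  expect_equal(so$sodp_q1, 0)
  expect_equal(so$sodp_q3, 0)
  expect_equal(so$ctm20, 0)
  expect_equal(so$ctm100, 1)

  fr <- fragmentation_features(worked_nn)
  expect_equal(fr$pip, 1)
  expect_equal(fr$pas, 1)
  expect_equal(fr$pss, 1)
})

test_that("every feature matches its independent direct-formula oracle", {
  cfg <- spectral_config()
  for (i in 1:100) {
    n <- withr::with_seed(1000 + i, sample(30:500, 1))
    x <- random_nn(n, seed = 2000 + i)
    got <- featurize_vector(x, NULL, cfg)
    want <- unlist(oracle_all_discrete(x))
    expect_equal(unname(got[names(want)]), unname(want),
      tolerance = 1e-9, label = paste("feature battery, case", i)
    )
  }
})

test_that("frequency features match the explicit-DFT oracle", {
  cfg <- spectral_config()
  for (i in 1:5) {
    n <- 160 + 40 * i
    x <- random_nn(n, seed = 300 + i)
    tt <- cumsum(x) / 1000
    vals <- spline_tachogram_values(x, tt, tt[1], tt[n], 4)
    got <- frequency_features(vals, cfg)
    want <- oracle_frequency(vals, 4, cfg)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9, label = f)
    }
  }
})

test_that("closed-form identities hold", {
  for (i in 1:20) {
    x <- random_nn(withr::with_seed(i, sample(30:300, 1)), seed = 400 + i)
    td <- time_domain_features(x)
    pc <- poincare_features(x)
    so <- sodp_features(x)
    # sd1 = rmssd / sqrt(2), exact
    expect_equal(pc$sd1, td$rmssd / sqrt(2), tolerance = 1e-12)
    # ctm monotone in radius
    expect_lte(so$ctm20, so$ctm50)
    expect_lte(so$ctm50, so$ctm100)
    expect_lte(so$ctm100, 1)
    # quadrant counts + axis points = number of SODP points
    d <- diff(x)
    axis_pts <- sum(d[-length(d)] == 0 | d[-1] == 0)
    expect_equal(
      so$sodp_q1 + so$sodp_q2 + so$sodp_q3 + so$sodp_q4 + axis_pts,
      length(d) - 1
    )
    # order statistics are monotone
    expect_lte(td$prc20_nn, td$median_nn)
    expect_lte(td$median_nn, td$prc80_nn)
    # hrvi >= 1
    expect_gte(td$hrvi, 1)
  }
})

test_that("spectral normalization identities hold", {
  cfg <- spectral_config()
  # Parseval for a pure 0.25-Hz tone: total power within 20% of A^2/2
  t <- seq(0, 300 - 0.25, by = 0.25)
  ff <- frequency_features(800 + 50 * sin(2 * pi * 0.25 * t), cfg)
  expect_lt(abs(ff$total_power - 1250) / 1250, 0.2)
  expect_gt(ff$hf_power / ff$lf_power, 10)

  # LF tone lands in the LF band
  ff2 <- frequency_features(800 + 50 * sin(2 * pi * 0.1 * t), cfg)
  expect_gt(ff2$lf_nu, 0.9)

  # normalized powers always sum to one, including for white noise
  wn <- withr::with_seed(5, 800 + rnorm(1200, 0, 20))
  ff3 <- frequency_features(wn, cfg)
  expect_equal(ff3$lf_nu + ff3$hf_nu, 1)
})

test_that("geometric features recover degenerate and triangular histograms", {
  g1 <- geometric_features(rep(800, 100))
  expect_equal(g1$hrvi, 1)
  expect_equal(g1$tinn, 0)

  # symmetric triangular histogram over k bins: tinn ~ k x 7.8125 ms
  bw <- 7.8125
  k <- 9
  counts <- c(1:5, 4:1) * 8
  x <- unlist(lapply(seq_len(k), function(j) {
    rep((j + 64.5) * bw, counts[j]) # bin centres, away from 0
  }))
  g2 <- geometric_features(x)
  expect_lt(abs(g2$tinn - k * bw), 1.6 * bw)
  expect_equal(g2$hrvi, length(x) / max(counts))
})

test_that("degenerate series produce the documented flags and limits", {
  const <- rep(800, 50)
  td <- time_domain_features(const)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$pnn50, 0)
  expect_equal(td$cvnn, 0)
  pr <- prsa_features(const)
  expect_true(all(is.na(unlist(pr))))

  # linear ramp: constant diffs, so the uncentered SD1 equals step/sqrt(2)
  # (tiny against SD2) and the sympathetic index blows up accordingly
  ramp <- seq(700, 900, by = 2)
  pc <- poincare_features(ramp)
  expect_equal(pc$sd1, 2 / sqrt(2))
  expect_gt(pc$sd2, 50 * pc$sd1)
  expect_equal(pc$csi, pc$sd2 / pc$sd1)
  fr <- fragmentation_features(ramp)
  expect_equal(fr$pip, 0)
  expect_equal(fr$pas, 0)
  expect_equal(fr$ials, 1 / (length(ramp) - 1))
  so <- sodp_features(ramp)
  expect_equal(so$sodp_q1, length(ramp) - 2)

  # long strictly alternating series: pip and pas at their upper limit
  alt <- rep(c(790, 810), 50)
  fr2 <- fragmentation_features(alt)
  expect_equal(fr2$pip, 1)
  expect_equal(fr2$pas, 1)
})

test_that("PRSA matches brute force and behaves on periodic/symmetric input", {
  # strict alternans: the 4-point Bauer window straddles one full period,
  # so deceleration and acceleration capacity are both exactly zero
  alt <- rep(c(790, 810), 20)
  pr <- prsa_features(alt)
  expect_equal(pr$dc, 0)
  expect_equal(pr$ac, 0)
  expect_equal(unclass(pr), unclass(oracle_prsa(alt)), tolerance = 1e-12)

  # sinusoid-modulated series: ac ~ -dc by symmetry (frequency chosen
  # incommensurate with the beat spacing to avoid phase-locking artifacts)
  tt <- cumsum(rep(0.8, 1000))
  x <- 800 + 40 * sin(2 * pi * 0.0773 * tt)
  pr2 <- prsa_features(x)
  expect_gt(pr2$dc, 0)
  expect_lt(pr2$ac, 0)
  expect_lt(abs(pr2$ac + pr2$dc) / pr2$dc, 0.05)
})

test_that("scale equivariance: doubling NN doubles ms-scale features only", {
  for (i in 1:5) {
    x <- random_nn(200, seed = 600 + i)
    a <- featurize_vector(x, NULL)
    b <- featurize_vector(2 * x, NULL)
    for (f in c("sdnn", "rmssd", "sdsd", "sd1", "sd2", "min_nn",
                "max_nn", "median_nn")) {
      expect_equal(b[f], 2 * a[f], tolerance = 1e-9, label = f)
    }
    # tinn scales only approximately: the 7.8125-ms bin grid is fixed, so
    # doubling the data re-quantizes the histogram
    expect_equal(b[["tinn"]], 2 * a[["tinn"]], tolerance = 0.25)
    for (f in c("pip", "ials", "pss", "pas", "cvnn", "cvsd", "sd1_sd2", "csi")) {
      expect_equal(b[f], a[f], tolerance = 1e-9, label = f)
    }
    # ctm on scaled radii: points double, so ctm_r(x) = ctm_2r(2x)
    d <- diff(2 * x)
    px <- d[-length(d)]
    py <- d[-1]
    expect_equal(unname(a["ctm50"]), mean(sqrt(px^2 + py^2) < 100))
  }
})

test_that("featurize returns the full 45-feature schema with flags", {
  expect_equal(length(af_feature_names()), 45)
  expect_false(any(duplicated(af_feature_names())))

  rec <- make_noisy_recording(seed = 4)
  nn <- extract_nn(rec, 1000, 1300)
  tach <- build_tachogram(nn, 1000, 1300, 4)
  row <- featurize(nn, tach)
  expect_setequal(setdiff(names(row), c("n_nn", "n_missing")), af_feature_names())
  expect_equal(row$n_missing, 0)

  # constant series: PRSA missing-flagged, the rest defined
  row2 <- featurize(rep(800, 60), NULL)
  expect_true(is.na(row2$dc))
  expect_equal(row2$rmssd, 0)
  expect_gte(row2$n_missing, 6)
})

test_that("raising HF modulation raises rmssd and hf_power monotonically", {
  vals <- purrr::map(c(10, 20, 40), function(amp) {
    rec <- generate_recording(
      "nsr",
      params = rr_params(hf_amp_ms = amp, pac_rate_per_min = 0),
      duration_s = 20000, seed = 99
    )
    nn <- extract_nn(rec, 1000, 1600)
    tach <- build_tachogram(nn, 1000, 1600, 4)
    v <- featurize_vector(nn, tach)
    c(rmssd = unname(v["rmssd"]), hf = unname(v["hf_power"]))
  })
  rmssd <- vapply(vals, `[[`, 0, "rmssd")
  hf <- vapply(vals, `[[`, 0, "hf")
  expect_true(all(diff(rmssd) > 0))
  expect_true(all(diff(hf) > 0))
})
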