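make_metas <- function(n_pat, recs_per_pat = 1) {
  purrr::map_dfr(seq_len(n_pat), function(i) {
    tibble::tibble(
      recording_id = sprintf("R%02d_%d", i, seq_len(recs_per_pat)),
      patient_id = sprintf("P%02d", i),
      recording_date = as.Date("2015-01-01") + (i - 1) * 37 +
        (seq_len(recs_per_pat) - 1) * 400
    )
  })
}

test_that("temporal folds are contiguous, balanced and patient-grouped", {
  metas <- make_metas(20)
  plan <- make_temporal_folds(metas, n_folds = 10)
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_equal(as.vector(table(plan$fold)), rep(2L, 10))
  # chronological contiguity: fold index is monotone in patient date order
  ord <- metas[order(metas$recording_date), ]
  folds_in_order <- plan$fold[match(ord$recording_id, plan$recording_id)]
  expect_true(all(diff(folds_in_order) >= 0))
  # partition: union = cohort, pairwise disjoint
  expect_setequal(plan$recording_id, metas$recording_id)
  expect_equal(anyDuplicated(plan$recording_id), 0L)
})

test_that("a patient's later recordings stay in the fold of their first", {
  metas <- make_metas(12)
  # one patient with recordings in 2015 and 2019
  metas <- dplyr::bind_rows(metas, tibble::tibble(
    recording_id = "R01_b", patient_id = "P01",
    recording_date = as.Date("2019-06-01")
  ))
  plan <- make_temporal_folds(metas, n_folds = 4)
  f <- plan$fold[plan$patient_id == "P01"]
  expect_equal(length(unique(f)), 1)
  # P01's reference date is the earliest, so it sits in fold 1
  expect_equal(unique(f), 1L)
  expect_error(
    make_temporal_folds(make_metas(5), n_folds = 10),
    class = "afonset_contract_error"
  )
})

test_that("folds are deterministic under re-run and tie-broken by patient id", {
  metas <- make_metas(15)
  metas$recording_date <- as.Date("2016-01-01") # all tied
  p1 <- make_temporal_folds(metas, 5)
  p2 <- make_temporal_folds(metas, 5)
  expect_identical(p1, p2)
  expect_equal(
    p1$fold[match(sort(metas$patient_id), p1$patient_id)],
    rep(1:5, each = 3)
  )
})

small_cv_fixture <- function(seed = 50) {
  recs <- c(
    purrr::map(1:6, function(i) {
      make_noisy_recording(sprintf("RA%02d", i), sprintf("PA%02d", i),
        class = "af", seed = seed + i
      )
    }),
    purrr::map(1:6, function(i) {
      make_noisy_recording(sprintf("RN%02d", i), sprintf("PN%02d", i),
        class = "nsr", seed = seed + 100 + i
      )
    })
  )
  metas <- purrr::map_dfr(recs, function(r)

    tibble::as_tibble(r$meta[c("recording_id", "patient_id", "recording_date")]))
  list(ds = build_dataset(recs), metas = metas)
}

test_that("cross-validated predictions cover every segment exactly once", {
  fx <- small_cv_fixture()
  plan <- make_temporal_folds(fx$metas, n_folds = 4)
  cv <- fit_predict_cv(fx$ds, plan, model_spec("gbt", nrounds = 30), seed = 1)
  expect_equal(nrow(cv$predictions), nrow(fx$ds))
  expect_true(all(cv$predictions$prob >= 0 & cv$predictions$prob <= 1))
  # every test recording predicted exactly once across folds
  by_rec <- dplyr::distinct(cv$predictions, .data$recording_id, .data$fold)
  expect_equal(anyDuplicated(by_rec$recording_id), 0L)

  # engine swap keeps the prediction-set shape identical
  cv_rf <- fit_predict_cv(fx$ds, plan, model_spec("rf", num_trees = 100), seed = 1)
  expect_identical(dim(cv_rf$predictions), dim(cv$predictions))
  expect_identical(names(cv_rf$predictions), names(cv$predictions))

  # determinism probe: shuffling training rows moves AUROC by < 0.01
  ds_shuf <- fx$ds[withr::with_seed(9, sample(nrow(fx$ds))), ]
  if (!inherits(ds_shuf, "af_dataset")) {
    class(ds_shuf) <- c("af_dataset", class(ds_shuf))
  }
  cv2 <- fit_predict_cv(ds_shuf, plan, model_spec("gbt", nrounds = 30), seed = 1)
  a1 <- auroc_rank(cv$predictions$prob, cv$predictions$y)
  a2 <- auroc_rank(cv2$predictions$prob, cv2$predictions$y)
  expect_lt(abs(a1 - a2), 0.01)
})

test_that("patients never straddle folds, even with repeated recordings", {
  # adversarial cohort: one patient contributes 5 recordings across all dates
  recs <- purrr::map(1:5, function(i) {
    make_noisy_recording(sprintf("RX%02d", i), "P_MULTI",
      class = "af", seed = 70 + i
    )
  })
  recs <- c(recs, purrr::map(1:9, function(i) {
    make_noisy_recording(sprintf("RY%02d", i), sprintf("PY%02d", i),
      class = c("af", "nsr")[1 + i %% 2], seed = 80 + i
    )
  }))
  metas <- purrr::map_dfr(recs, function(r) {
    tibble::as_tibble(r$meta[c("recording_id", "patient_id", "recording_date")])
  })
  # spread the multi-recording patient's dates across the whole range
  metas$recording_date[metas$patient_id == "P_MULTI"] <-
    as.Date("2015-01-01") + c(0, 400, 800, 1200, 1600)
  plan <- make_temporal_folds(metas, n_folds = 5)
  expect_equal(length(unique(plan$fold[plan$patient_id == "P_MULTI"])), 1)
  for (f in unique(plan$fold)) {
    train_p <- plan$patient_id[plan$fold != f]
    test_p <- plan$patient_id[plan$fold == f]
    expect_equal(length(intersect(train_p, test_p)), 0)
  }
  ds <- build_dataset(recs)
  cv <- fit_predict_cv(ds, plan, model_spec("gbt", nrounds = 20), seed = 2)
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
})

test_that("aggregation averages segments within windows, then windows", {
  preds <- tibble::tibble(
    recording_id = c("A", "A", "A", "B"),
    patient_id = "P", window_id = c("A:w1", "A:w1", "A:w1", "B:w1"),
    label = "pre_AF", y = 1L, age_group = "<60",
    segment_start_s = c(0, 60, 120, 0),
    fold = 1L, prob = c(0.8, 0.6, 0.7, 0.42)
  )
  rec <- aggregate_to_recording(preds)
  expect_equal(rec$prob[rec$recording_id == "A"], 0.7)
  expect_equal(rec$prob[rec$recording_id == "B"], 0.42) # single segment: identity

  # two windows in one recording: mean of window means, not of segments
  preds2 <- preds
  preds2$window_id <- c("A:w1", "A:w1", "A:w2", "B:w1")
  rec2 <- aggregate_to_recording(preds2)
  expect_equal(rec2$prob[rec2$recording_id == "A"], mean(c(mean(c(0.8, 0.6)), 0.7)))

  # aggregated value bounded by its segment values
  win <- aggregate_to_recording(preds, level = "window")
  expect_true(all(win$prob >= 0.6 & win$prob <= 0.8 | win$recording_id == "B"))
})

test_that("metric suite reproduces hand-computed values", {
  # AUROC 8/9 by exhaustive pair counting
  preds <- tibble::tibble(
    recording_id = paste0("r", 1:6),
    prob = c(0.9, 0.7, 0.4, 0.6, 0.3, 0.2),
    y = c(1L, 1L, 1L, 0L, 0L, 0L)
  )
  m <- classification_metrics(preds, n_boot = 0)
  expect_equal(m$estimate[m$metric == "auroc"], 8 / 9)
  expect_equal(m$estimate[m$metric == "auroc"], oracle_auroc(preds$prob, preds$y))

  # threshold-0.5 confusion family: everything 2/3
  preds2 <- tibble::tibble(
    recording_id = paste0("r", 1:6),
    prob = c(0.9, 0.7, 0.6, 0.4, 0.3, 0.2),
    y = c(1L, 1L, 0L, 1L, 0L, 0L)
  )
  m2 <- classification_metrics(preds2, threshold = 0.5, n_boot = 0)
  for (mm in c("sensitivity", "specificity", "ppv", "npv", "accuracy", "f1")) {
    expect_equal(m2$estimate[m2$metric == mm], 2 / 3, label = mm)
  }

  # perfect separation
  preds3 <- tibble::tibble(
    recording_id = paste0("r", 1:4),
    prob = c(0.9, 0.8, 0.2, 0.1), y = c(1L, 1L, 0L, 0L)
  )
  m3 <- classification_metrics(preds3, n_boot = 0)
  expect_equal(m3$estimate[m3$metric == "auroc"], 1)
  expect_equal(m3$estimate[m3$metric == "auprc"], 1)
})

test_that("AUROC/AUPRC agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  for (i in 1:5) {
    n <- 60
    y <- withr::with_seed(i, sample(0:1, n, TRUE))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    prob <- withr::with_seed(100 + i, round(runif(n), 2)) # ties included
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(y, prob, quiet = TRUE, direction = "<"))
    ))
    expect_equal(auroc_rank(prob, y), ref, tolerance = 1e-12)
    expect_equal(auroc_rank(prob, y), oracle_auroc(prob, y), tolerance = 1e-12)
  }
})

test_that("bootstrap CIs contain the estimate and tighten with cohort size", {
  make_preds <- function(n_per_class, seed) {
    withr::with_seed(seed, tibble::tibble(
      recording_id = paste0("r", seq_len(2 * n_per_class)),
      prob = c(rbeta(n_per_class, 4, 2), rbeta(n_per_class, 2, 4)),
      y = rep(1:0, each = n_per_class)
    ))
  }
  small <- classification_metrics(make_preds(15, 1), n_boot = 300, seed = 3)
  big <- classification_metrics(make_preds(120, 1), n_boot = 300, seed = 3)
  for (mm in unique(small$metric)) {
    est <- small$estimate[small$metric == mm]
    expect_gte(est, small$conf_low[small$metric == mm])
    expect_lte(est, small$conf_high[small$metric == mm])
  }
  w_small <- with(small, conf_high[metric == "auroc"] - conf_low[metric == "auroc"])
  w_big <- with(big, conf_high[metric == "auroc"] - conf_low[metric == "auroc"])
  expect_lt(w_big, w_small)
})

test_that("stratified reports cover every stratum at both levels", {
  fx <- small_cv_fixture(seed = 90)
  plan <- make_temporal_folds(fx$metas, n_folds = 3)
  cv <- fit_predict_cv(fx$ds, plan, model_spec("gbt", nrounds = 20), seed = 4)
  rep <- stratified_report(cv, n_boot = 0)
  strata <- unique(rep$stratum)
  expect_lte(length(strata), 5)
  expect_true("all" %in% strata)
  expect_setequal(unique(rep$level), c("segment", "recording"))
  # schema identical across strata; single-class strata flagged NA, not dropped
  counts <- dplyr::count(rep, .data$stratum, .data$level)
  expect_equal(length(unique(counts$n)), 1)
  # pooled recording-level N equals the sum over age strata
  recs <- aggregate_to_recording(cv)
  expect_equal(
    sum(table(recs$age_group)), nrow(recs)
  )
})

test_that("tidy and glance expose predictions and headline discrimination", {
  fx <- small_cv_fixture(seed = 110)
  plan <- make_temporal_folds(fx$metas, n_folds = 3)
  cv <- fit_predict_cv(fx$ds, plan, model_spec("gbt", nrounds = 20), seed = 5)
  expect_identical(tidy(cv), cv$predictions)
  expect_equal(nrow(tidy(cv, level = "recording")), 12)
  g <- glance(cv)
  expect_equal(g$n_recordings, 12)
  expect_true(g$auroc_segment >= 0 && g$auroc_segment <= 1)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("age and sex enter the model only when requested", {
  fx <- small_cv_fixture(seed = 150)
  plan <- make_temporal_folds(fx$metas, n_folds = 3)
  cv0 <- fit_predict_cv(fx$ds, plan, model_spec("gbt", nrounds = 10), seed = 7)
  cv1 <- fit_predict_cv(
    fx$ds, plan,
    model_spec("gbt", nrounds = 10, include_age_sex = TRUE), seed = 7
  )
  expect_equal(length(cv0$feature_names), 45)
  expect_setequal(setdiff(cv1$feature_names, cv0$feature_names), c("age", "sex_male"))
  m <- classification_metrics(cv1, n_boot = 0)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
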