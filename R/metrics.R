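# AUROC by the Mann-Whitney rank statistic (ties counted half)
auroc_rank <- function(prob, y) {
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    return(NA_real_)
  }
  r <- rank(prob, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# AUPRC by step integration of the precision-recall curve (average
# precision); tied scores are processed as one threshold group.
auprc_step <- function(prob, y) {
  n_pos <- sum(y == 1)
  if (n_pos == 0 || all(y == 1)) {
    return(NA_real_)
  }
  ord <- order(prob, decreasing = TRUE)
  y_ord <- y[ord]
  p_ord <- prob[ord]
  grp_last <- c(p_ord[-1] != p_ord[-length(p_ord)], TRUE)
  tp <- cumsum(y_ord)[grp_last]
  n_pred <- seq_along(y_ord)[grp_last]
  prec <- tp / n_pred
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

confusion_metrics <- function(prob, y, threshold) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0) {
    2 * ppv * sens / (ppv + sens)
  } else {
    NA_real_
  }
  c(
    accuracy = (tp + tn) / length(y), sensitivity = sens, specificity = spec,
    ppv = ppv, npv = npv, f1 = f1
  )
}

point_metrics <- function(prob, y, threshold) {
  c(
    auroc = auroc_rank(prob, y),
    auprc = auprc_step(prob, y),
    confusion_metrics(prob, y, threshold)
  )
}

#' Classification metric suite with bootstrap confidence intervals
#'
#' Computes AUROC (Mann-Whitney rank statistic), AUPRC (step-integrated
#' precision-recall curve) and the threshold metrics accuracy, sensitivity,
#' specificity, PPV, NPV and F1 at the given probability threshold. 95%
#' confidence intervals are percentile-bootstrap over recordings (the
#' independent sampling unit): whole recordings are resampled with
#' replacement, carrying all their rows; resamples that lose one class are
#' redrawn (and counted).
#'
#' @param preds Prediction tibble with columns `prob`, `y`, `recording_id` —
#'   segment-level (from [fit_predict_cv()]) or recording-level (from
#'   [aggregate_to_recording()]). An `af_cv` object is taken at segment
#'   level.
#' @param threshold Decision threshold (default 0.5).
#' @param n_boot Bootstrap resamples (default 1000); 0 skips the CIs.
#' @param seed Seed for the bootstrap (default 1).
#' @param level Label stored with the report, e.g. `"segment"` or
#'   `"recording"`.
#' @param stratum Label for the population stratum (default `"all"`).
#' @return An `af_metrics` tibble: `metric`, `estimate`, `conf_low`,
#'   `conf_high`, `level`, `stratum`, with attributes `threshold`, `n_pos`,
#'   `n_neg`, `n_redrawn`.
#' @export
classification_metrics <- function(preds, threshold = 0.5, n_boot = 1000,
                                   seed = 1, level = "segment",
                                   stratum = "all") {
  if (inherits(preds, "af_cv")) preds <- preds$predictions
  prob <- preds$prob
  y <- preds$y
  if (dplyr::n_distinct(y) < 2) {
    abort("Both classes must be present to compute metrics.",
      class = "afonset_contract_error"
    )
  }
  est <- point_metrics(prob, y, threshold)
  lo <- hi <- rep(NA_real_, length(est))
  n_redrawn <- 0L
  if (n_boot > 0) {
    recs <- unique(preds$recording_id)
    rows_of <- split(seq_len(nrow(preds)), preds$recording_id)[recs]
    boot <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          take <- sample.int(length(recs), replace = TRUE)
          idx <- unlist(rows_of[take], use.names = FALSE)
          if (dplyr::n_distinct(y[idx]) == 2) break
          n_redrawn <<- n_redrawn + 1L
        }
        point_metrics(prob[idx], y[idx], threshold)
      }, numeric(length(est)))
    })
    qs <- apply(boot, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  out <- tibble::tibble(
    metric = names(est), estimate = unname(est),
    conf_low = unname(lo), conf_high = unname(hi),
    level = level, stratum = stratum
  )
  structure(out,
    class = c("af_metrics", class(out)),
    threshold = threshold, n_pos = sum(y == 1), n_neg = sum(y == 0),
    n_redrawn = n_redrawn
  )
}

#' Metrics stratified by age group
#'
#' One metric report per age stratum plus the pooled cohort, at both the
#' segment and recording level. Strata where only one class is present yield
#' `NA` metrics (flagged, not dropped).
#'
#' @param cv An `af_cv` object (or segment-level prediction tibble with an
#'   `age_group` column).
#' @param threshold,n_boot,seed Passed to [classification_metrics()].
#' @return A tibble of stacked `af_metrics` rows over
#'   `stratum x level`.
#' @export
stratified_report <- function(cv, threshold = 0.5, n_boot = 1000, seed = 1) {
  seg <- if (inherits(cv, "af_cv")) cv$predictions else tibble::as_tibble(cv)
  rec <- aggregate_to_recording(seg)
  strata <- c("all", sort(unique(seg$age_group)))
  out <- list()
  for (s in strata) {
    for (lv in c("segment", "recording")) {
      d <- if (lv == "segment") seg else rec
      if (s != "all") d <- d[d$age_group == s, , drop = FALSE]
      if (nrow(d) == 0 || dplyr::n_distinct(d$y) < 2) {
        out[[length(out) + 1L]] <- tibble::tibble(
          metric = names(point_metrics(c(0.1, 0.9), c(0L, 1L), threshold)),
          estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
          level = lv, stratum = s
        )
      } else {
        out[[length(out) + 1L]] <- classification_metrics(
          d,
          threshold = threshold, n_boot = n_boot, seed = seed,
          level = lv, stratum = s
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
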