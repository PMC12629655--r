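nn_values <- function(nn) {
  if (is.numeric(nn)) as.double(nn) else as.double(nn$nn_ms)
}

#' Time-domain HRV features
#'
#' The sixteen time-domain statistics of the NN series: mean heart rate,
#' SDNN, RMSSD, SDSD, the coefficients of variation CVNN and CVSD, the
#' pNN10/20/50 proportions (successive differences *strictly* greater than the
#' threshold), the order statistics (min, max, median, 20th/80th percentile by
#' linear interpolation), and the two geometric measures TINN and HRVi from
#' [geometric_features()].
#'
#' SDNN and SDSD are sample standard deviations (n-1 denominator); RMSSD keeps
#' the plain mean inside the root, per its verbatim definition.
#'
#' @param nn An `nn_series` or a numeric vector of NN intervals in ms.
#' @return Named list of 16 values. `pnn*` are proportions in `[0, 1]`.
#' @export
time_domain_features <- function(nn) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 2) {
    out <- rep(NA_real_, 16)
    names(out) <- c(
      "mean_hr", "sdnn", "rmssd", "sdsd", "cvnn", "cvsd",
      "pnn10", "pnn20", "pnn50", "min_nn", "max_nn", "median_nn",
      "prc20_nn", "prc80_nn", "tinn", "hrvi"
    )
    return(as.list(out))
  }
  d <- diff(x)
  m <- mean(x)
  sdnn <- sd(x)
  sdsd <- sd(d)
  geo <- geometric_features(x)
  q <- unname(quantile(x, c(0.2, 0.8), type = 7))
  list(
    mean_hr = 60000 / m,
    sdnn = sdnn,
    rmssd = sqrt(mean(d^2)),
    sdsd = sdsd,
    cvnn = sdnn / m,
    cvsd = sdsd / m,
    pnn10 = mean(abs(d) > 10),
    pnn20 = mean(abs(d) > 20),
    pnn50 = mean(abs(d) > 50),
    min_nn = min(x),
    max_nn = max(x),
    median_nn = median(x),
    prc20_nn = q[1],
    prc80_nn = q[2],
    tinn = geo$tinn,
    hrvi = geo$hrvi
  )
}

#' Geometric HRV features (TINN and the triangular index)
#'
#' Builds the NN histogram with bins of width 7.8125 ms (1/128 s, the
#' conventional sampling-aligned width) anchored at 0. The HRV triangular
#' index is the number of NN intervals divided by the modal bin count. TINN is
#' the base width `M - N` of the least-squares triangular fit to the
#' histogram: the triangle rises linearly from 0 at `N` to the modal count at
#' the modal bin and falls to 0 at `M`; `N` and `M` are searched over bin
#' centres bracketing the mode (one empty bin beyond the occupied range on
#' each side).
#'
#' @inheritParams time_domain_features
#' @param bin_width_ms Histogram bin width (default 7.8125 ms).
#' @return List with `tinn` (ms) and `hrvi` (unitless, always >= 1).
#' @export
geometric_features <- function(nn, bin_width_ms = 7.8125) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 1) {
    return(list(tinn = NA_real_, hrvi = NA_real_))
  }
  idx <- floor(x / bin_width_ms)
  lo <- min(idx) - 1L
  hi <- max(idx) + 1L
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo + 1L)
  centers <- (lo:hi + 0.5) * bin_width_ms
  m_rel <- which.max(counts)
  peak <- counts[m_rel]
  hrvi <- n / peak
  x_mode <- centers[m_rel]
  k <- length(centers)

  # The squared error of a candidate triangle (N at centre a, M at centre b)
  # separates into an ascending part depending on a only and a descending
  # part depending on b only, so each limb is optimized independently.
  asc_err <- vapply(seq_len(m_rel), function(a) {
    left <- if (a > 1) sum(counts[seq_len(a - 1)]^2) else 0
    if (a == m_rel) {
      return(left) # degenerate limb: all ascending mass in the modal bin
    }
    up <- peak * (centers[a:(m_rel - 1)] - centers[a]) / (x_mode - centers[a])
    left + sum((counts[a:(m_rel - 1)] - up)^2)
  }, 0)
  desc_err <- vapply(m_rel:k, function(b) {
    right <- if (b < k) sum(counts[(b + 1):k]^2) else 0
    if (b == m_rel) {
      return(right)
    }
    down <- peak * (centers[b] - centers[(m_rel + 1):b]) / (centers[b] - x_mode)
    right + sum((counts[(m_rel + 1):b] - down)^2)
  }, 0)
  # ties resolved toward the narrowest triangle
  a_best <- max(which(asc_err <= min(asc_err) + 1e-12))
  b_best <- m_rel - 1L + min(which(desc_err <= min(desc_err) + 1e-12))
  list(tinn = centers[b_best] - centers[a_best], hrvi = hrvi)
}
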