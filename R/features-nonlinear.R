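#' Poincare-plot features
#'
#' From the scatter of consecutive NN pairs `(nn_i, nn_{i+1})`: SD1, the
#' spread perpendicular to the identity line (short-term variability), and
#' SD2, the spread along it (long-term variability). SD1 is the root mean
#' square of `(nn_{i+1} - nn_i) / sqrt(2)` (uncentered, n denominator), which
#' makes the identity `sd1 = rmssd / sqrt(2)` exact; SD2 is the population SD
#' of `(nn_{i+1} + nn_i) / sqrt(2)`. The autonomic indices follow the Toichi
#' convention with axes `T = 4 sd1`, `L = 4 sd2`: `csi = L / T`,
#' `cvi = log10(L T)`; `cvi_modified = log10(T^2 L / T)`, which reduces
#' algebraically to `cvi` (kept as specified for schema compatibility).
#'
#' @inheritParams time_domain_features
#' @return Named list: `sd1`, `sd2` (ms), `sd1_sd2`, `csi`, `cvi`,
#'   `cvi_modified`. When `sd1 = 0` (e.g. a perfectly linear ramp) `csi` is
#'   the finite sentinel `1e6`; log indices are `NA` when either spread is 0.
#' @export
poincare_features <- function(nn) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 3) {
    return(list(
      sd1 = NA_real_, sd2 = NA_real_, sd1_sd2 = NA_real_,
      csi = NA_real_, cvi = NA_real_, cvi_modified = NA_real_
    ))
  }
  d <- diff(x)
  sd1 <- sqrt(mean(d^2) / 2)
  s <- (x[-1] + x[-n]) / sqrt(2)
  sd2 <- sqrt(mean((s - mean(s))^2))
  t_ax <- 4 * sd1
  l_ax <- 4 * sd2
  csi <- if (sd1 > 0) l_ax / t_ax else if (sd2 > 0) 1e6 else NA_real_
  cvi <- if (sd1 > 0 && sd2 > 0) log10(l_ax * t_ax) else NA_real_
  # t_ax^2 * l_ax / t_ax == t_ax * l_ax: identical to cvi by construction
  cvi_mod <- if (sd1 > 0 && sd2 > 0) log10(t_ax^2 * l_ax / t_ax) else NA_real_
  list(
    sd1 = sd1, sd2 = sd2,
    sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_,
    csi = csi, cvi = cvi, cvi_modified = cvi_mod
  )
}

#' Second-order difference plot features
#'
#' The SODP scatters consecutive NN-interval differences
#' `(delta_i, delta_{i+1})`. Features are the strict quadrant counts (Q1:
#' both positive — three-beat decelerations; Q3: both negative; Q2/Q4 the
#' mixed quadrants; points on an axis belong to no quadrant) and the central
#' tendency measures CTM20/50/100: the proportion of points strictly inside a
#' circle of radius 20, 50 or 100 ms centred at the origin.
#'
#' @inheritParams time_domain_features
#' @return Named list: `sodp_q1` .. `sodp_q4` (counts), `ctm20`, `ctm50`,
#'   `ctm100` (proportions of all SODP points).
#' @export
sodp_features <- function(nn) {
  x <- nn_values(nn)
  if (length(x) < 4) {
    return(list(
      sodp_q1 = NA_real_, sodp_q2 = NA_real_, sodp_q3 = NA_real_,
      sodp_q4 = NA_real_, ctm20 = NA_real_, ctm50 = NA_real_,
      ctm100 = NA_real_
    ))
  }
  d <- diff(x)
  px <- d[-length(d)]
  py <- d[-1]
  r <- sqrt(px^2 + py^2)
  list(
    sodp_q1 = sum(px > 0 & py > 0),
    sodp_q2 = sum(px < 0 & py > 0),
    sodp_q3 = sum(px < 0 & py < 0),
    sodp_q4 = sum(px > 0 & py < 0),
    ctm20 = mean(r < 20),
    ctm50 = mean(r < 50),
    ctm100 = mean(r < 100)
  )
}

#' Phase-rectified signal averaging features
#'
#' PRSA aligns the NN series on heart-rate anchor beats and averages, which
#' isolates the mean deceleration/acceleration waveform from overlaid
#' oscillations. Deceleration anchors are beats with `nn_i > nn_{i-1}`,
#' acceleration anchors `nn_i < nn_{i-1}`. With the aligned average `X(j)`
#' (`j = 0` at the anchor) the capacity is
#' `(X(0) + X(1) - X(-1) - X(-2)) / 4`: `dc` from deceleration anchors
#' (reported positive), `ac` from acceleration anchors (negative). The
#' "modified" variants restrict anchors to relative changes of at most
#' `modified_tol` (ectopy protection). `ddck`/`ack` use a wider k-interval
#' wavelet, `(sum_{0..k-1} X - sum_{-k..-1} X) / (2k)`, on the unfiltered
#' deceleration/acceleration anchors. Anchors whose window would cross the
#' series edge are skipped.
#'
#' @inheritParams time_domain_features
#' @param k Wavelet half-width in beats for `ack`/`ddck` (default 4).
#' @param modified_tol Maximum relative change for a "modified" anchor
#'   (default 0.05).
#' @return Named list: `ac`, `dc`, `ac_modified`, `dc_modified`, `ack`,
#'   `ddck` (ms). All `NA` when a variant has no admissible anchor (e.g. a
#'   constant series).
#' @export
prsa_features <- function(nn, k = 4, modified_tol = 0.05) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 4) {
    return(list(
      ac = NA_real_, dc = NA_real_, ac_modified = NA_real_,
      dc_modified = NA_real_, ack = NA_real_, ddck = NA_real_
    ))
  }
  cs <- c(0, cumsum(x))
  prsa2 <- function(anchors) {
    anchors <- anchors[anchors >= 3 & anchors <= n - 1]
    if (length(anchors) == 0) {
      return(NA_real_)
    }
    mean((x[anchors] + x[anchors + 1] - x[anchors - 1] - x[anchors - 2]) / 4)
  }
  prsak <- function(anchors) {
    anchors <- anchors[anchors >= k + 1 & anchors <= n - k + 1]
    if (length(anchors) == 0) {
      return(NA_real_)
    }
    # cumulative sums: sum x[a..a+k-1] = cs[a+k] - cs[a]
    pos <- cs[anchors + k] - cs[anchors]
    neg <- cs[anchors] - cs[anchors - k]
    mean((pos - neg) / (2 * k))
  }
  d <- x[-1] - x[-n]
  i <- 2:n
  dec <- i[d > 0]
  acc <- i[d < 0]
  rel_ok <- abs(d) <= modified_tol * x[-n]
  list(
    ac = prsa2(acc),
    dc = prsa2(dec),
    ac_modified = prsa2(i[d < 0 & rel_ok]),
    dc_modified = prsa2(i[d > 0 & rel_ok]),
    ack = prsak(acc),
    ddck = prsak(dec)
  )
}

# zeros in the difference-sign sequence inherit the previous nonzero sign
# (Costa-style merge); leading zeros inherit the first nonzero sign.
fill_signs <- function(s) {
  nz <- which(s != 0)
  if (length(nz) == 0) {
    return(s)
  }
  idx <- cumsum(s != 0)
  idx[idx == 0] <- 1L
  s[nz][idx]
}

#' Heart-rate fragmentation indices
#'
#' Fragmentation quantifies abnormally frequent reversals of heart-rate
#' acceleration sign in the NN difference series. With the (zero-merged) sign
#' sequence of `delta nn`: `pip` is the fraction of consecutive sign pairs
#' that change sign; acceleration/deceleration segments are maximal runs of
#' constant sign, `ials` is the reciprocal of their mean length and `pss` the
#' fraction of differences in runs shorter than 3; `pas` is the fraction of NN
#' intervals inside alternation segments — stretches where the sign flips at
#' every beat, spanning at least 4 NN intervals (>= 3 alternating
#' differences).
#'
#' @inheritParams time_domain_features
#' @return Named list of proportions: `pip`, `ials`, `pss`, `pas`.
#' @export
fragmentation_features <- function(nn) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 3) {
    return(list(pip = NA_real_, ials = NA_real_, pss = NA_real_, pas = NA_real_))
  }
  d <- diff(x)
  m <- length(d)
  s <- fill_signs(sign(d))
  chg <- s[-1] != s[-m]
  pip <- sum(chg) / (m - 1)
  runs <- rle(s)
  ials <- 1 / mean(runs$lengths)
  pss <- sum(runs$lengths[runs$lengths < 3]) / m
  # alternation segments: maximal TRUE-runs of length >= 2 in the change
  # sequence; a run over changes a..b spans NN intervals a..b+2. Adjacent
  # segments can share a boundary interval, so coverage is a union, not a sum.
  cr <- rle(chg)
  ends <- cumsum(cr$lengths)
  starts <- ends - cr$lengths + 1L
  sel <- which(cr$values & cr$lengths >= 2)
  if (length(sel) > 0) {
    covered <- logical(n)
    for (r in sel) covered[starts[r]:(ends[r] + 2L)] <- TRUE
    pas <- sum(covered) / n
  } else {
    pas <- 0
  }
  list(pip = pip, ials = ials, pss = pss, pas = pas)
}
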