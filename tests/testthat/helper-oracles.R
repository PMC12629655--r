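# Independent direct-formula re-implementations of every feature, written as
# plain loops/explicit sums with no code shared with the package internals.
# These are the ground truth the fast implementations are checked against.

oracle_time <- function(x) {
  n <- length(x)
  d <- x[2:n] - x[1:(n - 1)]
  m <- sum(x) / n
  sdnn <- sqrt(sum((x - m)^2) / (n - 1))
  md <- sum(d) / length(d)
  sdsd <- sqrt(sum((d - md)^2) / (length(d) - 1))
  pct <- function(p) { # linear-interpolation percentile (type 7)
    xs <- sort(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  list(
    mean_hr = 60000 / m,
    sdnn = sdnn,
    rmssd = sqrt(sum(d^2) / length(d)),
    sdsd = sdsd,
    cvnn = sdnn / m,
    cvsd = sdsd / m,
    pnn10 = sum(abs(d) > 10) / length(d),
    pnn20 = sum(abs(d) > 20) / length(d),
    pnn50 = sum(abs(d) > 50) / length(d),
    min_nn = min(x), max_nn = max(x),
    median_nn = pct(0.5), prc20_nn = pct(0.2), prc80_nn = pct(0.8)
  )
}

# exhaustive-search triangular fit on the 7.8125-ms histogram
oracle_geometric <- function(x, bw = 7.8125) {
  bins <- floor(x / bw)
  rng <- (min(bins) - 1):(max(bins) + 1)
  h <- vapply(rng, function(b) sum(bins == b), 0L)
  centers <- (rng + 0.5) * bw
  mi <- which.max(h)
  peak <- h[mi]
  tri <- function(ai, bi) {
    t <- numeric(length(h))
    j <- seq_along(h)
    up <- j >= ai & j <= mi
    down <- j > mi & j <= bi
    t[up] <- if (ai == mi) peak else {
      peak * (centers[up] - centers[ai]) / (centers[mi] - centers[ai])
    }
    t[down] <- if (bi == mi) 0 else {
      peak * (centers[bi] - centers[down]) / (centers[bi] - centers[mi])
    }
    sum((h - t)^2)
  }
  best <- Inf
  width <- 0
  for (ai in 1:mi) {
    for (bi in mi:length(h)) {
      e <- tri(ai, bi)
      w <- centers[bi] - centers[ai]
      if (e < best - 1e-12 || (abs(e - best) <= 1e-12 && w < width)) {
        best <- e
        width <- w
      }
    }
  }
  list(tinn = width, hrvi = length(x) / peak)
}

oracle_poincare <- function(x) {
  n <- length(x)
  p1 <- x[1:(n - 1)]
  p2 <- x[2:n]
  sd1 <- sqrt(sum(((p2 - p1) / sqrt(2))^2) / (n - 1))
  s <- (p2 + p1) / sqrt(2)
  sd2 <- sqrt(sum((s - mean(s))^2) / (n - 1))
  list(
    sd1 = sd1, sd2 = sd2,
    sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_,
    csi = if (sd1 > 0) (4 * sd2) / (4 * sd1) else if (sd2 > 0) 1e6 else NA_real_,
    cvi = if (sd1 * sd2 > 0) log10(4 * sd1 * 4 * sd2) else NA_real_,
    cvi_modified = if (sd1 * sd2 > 0) {
      log10((4 * sd1)^2 * (4 * sd2) / (4 * sd1))
    } else {
      NA_real_
    }
  )
}

oracle_sodp <- function(x) {
  d <- diff(x)
  q <- c(0L, 0L, 0L, 0L)
  inr <- c(0L, 0L, 0L)
  np <- length(d) - 1
  for (i in seq_len(np)) {
    a <- d[i]
    b <- d[i + 1]
    if (a > 0 && b > 0) q[1] <- q[1] + 1L
    if (a < 0 && b > 0) q[2] <- q[2] + 1L
    if (a < 0 && b < 0) q[3] <- q[3] + 1L
    if (a > 0 && b < 0) q[4] <- q[4] + 1L
    r <- sqrt(a^2 + b^2)
    inr <- inr + (r < c(20, 50, 100))
  }
  list(
    sodp_q1 = q[1], sodp_q2 = q[2], sodp_q3 = q[3], sodp_q4 = q[4],
    ctm20 = inr[1] / np, ctm50 = inr[2] / np, ctm100 = inr[3] / np
  )
}

# PRSA via the averaged waveform X(j) (equal by linearity to the per-anchor
# route the package uses)
oracle_prsa <- function(x, k = 4, tol = 0.05) {
  n <- length(x)
  value_at <- function(anchors, half, wide) {
    anchors <- anchors[anchors - half >= 1 & anchors + half - 1 <= n]
    if (length(anchors) == 0) return(NA_real_)
    offs <- (-half):(half - 1)
    X <- vapply(offs, function(j) mean(x[anchors + j]), 0)
    names(X) <- as.character(offs)
    if (!wide) {
      unname((X["0"] + X["1"] - X["-1"] - X["-2"]) / 4)
    } else {
      unname(
        (sum(X[as.character(0:(half - 1))]) -
          sum(X[as.character((-half):(-1))])) / (2 * half)
      )
    }
  }
  dec <- which(c(FALSE, x[-1] > x[-n]))
  acc <- which(c(FALSE, x[-1] < x[-n]))
  small <- which(c(FALSE, abs(x[-1] - x[-n]) <= tol * x[-n]))
  list(
    ac = value_at(acc, 2, FALSE),
    dc = value_at(dec, 2, FALSE),
    ac_modified = value_at(intersect(acc, small), 2, FALSE),
    dc_modified = value_at(intersect(dec, small), 2, FALSE),
    ack = value_at(acc, k, TRUE),
    ddck = value_at(dec, k, TRUE)
  )
}

oracle_fragmentation <- function(x) {
  n <- length(x)
  d <- diff(x)
  m <- length(d)
  s <- sign(d)
  # zeros inherit previous nonzero sign; leading zeros the first nonzero
  first_nz <- 0
  for (i in seq_len(m)) {
    if (s[i] != 0) {
      first_nz <- s[i]
      break
    }
  }
  if (first_nz != 0) {
    prev <- first_nz
    for (i in seq_len(m)) {
      if (s[i] == 0) s[i] <- prev else prev <- s[i]
    }
  }
  changes <- 0L
  for (i in 2:m) if (s[i] != s[i - 1]) changes <- changes + 1L
  # maximal constant-sign runs
  lens <- integer(0)
  cur <- 1L
  for (i in 2:m) {
    if (s[i] == s[i - 1]) {
      cur <- cur + 1L
    } else {
      lens <- c(lens, cur)
      cur <- 1L
    }
  }
  lens <- c(lens, cur)
  # alternation segments: maximal stretches of per-step sign change covering
  # >= 4 NN intervals (>= 3 alternating differences)
  covered <- logical(n)
  i <- 1L
  while (i <= m - 1) {
    if (s[i + 1] != s[i]) {
      j <- i
      while (j <= m - 1 && s[j + 1] != s[j]) j <- j + 1L
      n_diff <- j - i + 1L
      if (n_diff >= 3) covered[i:(j + 1)] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(
    pip = changes / (m - 1),
    ials = 1 / (sum(lens) / length(lens)),
    pss = sum(lens[lens < 3]) / m,
    pas = sum(covered) / n
  )
}

# explicit-DFT Welch oracle (same estimator definition, independent route:
# per-frequency cosine/sine sums instead of fft)
oracle_frequency <- function(vals, fs, cfg) {
  n <- length(vals)
  nper <- min(cfg$seg_len_samples, n)
  step <- max(1, floor(nper * (1 - cfg$overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / (nper - 1))
  nf <- nper %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / nper
  psd <- numeric(nf)
  tt <- (1:nper) - (nper + 1) / 2
  for (s0 in starts) {
    y <- vals[s0:(s0 + nper - 1)]
    y <- y - mean(y) - tt * sum(tt * y) / sum(tt^2)
    yw <- y * w
    for (ki in seq_len(nf)) {
      kk <- ki - 1
      re <- sum(yw * cos(2 * pi * kk * (0:(nper - 1)) / nper))
      im <- -sum(yw * sin(2 * pi * kk * (0:(nper - 1)) / nper))
      p <- (re^2 + im^2) / (fs * sum(w^2))
      if (kk != 0 && !(nper %% 2 == 0 && ki == nf)) p <- 2 * p
      psd[ki] <- psd[ki] + p
    }
  }
  psd <- psd / length(starts)
  bp <- function(band) {
    sel <- freqs >= band[1] & freqs <= band[2]
    f <- freqs[sel]
    p <- psd[sel]
    if (length(f) < 2) return(0)
    s <- 0
    for (i in 2:length(f)) s <- s + (f[i] - f[i - 1]) * (p[i] + p[i - 1]) / 2
    s
  }
  lf <- bp(cfg$lf_band)
  hf <- bp(cfg$hf_band)
  list(
    total_power = bp(cfg$total_band), lf_power = lf, hf_power = hf,
    lf_nu = lf / (lf + hf), hf_nu = hf / (lf + hf),
    lf_hf_ratio = if (hf > 0) lf / hf else if (lf > 0) 1e6 else NA_real_
  )
}

oracle_all_discrete <- function(x) {
  c(
    oracle_time(x), oracle_geometric(x), oracle_poincare(x),
    oracle_sodp(x), oracle_prsa(x), oracle_fragmentation(x)
  )
}

# AUROC by exhaustive positive-negative pair counting
oracle_auroc <- function(prob, y) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# path-dependent conditional expectation of one xgboost tree: features in S
# follow their split, absent features average the children cover-weighted
tree_expectation <- function(tree, x, S) {
  node_row <- function(id) tree[tree$ID == id, , drop = FALSE]
  rec <- function(id) {
    nd <- node_row(id)
    if (nd$Feature == "Leaf") {
      return(nd$Gain)
    }
    if (nd$Feature %in% S) {
      xv <- x[[nd$Feature]]
      nxt <- if (is.na(xv)) nd$Missing else if (xv < nd$Split) nd$Yes else nd$No
      return(rec(nxt))
    }
    cy <- node_row(nd$Yes)$Cover
    cn <- node_row(nd$No)$Cover
    (cy * rec(nd$Yes) + cn * rec(nd$No)) / (cy + cn)
  }
  rec(tree$ID[1])
}

# exact Shapley values by 2^p coalition enumeration over the ensemble's
# expectation function
brute_force_shap <- function(fit, x_row, features) {
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit))
  trees <- split(tr, tr$Tree)
  v <- function(S) {
    sum(vapply(trees, tree_expectation, 0, x = x_row, S = S))
  }
  p <- length(features)
  subsets <- lapply(0:(2^p - 1), function(m) features[bitwAnd(m, 2^(0:(p - 1))) > 0])
  key_of <- function(s) paste0("k:", paste(sort(s), collapse = ","))
  vals <- vapply(subsets, v, 0)
  names(vals) <- vapply(subsets, key_of, "")
  phi <- numeric(p)
  names(phi) <- features
  for (j in features) {
    others <- setdiff(features, j)
    for (m in 0:(2^(p - 1) - 1)) {
      S <- others[bitwAnd(m, 2^(seq_len(p - 1) - 1)) > 0]
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      key_s <- key_of(S)
      key_sj <- key_of(c(S, j))
      phi[j] <- phi[j] + w * (vals[[key_sj]] - vals[[key_s]])
    }
  }
  phi
}


toy_shap_model <- function(p = 5, n = 200, nrounds = 8, depth = 3, seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n)
    colnames(x) <- paste0("f", seq_len(p))
    y <- as.integer(x[, 1] + 0.5 * x[, 2] - x[, 3] + rnorm(n, 0, 0.3) > 0)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = depth,
                    eta = 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = nrounds, verbose = 0
    )
    list(fit = fit, x = x, y = y)
  })
}

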