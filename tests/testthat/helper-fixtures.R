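# Shared fixtures (memoized: generated once per test run) and independent
# brute-force oracles used across the suite.

fixture_env <- new.env(parent = emptyenv())

# Modest expert session exercising every stage: 4 SOMIs (3 ChR2-projecting),
# 10 PCs (6 granule-like, 4 mossy-like: 2 SOM-inhibited, 2 disinhibited),
# 2 FSIs, 12 laps, light + sensory protocols.
small_fixture <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- synth_config(
      n_laps = 12, seed = 101,
      units = default_unit_specs("expert", n_somi = 4, n_pc = 10, n_fsi = 2),
      light = list(dg_50 = 30, fimbria_50 = 30, isi_s = 5, gain = 10),
      sensory = list(kinds = c("random_reward", "stim_airpuff"), n_each = 16,
                     duration_s = 0.5, isi_s = 5, gain = 3))
    fixture_env$small <- generate_session(cfg)
  }
  fixture_env$small
}

test_config <- function(...) {
  pipeline_config(seed = 11, n_perm = 100, n_shuffle = 200, ...)
}

# Homogeneous Poisson train (package generator with a constant profile).
poisson_train <- function(rate, duration, seed) {
  generate_spike_train(function(t) rep(rate, length(t)), c(0, duration),
                       max(rate, 1e-9), seed)
}

# O(n^2) autocorrelogram: every ordered pair, positive lags.
oracle_autocorr <- function(st, bin_ms = 1, max_lag_ms = 300) {
  nb <- ceiling(max_lag_ms / bin_ms)
  lags <- as.vector(outer(st, st, "-")) * 1000
  lags <- lags[lags > 0 & lags <= max_lag_ms]
  tabulate(pmin(ceiling(lags / bin_ms), nb), nbins = nb)
}

# O(n_pre * n_post) cross-correlogram over (-max, +max].
oracle_ccg <- function(pre, post, bin_ms = 0.5, max_lag_ms = 50) {
  nb <- 2 * ceiling(max_lag_ms / bin_ms)
  lags <- as.vector(outer(post, pre, "-")) * 1000
  lags <- lags[lags > -max_lag_ms & lags <= max_lag_ms]
  tabulate(pmax(pmin(ceiling((lags + max_lag_ms) / bin_ms), nb), 1L), nbins = nb)
}

# Brute-force peri-event histogram: one row per event.
oracle_align <- function(st, events, window, bin) {
  nb <- round(diff(window) / bin)
  t(vapply(events, function(ev) {
    rel <- st - ev
    counts <- integer(nb)
    for (b in seq_len(nb)) {
      lo <- window[1] + (b - 1) * bin
      counts[b] <- sum(rel >= lo & rel < lo + bin)
    }
    counts
  }, integer(nb)))
}

# Normal-equation OLS slope/intercept.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Direct Gaussian-sum KDE with reflection, matching the documented estimator.
oracle_kde <- function(rel, n_trials, window, h, grid_dt, floor_hz) {
  grid <- seq(window[1], window[2], by = grid_dt)
  pts <- c(rel, 2 * window[1] - rel, 2 * window[2] - rel)
  lam <- sapply(grid, function(g) sum(exp(-(g - pts)^2 / (2 * h^2))) /
                  (h * sqrt(2 * pi))) / n_trials
  pmax(lam, floor_hz)
}

# Exhaustive per-sample scan implementing the documented transition rules.
oracle_transitions <- function(time, speed, lo = 0.5, hi = 3,
                               min_imm_s = 3, max_tr_s = 3) {
  dt <- time[2] - time[1]
  n <- length(speed)
  min_imm <- ceiling(min_imm_s / dt)
  max_tr <- floor(max_tr_s / dt)
  ons <- offs <- numeric(0)
  for (i in seq(2, n)) {
    # onset candidate: sample i is first >= lo after >= 3 s of < lo
    if (speed[i] >= lo && speed[i - 1] < lo) {
      run <- 0
      j <- i - 1
      while (j >= 1 && speed[j] < lo) { run <- run + 1; j <- j - 1 }
      if (run >= min_imm) {
        seg <- speed[i:min(n, i - 1 + max_tr)]
        r <- which(seg >= hi)
        b <- which(seg < lo)
        if (length(r) && (!length(b) || min(r) < min(b))) ons <- c(ons, time[i])
      }
    }
    # offset candidate: sample i is first <= hi after locomotion
    if (speed[i] <= hi && speed[i - 1] > hi) {
      seg <- speed[i:min(n, i - 1 + max_tr)]
      d <- which(seg < lo)
      b <- which(seg > hi)
      if (length(d) && (!length(b) || min(d) < min(b))) {
        j <- i - 1 + min(d)
        rem <- speed[j:min(n, j + min_imm - 1)]
        if (length(rem) >= min_imm && all(rem < lo)) offs <- c(offs, time[i])
      }
    }
  }
  list(onsets = ons, offsets = offs)
}
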