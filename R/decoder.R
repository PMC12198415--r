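#' Kernel-density firing-rate estimate on a window
#'
#' Gaussian KDE (default bandwidth 200 ms) of spike times pooled over
#' training trials, normalized to Hz by the trial count, with
#' reflected-boundary edge correction at both window edges and a floor rate
#' (default 0.1 Hz) keeping subsequent log-likelihoods finite.
#'
#' @param rel_times Spike times relative to the event (s), pooled over
#'   trials, already restricted to `window`.
#' @param n_trials Number of training trials pooled.
#' @param window Length-2 estimation window (s).
#' @param config A [pipeline_config()] (bandwidth, grid step, floor).
#' @return Tibble `t` (grid), `rate_hz`.
#' @export
kde_rate <- function(rel_times, n_trials, window,
                     config = pipeline_config()) {
  stopifnot(n_trials >= 1)
  h <- config$kde_bandwidth_s
  grid <- seq(window[1], window[2], by = config$kde_grid_s)
  if (!length(rel_times)) {
    return(tibble::tibble(t = grid, rate_hz = rep(config$rate_floor_hz,
                                                  length(grid))))
  }
  pts <- c(rel_times, 2 * window[1] - rel_times, 2 * window[2] - rel_times)
  lam <- vapply(grid, function(g) sum(dnorm(g, pts, h)), numeric(1)) / n_trials
  tibble::tibble(t = grid, rate_hz = pmax(lam, config$rate_floor_hz))
}

#' Time-resolved Poisson count log-likelihood
#'
#' `sum_bins [ n log(lambda dt) - lambda dt - log(n!) ]` with the rate
#' averaged over each bin. Accepts non-integer counts (residualized
#' activity) through the gamma function.
#'
#' @param counts Spike counts per bin.
#' @param lambda_bin Rate (Hz) per bin.
#' @param dt_bin Bin width (s).
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(counts, lambda_bin, dt_bin = 0.25) {
  mu <- lambda_bin * dt_bin
  sum(counts * log(mu) - mu - lgamma(counts + 1))
}

# Average a KDE rate over likelihood bins anchored at `start`.
rate_in_bins <- function(kde, start, n_bins, dt_bin) {
  vapply(seq_len(n_bins), function(b) {
    lo <- start + (b - 1) * dt_bin
    hi <- start + b * dt_bin
    sel <- kde$t >= lo - 1e-9 & kde$t < hi - 1e-9
    if (!any(sel)) return(kde$rate_hz[which.min(abs(kde$t - (lo + hi) / 2))])
    mean(kde$rate_hz[sel])
  }, numeric(1))
}

# Spike times relative to each event, clipped to a window: list per trial.
trial_spikes <- function(spike_times, event_times, window) {
  lo <- findInterval(event_times + window[1], spike_times, left.open = TRUE)
  hi <- findInterval(event_times + window[2], spike_times)
  purrr::map(seq_along(event_times), function(i) {
    if (hi[i] > lo[i]) spike_times[(lo[i] + 1):hi[i]] - event_times[i]
    else numeric(0)
  })
}

# Internal decoding engine shared by single-cell and population decoders.
# cells: list of per-trial relative spike-time lists (all relative to reward).
# Returns per-pattern summed log-likelihood matrices and truth.
decode_core <- function(cells, n_trials, L, config,
                        counts_override = NULL) {
  bwin <- config$baseline_period_s
  ewin <- config$expectation_window_s
  dtb <- config$lik_bin_s
  nb <- round(L / dtb)
  if (L > diff(bwin) + 1e-9 || L > diff(ewin) + 1e-9) return(NULL)
  folds <- list(even = seq(2, n_trials, by = 2), odd = seq(1, n_trials, by = 2))
  patt_ll <- list()
  truth <- list()
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n_trials), test)
    ll_b <- ll_e <- matrix(0, nrow = length(test) * 2, ncol = length(cells))
    for (ci in seq_along(cells)) {
      tr_sp <- cells[[ci]]
      kb <- kde_rate(unlist(purrr::map(tr_sp[train], ~ .x[.x >= bwin[1] & .x <= bwin[2]])),
                     length(train), bwin, config)
      ke <- kde_rate(unlist(purrr::map(tr_sp[train], ~ .x[.x >= ewin[1] & .x <= ewin[2]])),
                     length(train), ewin, config)
      lam_b <- rate_in_bins(kb, bwin[1], nb, dtb)
      lam_e <- rate_in_bins(ke, ewin[1], nb, dtb)
      row <- 0
      for (tt in test) {
        for (cls in 1:2) {
          row <- row + 1
          w0 <- if (cls == 1) bwin[1] else ewin[1]
          cnts <- if (is.null(counts_override)) {
            edges <- w0 + dtb * (0:nb)
            bin_counts(tr_sp[[tt]], edges)
          } else {
            counts_override(ci, tt, w0, nb)
          }
          ll_b[row, ci] <- poisson_loglik(cnts, lam_b, dtb)
          ll_e[row, ci] <- poisson_loglik(cnts, lam_e, dtb)
        }
      }
    }
    patt_ll[[f]] <- list(b = ll_b, e = ll_e)
    truth[[f]] <- rep(c(1, 2), length(test))   # 1 baseline, 2 expectation
  }
  list(ll = patt_ll, truth = truth)
}

accuracy_from_ll <- function(core, cell_idx) {
  correct <- total <- 0
  for (f in seq_along(core$ll)) {
    sb <- rowSums(core$ll[[f]]$b[, cell_idx, drop = FALSE])
    se <- rowSums(core$ll[[f]]$e[, cell_idx, drop = FALSE])
    pred <- ifelse(se > sb, 2, 1)
    correct <- correct + sum(pred == core$truth[[f]])
    total <- total + length(pred)
  }
  correct / total
}

shuffle_null <- function(core, cell_idx, n_shuffle, seed) {
  preds <- truths <- integer(0)
  for (f in seq_along(core$ll)) {
    sb <- rowSums(core$ll[[f]]$b[, cell_idx, drop = FALSE])
    se <- rowSums(core$ll[[f]]$e[, cell_idx, drop = FALSE])
    preds <- c(preds, ifelse(se > sb, 2, 1))
    truths <- c(truths, core$truth[[f]])
  }
  with_seed(seed, {
    vapply(seq_len(n_shuffle), function(j)
      mean(preds == sample(truths)), numeric(1))
  })
}

#' Single-cell baseline-vs-expectation decoding
#'
#' Rate models for the baseline period (the 2.75 s ending 1.5 s before
#' reward) and the expectation period (-1.5 to +1.5 s around reward) are
#' estimated by Gaussian KDE on training trials; each held-out trial
#' contributes one test pattern per class (a window of length L anchored at
#' the class-window start) classified by the larger time-resolved Poisson
#' log-likelihood. Two-fold even/odd cross-validation; accuracy is the
#' fraction correct over all test patterns; significance compares the
#' accuracy with the 99th percentile of label-shuffled accuracies.
#'
#' @param spike_times Sorted spike times (s).
#' @param reward_times Reward onsets (s).
#' @param config A [pipeline_config()].
#' @param lengths Decoding window lengths (s); default 0.25 to 2.75.
#' @param seed Seed for the shuffles.
#' @return Tibble of class `decode_result`: per length `L`, `accuracy`,
#'   `null_q`, `significant`; attribute `min_significant_L`.
#' @export
decode_single <- function(spike_times, reward_times,
                          config = pipeline_config(),
                          lengths = NULL, seed = 1L) {
  lengths <- lengths %||% config$decode_lengths_s
  n_trials <- length(reward_times)
  if (n_trials < 6) abort("at least 6 trials required for decoding")
  full <- range(c(config$baseline_period_s, config$expectation_window_s))
  cells <- list(trial_spikes(spike_times, reward_times, full))
  rows <- purrr::map_dfr(lengths, function(L) {
    core <- decode_core(cells, n_trials, L, config)
    if (is.null(core)) {
      return(tibble::tibble(L = L, accuracy = NA_real_, null_q = NA_real_,
                            significant = NA))
    }
    acc <- accuracy_from_ll(core, 1)
    null <- shuffle_null(core, 1, config$n_shuffle,
                         stage_seed(seed, paste0("shuf", L)))
    q <- unname(quantile(null, config$shuffle_quantile))
    tibble::tibble(L = L, accuracy = acc, null_q = q, significant = acc > q)
  })
  sigL <- rows$L[which(rows$significant)]
  structure(rows, class = c("decode_result", class(rows)),
            min_significant_L = if (length(sigL)) min(sigL) else NA_real_)
}

#' Population decoding over increasing cell subsets
#'
#' Sums the per-cell Poisson log-likelihoods before taking the maximum, for
#' random cell subsets of each requested size (50 draws per size), under
#' the same even/odd two-fold scheme as [decode_single()].
#'
#' @param spike_trains List of sorted spike-time vectors (one per cell).
#' @param reward_times Reward onsets (s).
#' @param L Decoding window length (s).
#' @param subset_sizes Cell-subset sizes; defaults to `1:n_cells`.
#' @param config A [pipeline_config()].
#' @param seed Seed for subset draws.
#' @return Tibble of class `decode_result`: `n_cells`, `accuracy` (mean over
#'   draws), `accuracy_sd`, `n_draws`.
#' @export
decode_population <- function(spike_trains, reward_times, L = 1.5,
                              subset_sizes = NULL,
                              config = pipeline_config(), seed = 1L) {
  n_cells <- length(spike_trains)
  if (n_cells < 1) abort("at least one cell required")
  subset_sizes <- subset_sizes %||% seq_len(n_cells)
  clipped <- subset_sizes > n_cells
  subset_sizes[clipped] <- n_cells
  n_trials <- length(reward_times)
  full <- range(c(config$baseline_period_s, config$expectation_window_s))
  cells <- purrr::map(spike_trains, trial_spikes,
                      event_times = reward_times, window = full)
  core <- decode_core(cells, n_trials, L, config)
  if (is.null(core)) abort("decoding window exceeds the class windows")
  rows <- purrr::map_dfr(seq_along(subset_sizes), function(si) {
    k <- subset_sizes[si]
    accs <- if (k == n_cells) {
      accuracy_from_ll(core, seq_len(n_cells))
    } else {
      with_seed(stage_seed(seed, paste0("subset", si)), {
        vapply(seq_len(config$subset_draws), function(d)
          accuracy_from_ll(core, sample(n_cells, k)), numeric(1))
      })
    }
    tibble::tibble(n_cells = k, accuracy = mean(accs),
                   accuracy_sd = if (length(accs) > 1) sd(accs) else 0,
                   n_draws = length(accs), clipped = clipped[si])
  })
  structure(rows, class = c("decode_result", class(rows)), L = L)
}

#' Population decoding on GLM-residualized activity
#'
#' Replaces each cell's binned counts by counts minus the speed and
#' acceleration partial predictions of its encoding model (floored at 0),
#' re-estimates the class rate models from the residualized training
#' activity (per-bin means), and decodes as in [decode_population()].
#'
#' @param session A `somipipe_session`.
#' @param unit_ids Cells to decode (must have GLM fits).
#' @param glm_coefs Named list per unit id: coefficients with elements
#'   `speed` and `accel` (e.g. from fitting [build_design()]).
#' @param L Decoding window length (s).
#' @param config A [pipeline_config()].
#' @return Tibble like [decode_population()] for the full population, plus
#'   attribute `skipped` (units without fits).
#' @export
residualized_decode <- function(session, unit_ids, glm_coefs, L = 1.5,
                                config = pipeline_config()) {
  rewards <- session$events$time[session$events$kind == "reward"]
  n_trials <- length(rewards)
  full <- range(c(config$baseline_period_s, config$expectation_window_s))
  dtb <- config$lik_bin_s
  nb_full <- round(diff(full) / dtb)
  sp_fn <- approxfun(session$behavior$time, session$behavior$speed, rule = 2)
  have <- unit_ids %in% names(glm_coefs)
  skipped <- unit_ids[!have]
  unit_ids <- unit_ids[have]
  if (!length(unit_ids)) abort("no units with GLM fits")
  # residualized count tensor: cell x trial x bin over the full window
  resid <- purrr::map(unit_ids, function(uid) {
    st <- session$units$spike_times[[match(uid, session$units$unit_id)]]
    b <- glm_coefs[[uid]]
    t(vapply(rewards, function(tr) {
      edges <- tr + full[1] + dtb * (0:nb_full)
      cnt <- bin_counts(st, edges)
      centers <- edges[-1] - dtb / 2
      spd <- sp_fn(centers)
      acc <- c(0, diff(spd)) / dtb
      pmax(cnt - ((b["speed"] %||% 0) * spd + (b["accel"] %||% 0) * acc) * dtb, 0)
    }, numeric(nb_full)))
  })
  bwin <- config$baseline_period_s
  ewin <- config$expectation_window_s
  nb <- round(L / dtb)
  folds <- list(even = seq(2, n_trials, by = 2), odd = seq(1, n_trials, by = 2))
  correct <- total <- 0
  bin_start <- function(w0) round((w0 - full[1]) / dtb)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n_trials), test)
    lam <- purrr::map(resid, function(m) {
      mtr <- m[train, , drop = FALSE]
      rate <- colMeans(mtr) / dtb
      pmax(rate, config$rate_floor_hz)
    })
    for (tt in test) {
      for (cls in 1:2) {
        w0 <- if (cls == 1) bwin[1] else ewin[1]
        idx <- bin_start(w0) + seq_len(nb)
        sb <- se <- 0
        for (ci in seq_along(resid)) {
          cnts <- resid[[ci]][tt, idx]
          ib <- bin_start(bwin[1]) + seq_len(nb)
          ie <- bin_start(ewin[1]) + seq_len(nb)
          sb <- sb + poisson_loglik(cnts, lam[[ci]][ib], dtb)
          se <- se + poisson_loglik(cnts, lam[[ci]][ie], dtb)
        }
        pred <- if (se > sb) 2 else 1
        correct <- correct + (pred == cls)
        total <- total + 1
      }
    }
  }
  structure(tibble::tibble(n_cells = length(unit_ids),
                           accuracy = correct / total,
                           accuracy_sd = 0, n_draws = 1, clipped = FALSE),
            class = c("decode_result", "tbl_df", "tbl", "data.frame"),
            L = L, skipped = skipped)
}
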