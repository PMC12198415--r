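test_that("KDE rate matches the direct Gaussian-sum oracle", {
  cfg <- pipeline_config()
  set.seed(61)
  rel <- runif(40, -4.25, -1.5)
  win <- cfg$baseline_period_s
  k <- kde_rate(rel, n_trials = 8, window = win, config = cfg)
  o <- oracle_kde(rel, 8, win, cfg$kde_bandwidth_s, cfg$kde_grid_s,
                  cfg$rate_floor_hz)
  expect_equal(k$rate_hz, o, tolerance = 1e-10)

  # mass conservation: the estimate integrates to spikes per trial within 5%
  expect_lt(abs(sum(k$rate_hz) * cfg$kde_grid_s - length(rel) / 8) /
              (length(rel) / 8), 0.05)

  # single spike, one trial: a Gaussian bump peaking at the spike time
  k1 <- kde_rate(-3, 1, win, cfg)
  expect_lt(abs(k1$t[which.max(k1$rate_hz)] - (-3)), cfg$kde_grid_s + 1e-9)

  # no spikes: flat floor rate
  k0 <- kde_rate(numeric(0), 5, win, cfg)
  expect_true(all(k0$rate_hz == cfg$rate_floor_hz))
})

test_that("homogeneous training data recovers the true rate away from edges", {
  cfg <- pipeline_config()
  win <- c(-4.25, -1.5)
  n_trials <- 60
  rel <- unlist(lapply(seq_len(n_trials), function(i) {
    st <- poisson_train(5, diff(win), seed = 800 + i)
    st + win[1]
  }))
  k <- kde_rate(rel, n_trials, win, cfg)
  inner <- k$t > win[1] + 0.4 & k$t < win[2] - 0.4
  expect_lt(abs(mean(k$rate_hz[inner]) - 5), 3 * sqrt(5 / (n_trials * diff(win))))
})

test_that("Poisson log-likelihood has its closed forms", {
  expect_equal(poisson_loglik(rep(0, 6), rep(4, 6), 0.25), -6)
  n <- c(2, 0, 3)
  lam <- c(4, 2, 8)
  manual <- sum(n * log(lam * 0.25) - lam * 0.25 - lfactorial(n))
  expect_equal(poisson_loglik(n, lam, 0.25), manual)
})

test_that("decoding sits at chance without rate separation and at ceiling with it", {
  cfg <- test_config()
  rw <- seq(30, 30 + 29 * 15, by = 15)
  st_null <- poisson_train(5, 500, 66)
  res <- decode_single(st_null, rw, cfg, lengths = 1.5, seed = 2)
  expect_lt(abs(res$accuracy - 0.5), 0.25)   # 3 sigma at 60 test patterns
  expect_false(isTRUE(res$significant))

  # strong step modulation: near-perfect decoding
  rate_fn <- function(t) {
    r <- rep(2, length(t))
    for (e in rw) r[t >= e - 1.5 & t < e] <- 40
    r
  }
  st_big <- generate_spike_train(rate_fn, c(0, 500), 41, seed = 67)
  res2 <- decode_single(st_big, rw, cfg, lengths = 1.5, seed = 3)
  expect_gte(res2$accuracy, 0.95)
  expect_true(res2$significant)
})

test_that("the shuffle null is centered at chance", {
  cfg <- test_config()
  rw <- seq(30, 30 + 29 * 15, by = 15)
  st <- poisson_train(5, 500, 68)
  full <- range(c(cfg$baseline_period_s, cfg$expectation_window_s))
  cells <- list(somipipe:::trial_spikes(st, rw, full))
  core <- somipipe:::decode_core(cells, length(rw), 1.5, cfg)
  null <- somipipe:::shuffle_null(core, 1, 500, seed = 5)
  expect_lt(abs(mean(null) - 0.5), 3 * sd(null) / sqrt(500))
})

test_that("one-cell population decoding reproduces the single-cell result", {
  cfg <- test_config()
  rw <- seq(30, 30 + 23 * 15, by = 15)
  rate_fn <- function(t) {
    r <- rep(5, length(t))
    for (e in rw) r[t >= e - 1.5 & t < e] <- 10
    r
  }
  st <- generate_spike_train(rate_fn, c(0, 400), 11, seed = 71)
  acc_single <- decode_single(st, rw, cfg, lengths = 1.5, seed = 4)$accuracy
  pop <- decode_population(list(st), rw, L = 1.5, subset_sizes = 1,
                           config = cfg, seed = 4)
  expect_equal(pop$accuracy, acc_single)
  expect_true(pop$clipped[1] == FALSE)
  # oversized subsets are clipped with a flag
  pop2 <- decode_population(list(st), rw, L = 1.5, subset_sizes = 3,
                            config = cfg, seed = 4)
  expect_true(pop2$clipped[1])
})

test_that("accuracy grows with the rate separation between classes", {
  cfg <- test_config()
  rw <- seq(30, 30 + 19 * 15, by = 15)
  mean_acc <- sapply(c(1, 1.5, 2, 3), function(g) {
    accs <- sapply(1:25, function(k) {
      rate_fn <- function(t) {
        r <- rep(5, length(t))
        for (e in rw) r[t >= e - 1.5 & t < e] <- 5 * g
        r
      }
      st <- generate_spike_train(rate_fn, c(0, 350), 5 * g + 1,
                                 seed = 9000 + 100 * g + k)
      decode_population(list(st), rw, L = 1.5, subset_sizes = 1,
                        config = cfg, seed = k)$accuracy
    })
    mean(accs)
  })
  expect_true(all(diff(mean_acc) > -0.03))
  expect_gt(mean_acc[4], mean_acc[1] + 0.2)
})

test_that("large-gain single-cell accuracy approaches the analytic Poisson bound", {
  cfg <- test_config()
  rw <- seq(30, 30 + 59 * 12, by = 12)
  g <- 3
  rate_fn <- function(t) {
    r <- rep(5, length(t))
    for (e in rw) r[t >= e - 1.5 & t < e] <- 5 * g
    r
  }
  accs <- sapply(1:8, function(k) {
    st <- generate_spike_train(rate_fn, c(0, 760), 16, seed = 400 + k)
    decode_population(list(st), rw, L = 1.5, subset_sizes = 1,
                      config = cfg, seed = k)$accuracy
  })
  mu_b <- 5 * 1.5
  mu_e <- 15 * 1.5
  thr <- (mu_e - mu_b) / log(mu_e / mu_b)   # Poisson LRT threshold
  bound <- 0.5 * (ppois(thr, mu_b) + 1 - ppois(thr, mu_e))
  expect_lt(abs(mean(accs) - bound), 0.05)
})

test_that("residualization removes speed-driven decodability", {
  # one cell whose entire reward-locked structure comes from deceleration
  cfg <- test_config()
  gs <- generate_session(synth_config(
    n_laps = 15, seed = 301,
    units = tibble::tibble(
      unit_id = "u1", class = "SOMI", subtype = NA_character_,
      baseline_rate_hz = 2, reward_profile = "none", peak_gain = 1,
      peak_time_s = 0, width_s = 0.5, boxcar_lo = NA_real_, boxcar_hi = NA_real_,
      locomotion = "NON", speed_slope = 0.4, burst_prob = 0, ttp_ms = 0.55,
      place_center_cm = NA_real_, place_width_cm = NA_real_, place_gain = 0,
      ds_amplitude = 1, spatial_info_target = NA_real_,
      is_chr2 = FALSE, chr2_latency_ms = NA_real_, is_inhibited = FALSE,
      is_disinhibited = FALSE, projects_to_fimbria = FALSE,
      sensory_kinds = list(character(0))),
    synapses = tibble::tibble(pre = character(0), post = character(0),
                              efficacy = numeric(0), latency_ms = numeric(0),
                              jitter_ms = numeric(0)),
    light = NULL, sensory = NULL))
  s <- gs$session
  rw <- s$events$time[s$events$kind == "reward"]
  st <- s$units$spike_times[[1]]
  raw <- decode_population(list(st), rw, L = 1.5, subset_sizes = 1,
                           config = cfg, seed = 5)
  coefs <- list(u1 = glm_coefficients(build_design(s, "u1", config = cfg)))
  resid <- residualized_decode(s, "u1", coefs, L = 1.5, config = cfg)
  expect_gt(raw$accuracy, 0.65)
  expect_lt(resid$accuracy, raw$accuracy - 0.1)

  # zero coefficients leave the decoding essentially unchanged
  zero <- list(u1 = c(lick = 0, speed = 0, accel = 0, reward = 0))
  resid0 <- residualized_decode(s, "u1", zero, L = 1.5, config = cfg)
  expect_lt(abs(resid0$accuracy - raw$accuracy), 0.12)
})
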