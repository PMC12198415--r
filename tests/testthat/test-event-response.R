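test_that("event alignment equals a brute-force histogram oracle", {
  events <- c(20, 40, 60)
  st <- sort(events + 0.001)
  a <- align_events(st, events)
  zero_bin <- which(a$edges[-1] > 0 & a$edges[-length(a$edges)] <= 0)
  expect_true(all(a$counts[, zero_bin] == 1))
  expect_equal(sum(a$counts), 3)

  st2 <- poisson_train(6, 100, 41)
  ev2 <- c(15, 30, 52, 71, 88)
  a2 <- align_events(st2, ev2)
  expect_equal(unname(a2$counts), oracle_align(st2, ev2, c(-5, 5), 0.1),
               ignore_attr = TRUE)

  # events whose window exceeds the recording are dropped and reported
  a3 <- align_events(st2, c(2, 50), t_range = c(0, 100))
  expect_equal(a3$dropped, 2)
  expect_error(align_events(st2, numeric(0)), "no events")
})

test_that("flat Poisson activity yields a flat mean PSTH", {
  st <- poisson_train(10, 2000, 43)
  ev <- seq(20, 1980, by = 20)
  a <- align_events(st, ev)
  m <- colMeans(a$counts)   # expected 1 spike per 0.1 s bin
  se <- sqrt(1 / length(ev))
  expect_gt(mean(abs(m - 1) <= 3 * se), 0.95)
})

test_that("z-scoring normalizes the full matrix", {
  a <- align_events(poisson_train(6, 200, 44), c(50, 100, 150))
  z <- zscore_aligned(a)
  expect_equal(mean(z$counts), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(z$counts)), 1, tolerance = 1e-9)
})

test_that("reward modulation recovers predictive and consumption profiles", {
  gs <- small_fixture()
  s <- gs$session
  rw <- s$events$time[s$events$kind == "reward"]
  somi <- gs$truth$units$unit_id[gs$truth$units$class == "SOMI"]
  for (uid in somi) {
    st <- s$units$spike_times[[match(uid, s$units$unit_id)]]
    expect_equal(reward_modulation(st, rw)$classification, "anticipatory",
                 info = uid)
  }
  expect_error(reward_modulation(poisson_train(5, 100, 1), c(10, 20)),
               "at least 10")
})

test_that("null cells trigger each zone test at about the nominal alpha", {
  set.seed(51)
  n_sim <- 300
  rw <- seq(20, 20 + 29 * 15, by = 15)
  hits_pre <- hits_post <- 0
  for (i in seq_len(n_sim)) {
    st <- poisson_train(5, 500, seed = 7000 + i)
    r <- reward_modulation(st, rw)
    hits_pre <- hits_pre + (r$pre_direction != "none")
    hits_post <- hits_post + (r$post_direction != "none")
  }
  expect_lt(abs(hits_pre / n_sim - 0.05), 0.035)
  expect_lt(abs(hits_post / n_sim - 0.05), 0.035)
})

test_that("delay to maximal change recovers bump peaks within one bin", {
  mk_aligned <- function(peak_s, n_trials = 30, gain = 3, seed = 1) {
    ev <- seq(30, 30 + (n_trials - 1) * 20, by = 20)
    rate_fn <- function(t) {
      r <- rep(5, length(t))
      for (e in ev) r <- r + 5 * (gain - 1) * exp(-(t - e - peak_s)^2 / (2 * 0.3^2))
      r
    }
    st <- generate_spike_train(rate_fn, c(0, max(ev) + 10), 5 * gain + 1, seed)
    align_events(st, ev)
  }
  expect_lt(abs(delay_to_max_change(mk_aligned(-0.1, seed = 61)) - (-0.1)), 0.11)
  expect_lt(abs(delay_to_max_change(mk_aligned(1.2, seed = 62)) - 1.2), 0.11)

  # symmetric equal bumps tie-break to the earliest bin
  centers <- seq(-4.95, 4.95, by = 0.1)
  prof <- exp(-(centers - 1)^2 / 0.3) + exp(-(centers + 1)^2 / 0.3)
  prof <- (prof + rev(prof)) / 2    # exactly symmetric in floating point
  a <- align_events(0.5, 10, window = c(-5, 5))   # shell object
  a$counts <- matrix(rep(prof, 5), nrow = 5, byrow = TRUE)
  expect_lt(delay_to_max_change(a), 0)

  flat <- a
  flat$counts <- matrix(1, nrow = 5, ncol = 100)
  expect_error(delay_to_max_change(flat), "no modulation")
})

test_that("locomotion ON/OFF classification matches generator labels", {
  gs <- small_fixture()
  s <- gs$session
  trans <- segment_motion(s$behavior)$transitions
  truth <- gs$truth$units
  somi <- truth[truth$class == "SOMI", ]
  labs <- purrr::map_chr(somi$unit_id, function(uid)
    onoff_classify(s$units$spike_times[[match(uid, s$units$unit_id)]],
                   trans)$label)
  expect_gte(mean(labs == somi$locomotion), 0.75)
  few <- onoff_classify(poisson_train(5, 100, 1),
                        tibble::tibble(time = c(10, 20), kind = c("onset", "offset")))
  expect_true(few$flagged)
  expect_equal(few$label, "NON")
})

test_that("speed regression is exact on linear data and matches the OLS oracle", {
  block <- rep(c(10, 20), times = 150)   # speed per 1 s block
  beh <- tibble::tibble(time = seq(0, 299.5, 0.5), position = 0,
                        speed = rep(block, each = 2))
  # rate = 2 + 0.5 * speed spikes/s, realized exactly with 1 s bins
  st <- sort(unlist(lapply(seq_along(block), function(i) {
    (i - 1) + seq(0, 0.999, length.out = 2 + 0.5 * block[i])
  })))
  r <- speed_regression(st, beh, bin = 1)
  expect_equal(r$slope, 0.5, tolerance = 1e-9)
  expect_equal(r$r, 1, tolerance = 1e-9)

  set.seed(9)
  beh2 <- tibble::tibble(time = seq(0, 199.9, 0.1), position = 0,
                         speed = pmax(0, 10 + cumsum(rnorm(2000, 0, 0.2))))
  st2 <- poisson_train(8, 200, 71)
  r2 <- speed_regression(st2, beh2)
  rate <- somipipe:::bin_counts(st2, seq(0, 199.9, 0.1))[1:1999] / 0.1
  sp <- approx(beh2$time, beh2$speed, xout = seq(0.05, 199.85, 0.1))$y[1:1999]
  ob <- oracle_ols(sp, rate)
  expect_equal(r2$slope, unname(ob[2]), tolerance = 1e-8)

  const <- tibble::tibble(time = seq(0, 99.9, 0.1), position = 0, speed = 5)
  rc <- speed_regression(st2, const)
  expect_true(rc$constant)
  expect_equal(rc$r, 0)
})

test_that("sensory responses are detected per kind and skipped when sparse", {
  gs <- small_fixture()
  s <- gs$session
  somi1 <- s$units$spike_times[[match("somi01", s$units$unit_id)]]
  sr <- sensory_response(somi1, s$events)
  expect_equal(sr$direction[sr$kind == "random_reward"], "increase")
  expect_equal(sr$direction[sr$kind == "stim_airpuff"], "increase")
  expect_true(all(sr$skipped[sr$kind %in% c("stim_visual", "stim_sound")]))

  silent <- sensory_response(numeric(0), s$events)
  expect_true(all(silent$direction[!silent$skipped] == "none"))
})

test_that("lap-activity correlation contrasts stable and remapped epochs", {
  centers <- seq(-4.95, 4.95, 0.1)
  p1 <- 5 + 4 * exp(-(centers + 0.1)^2 / 0.5)
  p2 <- 5 + 4 * exp(-(centers - 1.5)^2 / 0.5)
  ident <- align_events(0.5, 10, window = c(-5, 5))
  ident$counts <- matrix(rep(p1, 10), nrow = 10, byrow = TRUE)
  r_same <- lap_activity_correlation(ident, 1:5, 6:10)
  expect_equal(r_same$mean_r, 1, tolerance = 1e-9)

  set.seed(15)
  remap <- ident
  remap$counts <- rbind(
    t(replicate(5, p1 + rnorm(100, 0, 0.5))),
    t(replicate(5, p2 + rnorm(100, 0, 0.5))))
  r_within <- lap_activity_correlation(remap, 1:3, 4:5)
  r_across <- lap_activity_correlation(remap, 1:5, 6:10)
  expect_gt(r_within$mean_r, r_across$mean_r)

  # independent noise laps: mean correlation near zero
  noise <- ident
  rs <- replicate(60, {
    noise$counts <- matrix(rnorm(1000), nrow = 10)
    lap_activity_correlation(noise, 1:5, 6:10)$mean_r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(60) + 0.02)

  allconst <- ident
  allconst$counts <- matrix(1, nrow = 10, ncol = 100)
  expect_true(is.nan(lap_activity_correlation(allconst, 1:5, 6:10)$mean_r))
})
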