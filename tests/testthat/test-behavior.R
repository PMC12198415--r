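make_trace <- function(speed, dt = 0.1) {
  tibble::tibble(time = (seq_along(speed) - 1) * dt,
                 position = rep(0, length(speed)), speed = speed)
}

test_that("degenerate traces segment without transitions", {
  m0 <- segment_motion(make_trace(rep(0, 100)))
  expect_equal(nrow(m0$segments), 1)
  expect_equal(m0$segments$state, "immobile")
  expect_equal(nrow(m0$transitions), 0)

  m10 <- segment_motion(make_trace(rep(10, 100)))
  expect_equal(m10$segments$state, "locomotion")
  expect_equal(nrow(m10$transitions), 0)

  expect_error(segment_motion(tibble::tibble(time = c(0, 0.1, 0.5),
                                             speed = c(0, 0, 0))),
               "not uniformly sampled")
})

test_that("a qualifying ramp yields one onset at the first sample above 0.5 cm/s", {
  speed <- c(rep(0, 40), seq(0.5, 5, length.out = 10), rep(5, 20))
  m <- segment_motion(make_trace(speed))
  ons <- m$transitions[m$transitions$kind == "onset", ]
  expect_equal(nrow(ons), 1)
  expect_equal(ons$time, 4.0)  # first sample at 0.5 cm/s
})

test_that("transition detection matches the exhaustive per-sample oracle", {
  cfg <- pipeline_config()
  for (k in 1:12) {
    set.seed(300 + k)
    # random piecewise trace alternating rest and running bouts
    pieces <- unlist(lapply(1:8, function(i) {
      if (i %% 2 == 1) rep(0, sample(20:50, 1))
      else c(seq(0, sample(4:20, 1), length.out = sample(3:40, 1)),
             rep(sample(4:20, 1), sample(10:40, 1)),
             seq(20, 0, length.out = sample(3:40, 1)))
    }))
    tr <- make_trace(pmax(pieces + rnorm(length(pieces), 0, 0.05), 0))
    got <- segment_motion(tr, cfg)
    want <- oracle_transitions(tr$time, tr$speed)
    expect_equal(got$transitions$time[got$transitions$kind == "onset"],
                 want$onsets, info = paste("trace", k))
    expect_equal(got$transitions$time[got$transitions$kind == "offset"],
                 want$offsets, info = paste("trace", k))
  }
})

test_that("zone rates count licks and average speed in reward-anchored windows", {
  beh <- make_trace(rep(10, 400), dt = 0.1)
  rw <- c(20, 30)
  licks_post <- c(rw[1] + 0.5, rw[1] + 1.5, rw[2] + 1)
  zr <- zone_rates(licks_post, beh, rw)
  expect_equal(zr$lick_baseline, c(0, 0))
  expect_equal(zr$lick_pre, c(0, 0))
  expect_equal(zr$lick_post, c(1, 0.5))
  expect_equal(zr$speed_pre, c(10, 10))

  licks_2hz <- seq(0.25, 40, by = 0.5)
  zr2 <- zone_rates(licks_2hz, beh, rw)
  expect_true(all(abs(as.matrix(zr2[, c("lick_baseline", "lick_pre",
                                        "lick_post")]) - 2) < 1e-9))
  # window clipped at the recording start is flagged
  zr3 <- zone_rates(licks_2hz, beh, c(3, 20))
  expect_true(zr3$clipped[1])
  expect_false(zr3$clipped[2])
})

test_that("expert calls require both the lick increase and the deceleration", {
  set.seed(42)
  n <- 30
  base <- tibble::tibble(
    trial = 1:n,
    lick_baseline = rpois(n, 1) / 2, lick_pre = rpois(n, 8) / 2,
    lick_post = rpois(n, 12) / 2,
    speed_baseline = rnorm(n, 25, 1), speed_pre = rnorm(n, 12, 1),
    speed_post = rnorm(n, 5, 1), clipped = FALSE)
  expect_equal(classify_performance(base)$performance, "expert")

  flat_speed <- base
  flat_speed$speed_pre <- rnorm(n, 25, 1)
  expect_equal(classify_performance(flat_speed)$performance, "nonexpert")

  flat_all <- base
  flat_all$lick_pre <- rpois(n, 1) / 2
  flat_all$speed_pre <- rnorm(n, 25, 1)
  expect_equal(classify_performance(flat_all)$performance, "nonexpert")

  expect_error(classify_performance(base[1:5, ]), "at least 10")
})

test_that("expert verdict false-positive rate on null sessions stays below 7.5%", {
  set.seed(99)
  n_sim <- 500
  hits <- 0
  for (i in seq_len(n_sim)) {
    n <- 30
    zr <- tibble::tibble(
      trial = 1:n,
      lick_baseline = rpois(n, 2) / 2, lick_pre = rpois(n, 2) / 2,
      lick_post = rpois(n, 2) / 2,
      speed_baseline = rnorm(n, 20, 3), speed_pre = rnorm(n, 20, 3),
      speed_post = rnorm(n, 20, 3), clipped = FALSE)
    if (classify_performance(zr)$performance == "expert") hits <- hits + 1
  }
  expect_lte(hits / n_sim, 0.075)
})

test_that("performance score counts anticipatory laps (binomial law)", {
  zr <- tibble::tibble(lick_pre = c(2, 3, 4), lick_baseline = c(1, 1, 1))
  expect_equal(performance_score(zr), 1)
  zr$lick_pre <- c(0.5, 1, 0.5)
  expect_equal(performance_score(zr), 0)

  # generator with per-lap anticipation probability 0.75: the expected score
  # follows from the Poisson lick law, computed here by enumeration
  p_antic <- 0.75
  gb <- generate_behavior(synth_config(n_laps = 100, seed = 17,
                                       reward_positions_cm = 200,
                                       anticipation_prob = p_antic))
  zr <- zone_rates(gb$events$time[gb$events$kind == "lick"], gb$behavior,
                   gb$reward_times)
  k <- 0:60
  p_gt <- function(mu_a, mu_b) {   # P(A > B), A~Pois(mu_a), B~Pois(mu_b)
    sum(outer(dpois(k, mu_a), dpois(k, mu_b)) * outer(k, k, ">"))
  }
  p1 <- p_gt(4 * 2, 0.5 * 2)       # boosted lap
  p0 <- p_gt(0.5 * 2, 0.5 * 2)     # flat lap
  expected <- p_antic * p1 + (1 - p_antic) * p0
  sigma <- sqrt(p_antic * p1 * (1 - p1) + (1 - p_antic) * p0 * (1 - p0)) / 10
  expect_true(abs(performance_score(zr) - expected) < 3 * sigma + 0.02)
})

test_that("lick-lap trend matches the normal-equation oracle", {
  r <- lick_lap_trend(1:20)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p, 0.001)

  rc <- lick_lap_trend(rep(2, 10))
  expect_true(rc$constant)
  expect_equal(rc$r, 0)

  set.seed(7)
  y <- seq(10, 2, length.out = 40) + rnorm(40, 0, 0.5)
  rt <- lick_lap_trend(y)
  ob <- oracle_ols(1:40, y)
  expect_lt(rt$slope, 0)
  expect_equal(rt$slope, unname(ob[2]), tolerance = 1e-10)
  expect_equal(rt$intercept, unname(ob[1]), tolerance = 1e-10)

  expect_error(lick_lap_trend(1:4), "at least 5")
})
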