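test_that("cross-correlogram bins post-minus-pre lags exactly", {
  ccg <- cross_correlogram(1.000, 1.002)
  expect_equal(sum(ccg$count), 1)
  hit <- ccg$lag_ms[ccg$count == 1]
  expect_true(hit > 1.5 && hit <= 2.25)   # bin containing +2 ms

  for (seed in c(11, 12)) {
    pre <- poisson_train(5, 100, seed)
    post <- poisson_train(5, 100, seed + 50)
    ccg2 <- cross_correlogram(pre, post)
    expect_identical(ccg2$count, oracle_ccg(pre, post))
  }
  flagged <- cross_correlogram(numeric(0), c(1, 2))
  expect_true(attr(flagged, "flagged"))
})

test_that("independent Poisson trains give a flat CCG at the expected level", {
  pre <- poisson_train(5, 600, 21)
  post <- poisson_train(5, 600, 22)
  ccg <- cross_correlogram(pre, post)
  expected <- length(pre) * 5 * 0.0005
  dev <- abs(ccg$count - expected) / sqrt(expected)
  expect_gt(mean(dev <= 3), 0.98)
})

test_that("hollow-Gaussian baseline has unit mass and the documented center weight", {
  flat <- structure(tibble::tibble(lag_ms = seq(-49.75, 49.75, 0.5),
                                   count = rep(7, 200)), flagged = FALSE)
  lam <- hollow_baseline(flat)
  expect_true(all(abs(lam - 7) < 1e-9))

  delta <- flat
  delta$count <- rep(0, 200)
  center_bin <- 100   # lag -0.25 side of zero; use an explicit center bin
  delta$count[center_bin] <- 1000
  lam_d <- hollow_baseline(delta)
  g <- dnorm(seq(-199, 199) * 0.5, sd = 10)
  g[200] <- g[200] * 0.4
  k_center <- g[200] / sum(g)
  expect_equal(lam_d[center_bin], 1000 * k_center, tolerance = 1e-3)

  # hollow fraction 0 reduces to plain Gaussian smoothing
  lam_g <- hollow_baseline(delta, hollow_fraction = 0)
  g2 <- dnorm(seq(-199, 199) * 0.5, sd = 10)
  expect_equal(lam_g[center_bin], 1000 * g2[200] / sum(g2), tolerance = 1e-3)
  expect_error(hollow_baseline(flat, sigma_ms = 0), "positive")
})

test_that("baseline is linear and shift-equivariant away from edges", {
  base <- tibble::tibble(lag_ms = seq(-49.75, 49.75, 0.5), count = rep(0, 200))
  a <- base; a$count[90] <- 50
  b <- base; b$count[110] <- 30
  ab <- base; ab$count[c(90, 110)] <- c(50, 30)
  expect_equal(hollow_baseline(ab), hollow_baseline(a) + hollow_baseline(b),
               tolerance = 1e-9)
  # shift equivariance holds up to the edge renormalization (sub-percent
  # effect more than 2.5 kernel SDs from the window edge)
  shifted <- base; shifted$count[95] <- 50
  expect_equal(hollow_baseline(shifted)[80:120],
               hollow_baseline(a)[75:115], tolerance = 2e-3)
})

test_that("a synthetic synapse is detected with its latency; reversals are not", {
  pre <- poisson_train(5, 600, 31)[1:3000]
  post0 <- poisson_train(5, 600, 32)
  post <- inject_synapse(pre, post0, efficacy = 0.3, latency_ms = 2,
                         jitter_ms = 0.2, seed = 33)
  ccg <- cross_correlogram(pre, post)
  v <- detect_connection(ccg, hollow_baseline(ccg))
  expect_true(v$connected)
  expect_true(v$latency_ms >= 1.5 && v$latency_ms <= 2.5)

  # mirrored synapse: peak sits at negative lags, rejected by the causal rule
  ccg_rev <- cross_correlogram(post, pre)
  v_rev <- detect_connection(ccg_rev, hollow_baseline(ccg_rev))
  expect_false(v_rev$connected)

  # independent trains are not connected
  ccg0 <- cross_correlogram(pre, post0)
  expect_false(detect_connection(ccg0, hollow_baseline(ccg0))$connected)
})

test_that("pair screening on the fixture finds exactly the injected synapses", {
  gs <- small_fixture()
  feats <- classify_units(gs$session)
  pre_ids <- feats$unit_id[feats$class == "PC"]
  post_ids <- gs$truth$units$unit_id[gs$truth$units$class == "SOMI"]
  pairs <- tidyr::expand_grid(pre = pre_ids, post = post_ids)
  res <- detect_connections(gs$session, pairs)
  found <- res[res$connected, c("pre", "post")]
  truth <- gs$truth$synapses[, c("pre", "post")]
  expect_equal(dplyr::arrange(found, pre), dplyr::arrange(truth, pre),
               ignore_attr = TRUE)
  lat <- res$latency_ms[res$connected]
  expect_true(all(abs(lat - 2) <= 0.5))
})
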