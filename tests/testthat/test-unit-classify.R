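test_that("autocorrelogram counts lag pairs exactly (brute-force oracle)", {
  ac <- autocorrelogram(c(1.000, 1.004))
  expect_equal(sum(ac$count), 1)
  expect_equal(sum(ac$count[ac$lag_ms > 3 & ac$lag_ms < 5]), 1)

  for (seed in c(4, 5)) {
    st <- poisson_train(8, 60, seed)   # a few hundred spikes
    ac2 <- autocorrelogram(st)
    expect_identical(ac2$count, oracle_autocorr(st))
  }
  ac_flag <- autocorrelogram(1.5)
  expect_true(attr(ac_flag, "flagged"))
  expect_equal(sum(ac_flag$count), 0)
})

test_that("a stationary Poisson train has a flat autocorrelogram", {
  st <- poisson_train(10, 600, seed = 31)
  ac <- autocorrelogram(st)
  expected <- length(st) * 10 * 0.001
  dev <- abs(ac$count - expected) / sqrt(expected)
  expect_gt(mean(dev <= 3), 0.98)
  expect_lt(abs(mean(ac$count) - expected), 3 * sqrt(expected / nrow(ac)))
})

test_that("bursting index separates doublet from Poisson firing", {
  st <- poisson_train(10, 600, seed = 31)
  bi_p <- bursting_index(autocorrelogram(st))
  expect_lt(abs(bi_p$value - 1), 0.3)

  # Poisson firing with a doublet 4 ms after every spike
  base <- poisson_train(1, 600, seed = 32)
  doublets <- sort(c(base, base + 0.004))
  bi_d <- bursting_index(autocorrelogram(doublets))
  expect_gt(bi_d$value, 3)
  # brute-force check of the same ratio
  oc <- oracle_autocorr(doublets)
  lag <- seq_len(300) - 0.5
  expect_equal(bi_d$value,
               mean(oc[lag > 3 & lag < 5]) / mean(oc[lag > 200 & lag < 300]))

  ac_s <- autocorrelogram(c(0, 0.25, 0.5))  # no 3-5 ms pairs
  expect_equal(bursting_index(ac_s)$value, 0)
  ac_none <- autocorrelogram(c(0, 0.001))   # nothing at long lags
  expect_true(bursting_index(ac_none)$flagged)
})

test_that("trough-to-peak reads 0.5 ms from a constructed biphasic wave", {
  fs <- 30000
  w <- rep(0, 80)
  w[30] <- -10
  w[45] <- 5
  expect_equal(trough_to_peak(w, fs)$ttp_ms, 0.5)

  # resampling x2 leaves the value unchanged
  w2 <- rep(0, 160)
  w2[59] <- -10
  w2[89] <- 5
  expect_equal(trough_to_peak(w2, fs * 2)$ttp_ms, 0.5)

  expect_error(trough_to_peak(-w, fs), "no trough")        # inverted wave
  expect_error(trough_to_peak(seq(1, 0, length.out = 10) * -1, fs), "no trough")
})

test_that("unit classification partitions the feature plane with strict thresholds", {
  expect_equal(classify_unit(3.5, 0.50), "PC")
  expect_equal(classify_unit(1.0, 0.30), "FSI")
  expect_equal(classify_unit(2.0, 0.60), "WI")
  expect_equal(classify_unit(5.0, 0.30), "unclassified")
  expect_equal(classify_unit(3, 0.6), "unclassified")      # boundary BI
  expect_equal(classify_unit(1, 0.45), "unclassified")     # boundary TTP
  expect_equal(classify_unit(NA, 0.5), "unclassified")
  set.seed(12)
  for (i in 1:50) {
    lab <- classify_unit(runif(1, 0, 8), runif(1, 0.1, 0.9))
    expect_true(lab %in% c("PC", "FSI", "WI", "unclassified"))
  }
})

test_that("Skaggs information matches closed forms and a direct-sum oracle", {
  expect_equal(spatial_information(rep(4, 32), rep(1, 32)), 0)
  one_hot <- c(rep(0, 31), 7)
  expect_equal(spatial_information(one_hot, rep(1, 32)), 5)  # log2(32)

  set.seed(3)
  rate <- runif(40, 0, 10)
  occ <- runif(40, 0.5, 2)
  p <- occ / sum(occ)
  lbar <- sum(p * rate)
  direct <- sum(ifelse(rate > 0, p * (rate / lbar) * log2(rate / lbar), 0))
  expect_equal(spatial_information(rate, occ), direct, tolerance = 1e-12)

  flagged <- spatial_information(rep(0, 10), rep(1, 10))
  expect_true(is.nan(flagged))
})

test_that("GC/MC clustering recovers separated feature blobs and labels by SI", {
  set.seed(8)
  n <- 12
  blob <- function(mu, sd = 0.1) rnorm(n, mu, sd)
  feats <- tibble::tibble(
    w_pc1 = c(blob(-2), blob(2)), w_pc2 = c(blob(0), blob(1)),
    ds_amplitude = c(blob(1.5), blob(0.5)),
    spatial_information = c(blob(2), blob(0.3)))
  cl <- cluster_gc_mc(feats, seed = 5)
  expect_equal(cl$labels, rep(c("putative_GC", "putative_MC"), each = n))

  # inverting the SI pattern flips the label assignment
  feats2 <- feats
  feats2$spatial_information <- rev(feats2$spatial_information)
  cl2 <- cluster_gc_mc(feats2, seed = 5)
  expect_equal(cl2$labels, rep(c("putative_MC", "putative_GC"), each = n))

  same <- tibble::tibble(w_pc1 = rep(1, 6), w_pc2 = rep(2, 6),
                         ds_amplitude = rep(1, 6),
                         spatial_information = rep(0.5, 6))
  expect_true(cluster_gc_mc(same)$degenerate)

  no_ds <- feats[setdiff(names(feats), "ds_amplitude")]
  expect_true(cluster_gc_mc(no_ds, seed = 5)$missing_ds)
})

test_that("session-level classification recovers generator classes", {
  gs <- small_fixture()
  feats <- classify_units(gs$session)
  truth <- gs$truth$units
  agree <- feats$class[match(truth$unit_id, feats$unit_id)] == truth$unit_class
  expect_gte(mean(agree), 0.95)
  # granule-like cells carry more spatial information than mossy-like ones
  si <- feats$spatial_information[match(truth$unit_id, feats$unit_id)]
  gc <- !is.na(truth$subtype) & truth$subtype == "gc" &
    truth$unit_id %in% feats$unit_id[feats$class == "PC"]
  mc <- !is.na(truth$subtype) & truth$subtype == "mc"
  expect_gt(mean(si[gc]), mean(si[mc]))
})
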