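#' Spike-train cross-correlogram
#'
#' Counts `post - pre` lag pairs in half-open bins `(lag, lag + bin]` over
#' `(-max_lag, +max_lag]` ms. Equals the brute-force double loop.
#'
#' @param pre_times,post_times Sorted spike times (s).
#' @param bin_ms Bin width (ms), default 0.5.
#' @param max_lag_ms Half-window (ms), default 50.
#' @return Tibble `lag_ms` (bin centers), `count`; attribute `flagged` when
#'   either train is empty.
#' @export
cross_correlogram <- function(pre_times, post_times, bin_ms = 0.5,
                              max_lag_ms = 50) {
  nb <- 2 * ceiling(max_lag_ms / bin_ms)
  edges <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  centers <- edges[-1] - bin_ms / 2
  counts <- integer(nb)
  flagged <- !length(pre_times) || !length(post_times)
  if (!flagged) {
    pre <- pre_times * 1000
    post <- post_times * 1000
    lo <- findInterval(pre - max_lag_ms, post)          # last post <= pre - max
    hi <- findInterval(pre + max_lag_ms, post)          # last post <= pre + max
    nvec <- hi - lo
    pos <- nvec > 0
    if (any(pos)) {
      idx <- sequence(nvec[pos], from = lo[pos] + 1L)
      lags <- post[idx] - rep(pre[pos], nvec[pos])
      lags <- lags[lags > -max_lag_ms & lags <= max_lag_ms]
      bins <- pmax(pmin(ceiling((lags + max_lag_ms) / bin_ms), nb), 1L)
      counts <- tabulate(bins, nbins = nb)
    }
  }
  structure(tibble::tibble(lag_ms = centers, count = counts), flagged = flagged)
}

#' Partially hollow Gaussian baseline of a cross-correlogram
#'
#' Convolves the observed CCG with a Gaussian kernel (default SD 10 ms)
#' whose center weight is scaled by `1 - hollow_fraction` (default 60%
#' hollow) before renormalizing the kernel to sum 1, so the baseline at each
#' lag is dominated by neighboring lags and a fast synaptic peak does not
#' inflate its own expectation. Kernel mass falling outside the lag window
#' is redistributed by renormalizing over the in-window support.
#'
#' @param ccg Output of [cross_correlogram()].
#' @param sigma_ms Kernel SD (ms).
#' @param hollow_fraction Fraction of the center weight removed.
#' @param bin_ms Bin width of the CCG (ms).
#' @return Numeric vector `lambda`, the expected count per bin.
#' @export
hollow_baseline <- function(ccg, sigma_ms = 10, hollow_fraction = 0.6,
                            bin_ms = NULL) {
  if (sigma_ms <= 0) abort("kernel SD must be positive")
  counts <- ccg$count
  n <- length(counts)
  if (is.null(bin_ms)) bin_ms <- diff(ccg$lag_ms[1:2])
  half <- n - 1
  offs <- seq(-half, half)
  k <- dnorm(offs * bin_ms, sd = sigma_ms)
  k[offs == 0] <- k[offs == 0] * (1 - hollow_fraction)
  k <- k / sum(k)
  lambda <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq_len(n)
    w <- k[(j - i) + half + 1]
    lambda[i] <- sum(counts[j] * w) / sum(w)
  }
  lambda
}

#' Detect a putative monosynaptic excitatory connection
#'
#' A bin is significant when its count exceeds the 99.9th percentile of the
#' cumulative Poisson distribution with the hollow-Gaussian baseline as
#' mean. A connection requires (a) at least 2 consecutive significant bins
#' with centers inside the +1.2 to +4 ms causal window and (b) the causal
#' peak count exceeding the same Poisson quantile taken at the largest
#' anti-causal peak (mirror window -4 to -1.2 ms). The latency is the lag of
#' the causal peak.
#'
#' @param ccg Output of [cross_correlogram()].
#' @param lambda Baseline from [hollow_baseline()].
#' @param config A [pipeline_config()].
#' @return List of class `ccg_verdict`: `connected`, `latency_ms`,
#'   `significant_lags`, `causal_peak`, `anticausal_peak`, `p_min`.
#' @export
detect_connection <- function(ccg, lambda, config = pipeline_config()) {
  q <- config$poisson_quantile
  win <- config$causal_window_ms
  lag <- ccg$lag_ms
  counts <- ccg$count
  thresh <- qpois(q, lambda)
  sig <- counts > thresh
  causal <- lag >= win[1] & lag <= win[2]
  anticausal <- lag >= -win[2] & lag <= -win[1]
  sig_c <- sig & causal
  runs <- rle(sig_c[causal])
  two_consec <- any(runs$values & runs$lengths >= 2)
  causal_peak <- max(counts[causal])
  anticausal_peak <- max(counts[anticausal])
  dir_ok <- causal_peak > qpois(q, anticausal_peak)
  connected <- two_consec && dir_ok
  pvals <- ppois(counts - 1, lambda, lower.tail = FALSE)
  list(connected = connected,
       latency_ms = if (connected) lag[causal][which.max(counts[causal])] else NA_real_,
       significant_lags = lag[sig & causal],
       causal_peak = causal_peak, anticausal_peak = anticausal_peak,
       p_min = min(pvals[causal]))
}

#' Screen unit pairs for monosynaptic connections
#'
#' @param session A `somipipe_session`.
#' @param pairs Tibble with `pre`, `post` unit ids.
#' @param config A [pipeline_config()].
#' @return Tibble: pair ids, `connected`, `latency_ms`, peak counts, `p_min`.
#' @export
detect_connections <- function(session, pairs, config = pipeline_config()) {
  st <- stats::setNames(session$units$spike_times, session$units$unit_id)
  purrr::map_dfr(seq_len(nrow(pairs)), function(j) {
    ccg <- cross_correlogram(st[[pairs$pre[j]]], st[[pairs$post[j]]],
                             config$ccg_bin_ms, config$ccg_max_lag_ms)
    lam <- hollow_baseline(ccg, config$ccg_sigma_ms, config$ccg_hollow_fraction)
    v <- detect_connection(ccg, lam, config)
    tibble::tibble(pre = pairs$pre[j], post = pairs$post[j],
                   connected = v$connected, latency_ms = v$latency_ms,
                   causal_peak = v$causal_peak,
                   anticausal_peak = v$anticausal_peak, p_min = v$p_min)
  })
}
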