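#' Spike-train autocorrelogram
#'
#' Counts spike pairs at lags in half-open 1 ms bins `(0, max_lag]`
#' (positive lags only; the autocorrelogram is symmetric by construction and
#' zero-lag self-pairs are excluded).
#'
#' @param spike_times Sorted spike times (s).
#' @param bin_ms Bin width (ms), default 1.
#' @param max_lag_ms Maximum lag (ms), default 300.
#' @return Tibble with `lag_ms` (bin centers) and `count`; attribute
#'   `flagged` is `TRUE` when fewer than 2 spikes were supplied.
#' @export
autocorrelogram <- function(spike_times, bin_ms = 1, max_lag_ms = 300) {
  nb <- ceiling(max_lag_ms / bin_ms)
  edges <- seq(0, nb * bin_ms, by = bin_ms)
  counts <- integer(nb)
  flagged <- length(spike_times) < 2
  if (!flagged) {
    st <- spike_times * 1000      # ms
    max_lag <- nb * bin_ms
    hi <- findInterval(st + max_lag, st)
    nvec <- hi - seq_along(st)
    pos <- nvec > 0
    if (any(pos)) {
      idx <- sequence(nvec[pos], from = which(pos) + 1L)
      lags <- st[idx] - rep(st[pos], nvec[pos])
      lags <- lags[lags > 0 & lags <= max_lag]
      counts <- tabulate(pmin(ceiling(lags / bin_ms), nb), nbins = nb)
    }
  }
  structure(tibble::tibble(lag_ms = edges[-1] - bin_ms / 2, count = counts),
            flagged = flagged)
}

#' Bursting index
#'
#' Ratio of the mean autocorrelogram count in the 3-5 ms bins to the mean
#' count in the 200-300 ms bins. High values indicate burst firing.
#'
#' @param autocorr Output of [autocorrelogram()]; must cover at least 300 ms.
#' @return List with `value` and `flagged` (`TRUE` when the 200-300 ms
#'   denominator is zero, in which case `value` is `NA`).
#' @export
bursting_index <- function(autocorr) {
  if (max(autocorr$lag_ms) < 299) abort("autocorrelogram must cover >= 300 ms")
  lag <- autocorr$lag_ms
  num <- mean(autocorr$count[lag > 3 & lag < 5])
  den <- mean(autocorr$count[lag > 200 & lag < 300])
  if (is.na(den) || den == 0) {
    list(value = NA_real_, flagged = TRUE)
  } else {
    list(value = num / den, flagged = FALSE)
  }
}

#' Trough-to-peak duration of a mean waveform
#'
#' Uses the recording site with the largest peak-to-peak amplitude; the
#' duration runs from the global trough to the subsequent maximum.
#'
#' @param waveform Site x sample matrix (or a numeric vector for one site).
#' @param fs Sample rate (Hz).
#' @return List with `ttp_ms` and `peak_site`.
#' @export
trough_to_peak <- function(waveform, fs) {
  if (is.null(dim(waveform))) waveform <- matrix(waveform, nrow = 1)
  amp <- apply(waveform, 1, function(w) diff(range(w)))
  site <- which.max(amp)
  w <- waveform[site, ]
  tr <- which.min(w)
  if (max(w) >= -min(w)) {
    abort("no trough: dominant deflection is not negative")
  }
  if (tr >= length(w) || tr == 1) {
    abort("no trough: waveform minimum sits at its edge")
  }
  after <- w[(tr + 1):length(w)]
  pk <- which.max(after)
  if (max(after) <= w[tr]) abort("no trough-to-peak structure in waveform")
  list(ttp_ms = pk / fs * 1000, peak_site = site)
}

#' Classify a unit from bursting index and trough-to-peak duration
#'
#' Putative principal cell (PC): bursting index above 3 and trough-to-peak
#' above 0.45 ms. Fast-spiking interneuron (FSI): both below. Wide-spike
#' interneuron (WI): trough-to-peak above 0.45 ms with bursting index below
#' 3. The remaining quadrant, values exactly at a threshold, and flagged
#' bursting indices are "unclassified".
#'
#' @param bi Bursting index.
#' @param ttp_ms Trough-to-peak duration (ms).
#' @param config A [pipeline_config()].
#' @return One of `"PC"`, `"FSI"`, `"WI"`, `"unclassified"`.
#' @export
classify_unit <- function(bi, ttp_ms, config = pipeline_config()) {
  bt <- config$bi_threshold
  tt <- config$ttp_threshold_ms
  if (is.na(bi) || is.na(ttp_ms)) return("unclassified")
  if (bi > bt && ttp_ms > tt) return("PC")
  if (bi < bt && ttp_ms < tt) return("FSI")
  if (bi < bt && ttp_ms > tt) return("WI")
  "unclassified"
}

#' Skaggs spatial information (bits/spike)
#'
#' `sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` with
#' occupancy probabilities `p_i`; zero-rate bins contribute 0.
#'
#' @param rate_map Mean firing rate per position bin (Hz).
#' @param occupancy Occupancy per bin (any scale; normalized internally).
#' @return Bits per spike, or flagged `NaN` when the mean rate is zero.
#' @export
spatial_information <- function(rate_map, occupancy) {
  stopifnot(length(rate_map) == length(occupancy))
  p <- occupancy / sum(occupancy)
  lam_bar <- sum(p * rate_map)
  if (lam_bar <= 0) return(structure(NaN, flagged = TRUE))
  rel <- rate_map / lam_bar
  terms <- ifelse(rate_map > 0, p * rel * log2(rel), 0)
  sum(terms)
}

#' Position-binned rate map and occupancy
#'
#' @param spike_times Spike times (s).
#' @param behavior Behavior tibble (`time`, `position`), uniformly sampled.
#' @param n_bins Number of position bins over the track.
#' @param track_length Track length (cm).
#' @param min_speed Only samples above this speed (cm/s) count, mirroring the
#'   convention that spatial tuning is measured during locomotion; `NULL`
#'   uses all samples.
#' @return Tibble with `bin`, `rate_hz`, `occupancy_s`.
#' @export
spatial_rate_map <- function(spike_times, behavior, n_bins = 40,
                             track_length = 400, min_speed = 3) {
  dt <- diff(behavior$time[1:2])
  keep <- if (is.null(min_speed)) rep(TRUE, nrow(behavior)) else
    behavior$speed > min_speed
  edges <- seq(0, track_length, length.out = n_bins + 1)
  occ <- bin_counts(behavior$position[keep], edges) * dt
  pos_fn <- approxfun(behavior$time, behavior$position, method = "constant",
                      rule = 2)
  st <- spike_times[spike_times >= min(behavior$time) &
                      spike_times <= max(behavior$time)]
  keep_fn <- approxfun(behavior$time, as.numeric(keep), method = "constant",
                       rule = 2)
  st <- st[keep_fn(st) > 0.5]
  cnt <- bin_counts(pos_fn(st), edges)
  tibble::tibble(bin = seq_len(n_bins),
                 rate_hz = ifelse(occ > 0, cnt / occ, 0),
                 occupancy_s = occ)
}

#' Waveform principal-component scores
#'
#' PCA across units of the second derivative (central differences) of each
#' unit's largest-amplitude mean waveform over 0-0.8 ms from the trough.
#'
#' @param waveforms List of site x sample matrices.
#' @param fs Sample rate (Hz), shared.
#' @return Tibble with `w_pc1`, `w_pc2` per unit.
#' @export
waveform_pcs <- function(waveforms, fs) {
  n_keep <- floor(0.8e-3 * fs)
  segs <- purrr::map(waveforms, function(wf) {
    if (is.null(dim(wf))) wf <- matrix(wf, nrow = 1)
    site <- which.max(apply(wf, 1, function(w) diff(range(w))))
    w <- wf[site, ]
    tr <- which.min(w)
    seg <- w[tr:min(length(w), tr + n_keep)]
    if (length(seg) < n_keep + 1) seg <- c(seg, rep(seg[length(seg)], n_keep + 1 - length(seg)))
    d2 <- diff(diff(seg))          # central second difference
    d2
  })
  m <- do.call(rbind, segs)
  if (nrow(m) < 2) {
    return(tibble::tibble(w_pc1 = rep(0, nrow(m)), w_pc2 = rep(0, nrow(m))))
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  tibble::tibble(w_pc1 = pc$x[, 1],
                 w_pc2 = if (k >= 2) pc$x[, 2] else rep(0, nrow(m)))
}

#' Cluster putative principal cells into granule-like and mossy-like groups
#'
#' k = 2 k-means (50 restarts, seeded) on z-scored features `w_pc1`,
#' `w_pc2`, `ds_amplitude`, `spatial_information`. The cluster with higher
#' mean spatial information is labeled `putative_GC` (granule cells carry
#' sparser, more spatially informative firing than mossy cells); when a
#' `mean_rate` column is supplied it breaks ties toward the lower-rate
#' cluster.
#'
#' @param features Tibble with columns `w_pc1`, `w_pc2`, `ds_amplitude`
#'   (optional), `spatial_information`, and optionally `mean_rate`.
#' @param config A [pipeline_config()].
#' @param seed Seed for the k-means restarts.
#' @return List with `labels` (character vector `putative_GC`/`putative_MC`),
#'   `degenerate` flag (single effective cluster), `missing_ds` flag.
#' @export
cluster_gc_mc <- function(features, config = pipeline_config(), seed = 1L) {
  cols <- c("w_pc1", "w_pc2", "ds_amplitude", "spatial_information")
  missing_ds <- !"ds_amplitude" %in% names(features) ||
    all(is.na(features$ds_amplitude))
  use <- if (missing_ds) setdiff(cols, "ds_amplitude") else cols
  if (nrow(features) < 4) abort("at least 4 units required for GC/MC clustering")
  x <- as.matrix(features[use])
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) {
    return(list(labels = rep("putative_GC", nrow(x)), degenerate = TRUE,
                missing_ds = missing_ds))
  }
  x <- scale(x[, sds > 0, drop = FALSE])
  km <- with_seed(seed, kmeans(x, centers = 2, nstart = config$kmeans_restarts))
  si <- tapply(features$spatial_information, km$cluster, mean)
  gc_cluster <- as.integer(names(si)[which.max(si)])
  if ("mean_rate" %in% names(features) && length(unique(round(si, 12))) == 1) {
    mr <- tapply(features$mean_rate, km$cluster, mean)
    gc_cluster <- as.integer(names(mr)[which.min(mr)])
  }
  list(labels = ifelse(km$cluster == gc_cluster, "putative_GC", "putative_MC"),
       degenerate = min(km$size) == 0, missing_ds = missing_ds)
}

#' Compute waveform/burstiness features and classes for all units
#'
#' @param session A `somipipe_session`.
#' @param config A [pipeline_config()].
#' @return Tibble: `unit_id`, `bi`, `ttp_ms`, `class`, `mean_rate`,
#'   `spatial_information`, `w_pc1`, `w_pc2`.
#' @export
classify_units <- function(session, config = pipeline_config()) {
  u <- session$units
  dur <- max(c(unlist(u$spike_times), session$behavior$time, 1))
  feats <- purrr::map_dfr(seq_len(nrow(u)), function(i) {
    ac <- autocorrelogram(u$spike_times[[i]], config$ac_bin_ms, config$ac_max_lag_ms)
    bi <- bursting_index(ac)
    tp <- trough_to_peak(u$waveform[[i]], u$fs[i])
    si <- if (nrow(session$behavior)) {
      rm_ <- spatial_rate_map(u$spike_times[[i]], session$behavior)
      as.numeric(spatial_information(rm_$rate_hz, rm_$occupancy_s))
    } else NA_real_
    cls <- classify_unit(bi$value, tp$ttp_ms, config)
    tibble::tibble(unit_id = u$unit_id[i], bi = bi$value, ttp_ms = tp$ttp_ms,
                   class = cls,
                   mean_rate = length(u$spike_times[[i]]) / dur,
                   spatial_information = si)
  })
  dplyr::bind_cols(feats, waveform_pcs(u$waveform, u$fs[1]))
}
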