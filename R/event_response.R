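#' Event-aligned binned spike counts
#'
#' Bins spikes in half-open 100 ms bins over a window around each event.
#' Events whose window exceeds the recording extent are dropped and flagged.
#'
#' @param spike_times Sorted spike times (s).
#' @param event_times Event onset times (s); onset maps to t = 0.
#' @param window Length-2 window (s), default `c(-5, 5)`.
#' @param bin Bin width (s), default 0.1.
#' @param t_range Recording extent used for the drop rule; defaults to the
#'   spike-train extent padded by the window.
#' @return Object of class `aligned_activity`: fields `counts` (trial x bin
#'   matrix), `edges`, `centers`, `bin`, `events`, `dropped`, `smoothed`,
#'   `zscored`.
#' @export
align_events <- function(spike_times, event_times, window = c(-5, 5),
                         bin = 0.1, t_range = NULL) {
  if (!length(event_times)) abort("no events to align to")
  if (is.null(t_range)) t_range <- c(0, max(c(spike_times, event_times)) + window[2])
  keep <- event_times + window[1] >= t_range[1] &
    event_times + window[2] <= t_range[2]
  dropped <- event_times[!keep]
  event_times <- event_times[keep]
  if (!length(event_times)) abort("all events dropped: windows exceed recording")
  nb <- round(diff(window) / bin)
  edges <- window[1] + bin * (0:nb)
  counts <- t(vapply(event_times, function(ev) {
    bin_counts(spike_times - ev, edges)
  }, numeric(nb)))
  structure(list(counts = counts, edges = edges,
                 centers = edges[-1] - bin / 2, bin = bin,
                 events = event_times, dropped = dropped,
                 smoothed = FALSE, zscored = FALSE),
            class = "aligned_activity")
}

#' Gaussian-smooth aligned activity along time
#'
#' Smoothing (default SD 1 bin) is applied to each trial row separately,
#' never across trials.
#'
#' @param aligned An `aligned_activity`.
#' @param sigma_bins Kernel SD in bins.
#' @return The smoothed `aligned_activity`.
#' @export
smooth_aligned <- function(aligned, sigma_bins = 1) {
  aligned$counts <- t(apply(aligned$counts, 1, gauss_smooth, sigma_bins = sigma_bins))
  aligned$smoothed <- TRUE
  aligned
}

#' Z-score aligned activity
#'
#' Centers and scales with the mean and SD taken over the full trial x bin
#' matrix, removing the between-unit firing-rate bias before averaging.
#'
#' @param aligned An `aligned_activity`.
#' @return The z-scored `aligned_activity` (flat matrices are left centered
#'   at zero with a `flat` attribute).
#' @export
zscore_aligned <- function(aligned) {
  m <- aligned$counts
  s <- sd(as.vector(m))
  if (is.na(s) || s == 0) {
    aligned$counts <- m - mean(m)
    attr(aligned, "flat") <- TRUE
  } else {
    aligned$counts <- (m - mean(m)) / s
  }
  aligned$zscored <- TRUE
  aligned
}

#' @export
print.aligned_activity <- function(x, ...) {
  cat("<aligned_activity> ", nrow(x$counts), " trials x ", ncol(x$counts),
      " bins (", x$bin, " s); smoothed=", x$smoothed,
      ", zscored=", x$zscored, "\n", sep = "")
  invisible(x)
}

#' Reward modulation of a unit
#'
#' Per-trial mean rates in the pre (-2 to 0 s) and post (0 to +2 s) zones
#' are compared with the baseline window (default -6 to -4 s) by paired
#' two-sided Wilcoxon tests (alpha 0.05), computed from raw spike counts.
#' A cell is "anticipatory" when its pre-zone rate is significantly
#' up-modulated, "non-anticipatory" when modulated in any other way, and
#' "unmodulated" otherwise.
#'
#' @param spike_times Sorted spike times (s).
#' @param reward_times Reward onsets (s).
#' @param config A [pipeline_config()].
#' @return Tibble with one row: directions and p values per zone plus
#'   `classification`.
#' @export
reward_modulation <- function(spike_times, reward_times,
                              config = pipeline_config()) {
  if (length(reward_times) < config$min_trials) {
    abort(paste0("only ", length(reward_times), " trials; at least ",
                 config$min_trials, " required"))
  }
  zones <- list(pre = c(-config$pre_zone_s, 0), post = c(0, config$post_zone_s))
  bw <- config$baseline_window_s
  base <- count_in(spike_times, reward_times + bw[1], reward_times + bw[2]) /
    diff(bw)
  res <- purrr::imap(zones, function(w, nm) {
    z <- count_in(spike_times, reward_times + w[1], reward_times + w[2]) /
      diff(w)
    paired_test(z, base, config$alpha)
  })
  classification <- if (res$pre$direction == "increase") "anticipatory"
  else if (res$pre$direction == "decrease" || res$post$direction != "none")
    "non-anticipatory"
  else "unmodulated"
  tibble::tibble(pre_direction = res$pre$direction, pre_p = res$pre$p,
                 post_direction = res$post$direction, post_p = res$post$p,
                 classification = classification)
}

#' Delay from reward onset to the maximal activity change
#'
#' On the smoothed, z-scored, trial-averaged trace, finds the time in the
#' search window (default -2 to +2 s) with the largest absolute deviation
#' from the baseline z level (mean z over the baseline window clipped to the
#' alignment window). Ties resolve to the earliest bin.
#'
#' @param aligned An `aligned_activity` (raw counts are fine; smoothing and
#'   z-scoring are applied internally when missing).
#' @param config A [pipeline_config()].
#' @return Delay in seconds (bin center).
#' @export
delay_to_max_change <- function(aligned, config = pipeline_config()) {
  a <- aligned
  if (!a$smoothed) a <- smooth_aligned(a, config$smooth_sigma_bins)
  if (!a$zscored) a <- zscore_aligned(a)
  z <- colMeans(a$counts)
  if (isTRUE(attr(a, "flat")) || sd(z) == 0) abort("no modulation: flat trace")
  bw <- config$baseline_window_s
  bw[1] <- max(bw[1], a$edges[1])
  zb <- mean(z[a$centers > bw[1] & a$centers < bw[2]])
  sw <- config$delay_search_s
  idx <- which(a$centers >= sw[1] & a$centers <= sw[2])
  dev <- abs(z[idx] - zb)
  a$centers[idx[which.max(dev)]]       # which.max takes the earliest tie
}

#' Classify locomotion ON / OFF / NON units
#'
#' Compares mean rates in the immobile-side window (-3 to -1 s) and the
#' moving-side window (+1 to +3 s) around running onsets and offsets
#' (paired Wilcoxon, alpha 0.05). OFF: rate drops at onsets and rises at
#' offsets; ON: the reverse; NON otherwise. With fewer than 8 onsets or
#' offsets the unit is NON with a flag.
#'
#' @param spike_times Sorted spike times (s).
#' @param transitions Transition tibble from [segment_motion()].
#' @param config A [pipeline_config()].
#' @return Tibble: `label`, per-test p values, `flagged`.
#' @export
onoff_classify <- function(spike_times, transitions,
                           config = pipeline_config()) {
  ons <- transitions$time[transitions$kind == "onset"]
  offs <- transitions$time[transitions$kind == "offset"]
  if (length(ons) < config$min_transitions ||
      length(offs) < config$min_transitions) {
    return(tibble::tibble(label = "NON", p_onset = NA_real_,
                          p_offset = NA_real_, flagged = TRUE))
  }
  rate_in <- function(ev, w) count_in(spike_times, ev + w[1], ev + w[2]) / diff(w)
  wi <- config$onoff_immobile_s
  wm <- config$onoff_moving_s
  on_t <- paired_test(rate_in(ons, wm), rate_in(ons, wi), config$alpha)
  off_t <- paired_test(rate_in(offs, wm), rate_in(offs, wi), config$alpha)
  # at offsets the immobile side is the +1..+3 s window
  label <- if (on_t$direction == "decrease" && off_t$direction == "increase") {
    "OFF"
  } else if (on_t$direction == "increase" && off_t$direction == "decrease") {
    "ON"
  } else "NON"
  tibble::tibble(label = label, p_onset = on_t$p, p_offset = off_t$p,
                 flagged = FALSE)
}

#' Firing-rate versus running-speed regression
#'
#' Bins rate and speed in 100 ms bins on the behavior clock and fits
#' ordinary least squares of rate on speed; the steady-state variant keeps
#' only bins with speed above 3 cm/s.
#'
#' @param spike_times Sorted spike times (s).
#' @param behavior Behavior tibble.
#' @param config A [pipeline_config()].
#' @param steady_state_only Restrict to steady-state locomotion bins.
#' @param bin Bin width (s).
#' @return Tibble: `slope`, `intercept`, `r`, `p`, `n_bins`, `constant` flag.
#' @export
speed_regression <- function(spike_times, behavior,
                             config = pipeline_config(),
                             steady_state_only = FALSE, bin = 0.1) {
  t0 <- min(behavior$time)
  t1 <- max(behavior$time)
  edges <- seq(t0, t1, by = bin)
  if (length(edges) < 2) abort("behavior trace too short")
  rate <- bin_counts(spike_times, edges) / bin
  centers <- edges[-1] - bin / 2
  sp <- approx(behavior$time, behavior$speed, xout = centers, rule = 2)$y
  keep <- rep(TRUE, length(rate))
  if (steady_state_only) keep <- sp > config$locomotion_thresh
  rate <- rate[keep]; sp <- sp[keep]
  if (length(rate) < 100) abort("fewer than 100 usable bins")
  if (sd(sp) == 0) {
    return(tibble::tibble(slope = 0, intercept = mean(rate), r = 0,
                          p = NA_real_, n_bins = length(rate), constant = TRUE))
  }
  fit <- lm(rate ~ sp)
  ct <- suppressWarnings(cor.test(sp, rate))
  tibble::tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value,
                 n_bins = length(rate), constant = FALSE)
}

#' Sensory responses of a unit
#'
#' For each stimulus kind with at least 15 events, compares spike counts
#' during the stimulus epoch with the same-length pre-stimulus interval
#' (paired Wilcoxon, alpha 0.05). Kinds with too few events are skipped
#' with a flag.
#'
#' @param spike_times Sorted spike times (s).
#' @param events Event tibble (`time`, `kind`, `duration`).
#' @param kinds Stimulus kinds to test.
#' @param config A [pipeline_config()].
#' @return Tibble: `kind`, `direction`, `p`, `n_events`, `skipped`.
#' @export
sensory_response <- function(spike_times, events,
                             kinds = c("random_reward", "stim_visual",
                                       "stim_sound", "stim_airpuff"),
                             config = pipeline_config()) {
  purrr::map_dfr(kinds, function(k) {
    ev <- events[events$kind == k, ]
    if (nrow(ev) < config$min_stim) {
      return(tibble::tibble(kind = k, direction = NA_character_, p = NA_real_,
                            n_events = nrow(ev), skipped = TRUE))
    }
    during <- count_in(spike_times, ev$time, ev$time + ev$duration)
    pre <- count_in(spike_times, ev$time - ev$duration, ev$time)
    tst <- paired_test(during, pre, config$alpha)
    tibble::tibble(kind = k, direction = tst$direction, p = tst$p,
                   n_events = nrow(ev), skipped = FALSE)
  })
}

#' Mean lap-pair activity correlation between two lap groups
#'
#' Pearson correlation of smoothed per-lap binned-rate vectors for every
#' pair of laps across groups A and B; returns the mean over pairs.
#' Constant lap vectors are excluded with a flag.
#'
#' @param aligned An `aligned_activity` whose trials are laps.
#' @param group_a,group_b Trial (row) indices of the two groups.
#' @param config A [pipeline_config()].
#' @return List: `mean_r`, `n_pairs`, `n_excluded`, `flagged`.
#' @export
lap_activity_correlation <- function(aligned, group_a, group_b,
                                     config = pipeline_config()) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("at least 2 laps per group required")
  }
  a <- if (aligned$smoothed) aligned else
    smooth_aligned(aligned, config$smooth_sigma_bins)
  if (ncol(a$counts) < 10) abort("lap vectors need at least 10 bins")
  ok <- apply(a$counts, 1, sd) > 0
  ga <- intersect(group_a, which(ok))
  gb <- intersect(group_b, which(ok))
  n_excl <- (length(group_a) - length(ga)) + (length(group_b) - length(gb))
  if (!length(ga) || !length(gb)) {
    return(list(mean_r = NaN, n_pairs = 0, n_excluded = n_excl, flagged = TRUE))
  }
  rs <- as.vector(stats::cor(t(a$counts[ga, , drop = FALSE]),
                             t(a$counts[gb, , drop = FALSE])))
  list(mean_r = mean(rs), n_pairs = length(rs), n_excluded = n_excl,
       flagged = n_excl > 0)
}
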