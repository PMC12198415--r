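#' Segment a speed trace into motion states and detect running transitions
#'
#' Samples with speed below 0.5 cm/s are immobile, above 3 cm/s steady-state
#' locomotion, and in between intermediate (the two published thresholds
#' leave a gap). A running onset requires at least 3 s of immobility followed
#' by the speed reaching 3 cm/s within 3 s of leaving immobility; the onset
#' time is the first sample at or above 0.5 cm/s of the qualifying ramp. The
#' offset criterion is symmetric: a drop from above 3 cm/s to below 0.5 cm/s
#' within 3 s, followed by at least 3 s of immobility; the offset time is the
#' first sample below 3 cm/s of the qualifying ramp.
#'
#' @param behavior Tibble with uniformly sampled `time` and `speed` columns.
#' @param config A [pipeline_config()].
#' @return List with `segments` (tibble: start, end, state) and `transitions`
#'   (tibble: time, kind in onset/offset).
#' @export
segment_motion <- function(behavior, config = pipeline_config()) {
  t <- behavior$time
  sp <- behavior$speed
  if (length(t) > 1) {
    dt <- diff(t)
    if ((max(dt) - min(dt)) > 1e-6) abort("speed trace is not uniformly sampled")
    dt <- dt[1]
  } else dt <- NA_real_
  lo <- config$immobility_thresh
  hi <- config$locomotion_thresh
  state <- ifelse(sp < lo, "immobile", ifelse(sp > hi, "locomotion", "intermediate"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  segments <- tibble::tibble(start = t[starts],
                             end = t[ends] + ifelse(is.na(dt), 0, dt),
                             state = r$values)

  transitions <- tibble::tibble(time = numeric(0), kind = character(0))
  n <- length(sp)
  if (n >= 2) {
    min_imm <- ceiling(config$min_immobility_s / dt)
    max_tr <- floor(config$max_transition_s / dt)
    ons <- offs <- numeric(0)
    for (k in seq_along(r$values)) {
      if (r$values[k] == "immobile" && r$lengths[k] >= min_imm && k < length(r$values)) {
        i <- ends[k] + 1          # first sample >= lo
        lim <- min(n, ends[k] + max_tr)
        reach <- which(sp[i:lim] >= hi)
        stillimm <- which(sp[i:lim] < lo)
        reach_ok <- length(reach) &&
          (!length(stillimm) || min(reach) < min(stillimm))
        if (reach_ok) ons <- c(ons, t[i])
      }
      if (r$values[k] == "locomotion" && k < length(r$values)) {
        i <- ends[k] + 1          # first sample <= hi
        lim <- min(n, ends[k] + max_tr)
        dropidx <- which(sp[i:lim] < lo)
        backup <- which(sp[i:lim] > hi)
        drop_ok <- length(dropidx) &&
          (!length(backup) || min(dropidx) < min(backup))
        if (drop_ok) {
          j <- ends[k] + min(dropidx)   # first immobile sample
          rem <- sp[j:min(n, j + min_imm - 1)]
          if (length(rem) >= min_imm && all(rem < lo)) offs <- c(offs, t[i])
        }
      }
    }
    transitions <- dplyr::bind_rows(
      tibble::tibble(time = ons, kind = "onset"),
      tibble::tibble(time = offs, kind = "offset")) |>
      dplyr::arrange(.data$time)
  }
  list(segments = segments, transitions = transitions)
}

#' Per-trial lick rates and mean speeds in reward-anchored zones
#'
#' For each reward delivery, computes the lick rate (count / window length)
#' and mean running speed in the baseline (default -6 to -4 s), pre (-2 to
#' 0 s) and post (0 to +2 s) windows. Windows reaching before the start of
#' the recording (or of the reward's lap) are clipped and flagged.
#'
#' @param licks Numeric lick times (s).
#' @param behavior Behavior tibble (`time`, `speed`).
#' @param reward_times Reward onset times (s).
#' @param laps Optional lap tibble used for clipping; `NULL` skips it.
#' @param config A [pipeline_config()].
#' @return Tibble, one row per reward: `trial`, `lick_baseline`, `lick_pre`,
#'   `lick_post` (Hz), `speed_baseline`, `speed_pre`, `speed_post` (cm/s),
#'   `clipped` (logical).
#' @export
zone_rates <- function(licks, behavior, reward_times, laps = NULL,
                       config = pipeline_config()) {
  if (!length(reward_times)) abort("at least one reward event required")
  bw <- config$baseline_window_s
  wins <- list(baseline = bw, pre = c(-config$pre_zone_s, 0),
               post = c(0, config$post_zone_s))
  t0 <- if (nrow(behavior)) min(behavior$time) else 0
  purrr::map_dfr(seq_along(reward_times), function(i) {
    tr <- reward_times[i]
    floor_t <- t0
    clipped <- tr + bw[1] < floor_t
    row <- list(trial = i)
    for (nm in names(wins)) {
      w <- tr + wins[[nm]]
      w[1] <- max(w[1], floor_t)
      len <- max(w[2] - w[1], 0)
      row[[paste0("lick_", nm)]] <-
        if (len > 0) sum(licks %inwin% w) / len else NA_real_
      sel <- behavior$time %inwin% w
      row[[paste0("speed_", nm)]] <-
        if (any(sel)) mean(behavior$speed[sel]) else NA_real_
    }
    row$clipped <- clipped
    tibble::as_tibble(row)
  })
}

#' Classify a session as expert or non-expert
#'
#' Expert requires both (a) a significant per-trial increase of the
#' pre-reward lick rate over baseline and (b) a significant per-trial
#' decrease of pre-reward speed relative to baseline (paired two-sided
#' Wilcoxon signed-rank with the direction read from the median difference,
#' alpha 0.05). Refuses sessions with fewer than 10 rewarded trials.
#'
#' @param rates A [zone_rates()] tibble.
#' @param config A [pipeline_config()].
#' @return List: `performance` ("expert"/"nonexpert"), `p_lick`, `p_speed`.
#' @export
classify_performance <- function(rates, config = pipeline_config()) {
  r <- rates[stats::complete.cases(rates[c("lick_pre", "lick_baseline",
                                           "speed_pre", "speed_baseline")]), ]
  if (nrow(r) < config$min_trials) {
    abort(paste0("only ", nrow(r), " usable rewarded trials; at least ",
                 config$min_trials, " required for performance classification"))
  }
  lick <- paired_test(r$lick_pre, r$lick_baseline, config$alpha)
  speed <- paired_test(r$speed_pre, r$speed_baseline, config$alpha)
  expert <- lick$direction == "increase" && speed$direction == "decrease"
  list(performance = if (expert) "expert" else "nonexpert",
       p_lick = lick$p, p_speed = speed$p,
       lick_direction = lick$direction, speed_direction = speed$direction)
}

#' Fraction of laps with anticipatory licking
#'
#' The performance score is the fraction of rewarded trials in which the
#' pre-reward lick rate exceeds the baseline lick rate.
#'
#' @param rates A [zone_rates()] tibble.
#' @return A number in `[0, 1]`.
#' @export
performance_score <- function(rates) {
  r <- rates[stats::complete.cases(rates[c("lick_pre", "lick_baseline")]), ]
  if (!nrow(r)) abort("no usable trials")
  mean(r$lick_pre > r$lick_baseline)
}

#' Linear trend of lick rate across laps
#'
#' Ordinary least-squares fit of per-lap lick rate on lap index with the
#' Pearson correlation and its two-sided p value.
#'
#' @param per_lap_rates Numeric vector of per-lap lick rates (Hz), in lap
#'   order.
#' @return Tibble with `slope`, `intercept`, `r`, `p`, `constant` (flag).
#' @export
lick_lap_trend <- function(per_lap_rates) {
  n <- length(per_lap_rates)
  if (n < 5) abort("at least 5 laps required for a lap trend")
  lap <- seq_len(n)
  if (sd(per_lap_rates) == 0) {
    return(tibble::tibble(slope = 0, intercept = per_lap_rates[1], r = 0,
                          p = NA_real_, constant = TRUE))
  }
  fit <- lm(per_lap_rates ~ lap)
  ct <- cor.test(lap, per_lap_rates)
  tibble::tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value, constant = FALSE)
}
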