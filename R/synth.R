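#' Synthetic-session configuration
#'
#' Defines the study conditions a generated session emulates: a 4 m circular
#' virtual track with two fixed reward sites, expert behavior (anticipatory
#' licking and deceleration in the 2 s pre-reward zone, reward-zone speed
#' approaching 5 cm/s) or non-expert behavior (flat licking and speed until
#' reward), SOMI units with predictive (pre-reward) or consumption
#' (post-reward) firing peaks, ChR2 light responses, locomotion-state
#' modulation, place-modulated principal cells, and optional monosynaptic
#' PC to SOMI coupling.
#'
#' @param n_laps Number of laps (default 30).
#' @param performance `"expert"` or `"nonexpert"`.
#' @param reward_positions_cm Reward site positions on the 400 cm track.
#' @param dt Behavior sample interval (s).
#' @param run_speed Cruising speed (cm/s).
#' @param reward_speed Expert reward-zone speed (cm/s); the deceleration is a
#'   linear ramp over the final 2 s before reward.
#' @param lick_rates Named vector `c(baseline=, pre=, post=)` in Hz; defaults
#'   depend on `performance`.
#' @param anticipation_prob Per-lap probability that the expert pre-zone lick
#'   boost is present (1 = every lap).
#' @param speed_cv Coefficient of variation of smooth multiplicative speed
#'   noise emulating trial-to-trial running variability (default 0.08).
#' @param units Unit specification tibble; see [default_unit_specs()].
#' @param synapses Tibble with columns `pre`, `post` (unit ids), `efficacy`,
#'   `latency_ms`, `jitter_ms`.
#' @param light List with pulse counts per block (`dg_50`, `dg_250`,
#'   `fimbria_50`, `fimbria_250`), `isi_s`, `gain` (ChR2 rate multiplier) or
#'   `NULL` to omit the tagging protocol.
#' @param sensory List with `kinds`, `n_each`, `duration_s`, `isi_s`, `gain`
#'   or `NULL` to omit the sensory protocol.
#' @param seed Master seed for the generator.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_laps = 30,
                         performance = c("expert", "nonexpert"),
                         reward_positions_cm = c(100, 300),
                         dt = 0.05,
                         run_speed = 25,
                         reward_speed = 5,
                         lick_rates = NULL,
                         anticipation_prob = 1,
                         speed_cv = 0.08,
                         units = NULL,
                         synapses = NULL,
                         light = list(dg_50 = 100, dg_250 = 70,
                                      fimbria_50 = 100, fimbria_250 = 70,
                                      isi_s = 5, gain = 10),
                         sensory = list(kinds = c("random_reward", "stim_visual",
                                                  "stim_sound", "stim_airpuff"),
                                        n_each = 20, duration_s = 0.5,
                                        isi_s = 5, gain = 3),
                         seed = 1L) {
  performance <- match.arg(performance)
  if (any(reward_positions_cm < 0 | reward_positions_cm >= 400)) {
    abort("reward positions must lie in [0, 400) cm")
  }
  if (is.null(lick_rates)) {
    lick_rates <- if (performance == "expert") {
      c(baseline = 0.5, pre = 4, post = 8)
    } else {
      c(baseline = 0.5, pre = 0.5, post = 8)
    }
  }
  if (is.null(units)) units <- default_unit_specs(performance)
  if (is.null(synapses)) {
    mcs <- units$unit_id[units$class == "PC" &
                           !is.na(units$subtype) & units$subtype == "mc"]
    somis <- units$unit_id[units$class == "SOMI"]
    n_syn <- min(3, length(mcs), length(somis))
    synapses <- tibble::tibble(pre = mcs[seq_len(n_syn)],
                               post = somis[seq_len(n_syn)],
                               efficacy = rep(0.3, n_syn),
                               latency_ms = rep(2, n_syn),
                               jitter_ms = rep(0.2, n_syn))
  }
  structure(list(n_laps = n_laps, performance = performance,
                 reward_positions_cm = sort(reward_positions_cm), dt = dt,
                 run_speed = run_speed, reward_speed = reward_speed,
                 lick_rates = lick_rates, anticipation_prob = anticipation_prob,
                 speed_cv = speed_cv,
                 units = tibble::as_tibble(units), synapses = synapses,
                 light = light, sensory = sensory, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default unit specifications for a synthetic session
#'
#' 12 SOMIs (ChR2-expressing, wide waveform, non-bursting; predictive reward
#' peaks in expert sessions, consumption peaks in non-expert ones; a mix of
#' locomotion ON/OFF/NON types; 8 of 12 project to the fimbria), 20 principal
#' cells (12 sparse high-spatial-information granule-like and 8 higher-rate
#' mossy-like units, both bursty and place-modulated), and 6 fast-spiking
#' interneurons. Two mossy-like units are SOMI-inhibited, two disinhibited,
#' and two fast-spiking units are SOMI-inhibited.
#'
#' @param performance `"expert"` or `"nonexpert"`; selects the SOMI reward
#'   profile (predictive peak at -0.1 s vs consumption peak at +1.2 s).
#' @param n_somi,n_pc,n_fsi Unit counts per class.
#' @return A tibble, one row per unit.
#' @export
default_unit_specs <- function(performance = "expert",
                               n_somi = 12, n_pc = 20, n_fsi = 6) {
  profile <- if (performance == "expert") "predictive" else "consumption"
  peak_t <- if (performance == "expert") -0.1 else 1.2
  width <- 0.5
  n_gc <- round(n_pc * 0.6)
  n_mc <- n_pc - n_gc
  somi <- tibble::tibble(
    unit_id = sprintf("somi%02d", seq_len(n_somi)),
    class = "SOMI", subtype = NA_character_,
    baseline_rate_hz = 8,
    reward_profile = profile, peak_gain = 3, peak_time_s = peak_t,
    width_s = width, boxcar_lo = NA_real_, boxcar_hi = NA_real_,
    locomotion = rep(c("ON", "OFF", "NON"), length.out = n_somi),
    burst_prob = 0, ttp_ms = 0.55,
    place_center_cm = NA_real_, place_width_cm = NA_real_, place_gain = 0,
    ds_amplitude = rnorm2(n_somi, 1.0, 0.2),
    spatial_info_target = NA_real_,
    is_chr2 = TRUE, chr2_latency_ms = seq(1.5, 3, length.out = n_somi),
    is_inhibited = FALSE, is_disinhibited = FALSE,
    projects_to_fimbria = seq_len(n_somi) <= round(0.7 * n_somi),
    sensory_kinds = list(c("random_reward", "stim_airpuff")))
  gc <- tibble::tibble(
    unit_id = sprintf("gc%02d", seq_len(n_gc)),
    class = "PC", subtype = "gc",
    baseline_rate_hz = 0.6,
    reward_profile = "none", peak_gain = 1, peak_time_s = 0, width_s = 0.5,
    boxcar_lo = NA_real_, boxcar_hi = NA_real_,
    locomotion = "NON", burst_prob = 0.25, ttp_ms = 0.62,
    place_center_cm = seq(10, 390, length.out = n_gc) + 17,
    place_width_cm = 12, place_gain = 10,
    ds_amplitude = rnorm2(n_gc, 1.6, 0.2),
    spatial_info_target = NA_real_,
    is_chr2 = FALSE, chr2_latency_ms = NA_real_,
    is_inhibited = FALSE,
    is_disinhibited = seq_len(n_gc) <= 0,
    projects_to_fimbria = FALSE,
    sensory_kinds = list(character(0)))
  mc <- tibble::tibble(
    unit_id = sprintf("mc%02d", seq_len(n_mc)),
    class = "PC", subtype = "mc",
    baseline_rate_hz = 6,
    reward_profile = "none", peak_gain = 1, peak_time_s = 0, width_s = 0.5,
    boxcar_lo = NA_real_, boxcar_hi = NA_real_,
    locomotion = "NON", burst_prob = 0.25, ttp_ms = 0.58,
    place_center_cm = seq(30, 370, length.out = n_mc),
    place_width_cm = 45,
    # the first three mossy-like units are the default presynaptic partners
    # of SOMIs; they are kept non-spatial so synaptic drive does not copy a
    # place field into the postsynaptic reward-window statistics
    place_gain = c(rep(0, min(3, n_mc)), rep(1.5, max(0, n_mc - 3))),
    ds_amplitude = rnorm2(n_mc, 0.6, 0.2),
    spatial_info_target = NA_real_,
    is_chr2 = FALSE, chr2_latency_ms = NA_real_,
    is_inhibited = seq_len(n_mc) <= 2,
    is_disinhibited = seq_len(n_mc) > 2 & seq_len(n_mc) <= 4,
    projects_to_fimbria = FALSE,
    sensory_kinds = list(character(0)))
  fsi <- tibble::tibble(
    unit_id = sprintf("fsi%02d", seq_len(n_fsi)),
    class = "FSI", subtype = NA_character_,
    baseline_rate_hz = 15,
    reward_profile = "none", peak_gain = 1, peak_time_s = 0, width_s = 0.5,
    boxcar_lo = NA_real_, boxcar_hi = NA_real_,
    locomotion = "NON", burst_prob = 0, ttp_ms = 0.25,
    place_center_cm = NA_real_, place_width_cm = NA_real_, place_gain = 0,
    ds_amplitude = rnorm2(n_fsi, 0.8, 0.2),
    spatial_info_target = NA_real_,
    is_chr2 = FALSE, chr2_latency_ms = NA_real_,
    is_inhibited = seq_len(n_fsi) <= 2, is_disinhibited = FALSE,
    projects_to_fimbria = FALSE,
    sensory_kinds = list(character(0)))
  dplyr::bind_rows(somi, gc, mc, fsi)
}

# deterministic spread used for feature defaults (not a random draw: unit
# specs are configuration, randomness enters only through spike generation)
rnorm2 <- function(n, mean, sd) mean + sd * sin(seq_len(n) * 2.3)

#' Unit specification for a reward-anticipation decoder cohort
#'
#' A cohort of identical reward-anticipatory SOMIs whose rate steps from the
#' baseline level to `gain` times baseline during the window before reward
#' onset — the configuration used to probe population decoding (10 cells,
#' 5 Hz baseline, rate doubling over the 1.5 s preceding reward).
#'
#' @param n_cells Number of SOMIs.
#' @param baseline_hz Baseline rate (Hz).
#' @param gain Multiplicative rate step during `window`.
#' @param window Step window relative to reward onset (s).
#' @return A unit-spec tibble for [synth_config()].
#' @export
decoder_cohort_spec <- function(n_cells = 10, baseline_hz = 5, gain = 2,
                                window = c(-1.5, 0)) {
  tibble::tibble(
    unit_id = sprintf("dec%02d", seq_len(n_cells)),
    class = "SOMI", subtype = NA_character_,
    baseline_rate_hz = baseline_hz,
    reward_profile = "boxcar", peak_gain = gain, peak_time_s = 0,
    width_s = 0.5, boxcar_lo = window[1], boxcar_hi = window[2],
    locomotion = "NON", burst_prob = 0, ttp_ms = 0.55,
    place_center_cm = NA_real_, place_width_cm = NA_real_, place_gain = 0,
    ds_amplitude = 1, spatial_info_target = NA_real_,
    is_chr2 = FALSE, chr2_latency_ms = NA_real_, is_inhibited = FALSE,
    is_disinhibited = FALSE, projects_to_fimbria = FALSE,
    sensory_kinds = list(character(0)))
}

# ---- behavior -------------------------------------------------------------

# A lap is a chain of constant-acceleration segments. Returns a tibble
# (duration, v0, v1, reward) where reward marks segment ends at reward sites.
# The immobility bout sits right after the first reward's post zone so that
# the 4-6 s pre-reward baseline windows of both sites fall on steady cruise.
lap_segments <- function(cfg) {
  rs <- cfg$reward_positions_cm
  v <- cfg$run_speed
  vr <- cfg$reward_speed
  seg <- function(duration, v0, v1, reward = FALSE) {
    tibble::tibble(duration = duration, v0 = v0, v1 = v1, reward = reward)
  }
  out <- list()
  pos <- 0
  if (cfg$performance == "expert") {
    d_dec <- (v + vr)            # 2 s deceleration ramp distance
    for (i in seq_along(rs)) {
      d_app <- rs[i] - pos - d_dec
      if (d_app < 10) abort("reward positions too close for expert profile")
      out <- c(out, list(seg(d_app / v, v, v),
                         seg(2, v, vr, reward = TRUE),
                         seg(2, vr, vr),
                         seg(1, vr, v)))
      pos <- rs[i] + 2 * vr + (vr + v) / 2
      if (i == length(rs)) {
        # immobility bout after the last reward zone, separated from the
        # reward response by a short cruise so transition windows are clean
        out <- c(out, list(seg(0.5, v, v),
                           seg(1, v, 0),
                           seg(4, 0, 0),
                           seg(2, 0, v)))
        pos <- pos + v / 2 + v / 2 + v
      }
    }
  } else {
    for (i in seq_along(rs)) {
      out <- c(out, list(seg((rs[i] - pos) / v, v, v, reward = TRUE)))
      pos <- rs[i]
      if (i == 1) {
        out <- c(out, list(seg(10 / v, v, v),
                           seg(1, v, 0),
                           seg(4, 0, 0),
                           seg(2, 0, v)))
        pos <- pos + 10 + v / 2 + v
      }
    }
  }
  last_d <- 400 - pos
  if (last_d < 10) abort("track layout leaves no room for final cruise")
  out <- c(out, list(seg(last_d / v, v, v)))
  dplyr::bind_rows(out)
}

#' Generate behavior traces, lick/reward events, and laps
#'
#' Position advances monotonically modulo 400 cm. Expert sessions decelerate
#' linearly over the final 2 s before each reward to the reward-zone speed
#' and boost the lick rate in the 2 s pre-reward window; non-expert sessions
#' cruise through rewards at constant speed with flat pre-reward licking.
#' Every lap contains an immobility bout (4 s at 0 cm/s) flanked by 1-2 s
#' speed ramps so running-transition detection is exercised.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `behavior`, `events`, `laps`, `reward_times`,
#'   `anticipatory_laps` (logical, per lap).
#' @export
generate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  segs <- lap_segments(cfg)
  lap_dur <- sum(segs$duration)
  # prelude: rest then ramp up so lap 1 starts at position 0 at run speed
  pre <- tibble::tibble(duration = c(3.5, 2), v0 = c(0, 0),
                        v1 = c(0, cfg$run_speed), reward = FALSE)
  all_segs <- dplyr::bind_rows(
    pre, purrr::map_dfr(seq_len(cfg$n_laps), ~segs))
  t0 <- cumsum(c(0, all_segs$duration))
  t_end <- t0[length(t0)]
  n_lap_seg <- nrow(segs)

  reward_times <- t0[-1][all_segs$reward]
  laps <- tibble::tibble(lap = seq_len(cfg$n_laps),
                         start = t0[2 + (seq_len(cfg$n_laps) - 1) * n_lap_seg + 1],
                         end = t0[2 + seq_len(cfg$n_laps) * n_lap_seg + 1])

  if (cfg$n_laps == 0) {
    return(list(behavior = tibble::tibble(time = numeric(0), position = numeric(0),
                                          speed = numeric(0)),
                events = tibble::tibble(time = numeric(0), kind = character(0),
                                        duration = numeric(0)),
                laps = tibble::tibble(lap = integer(0), start = numeric(0),
                                      end = numeric(0)),
                reward_times = numeric(0), anticipatory_laps = logical(0)))
  }

  # sample speed / analytic position on the dt grid
  tt <- seq(0, t_end - cfg$dt / 2, by = cfg$dt)
  seg_idx <- findInterval(tt, t0, rightmost.closed = TRUE)
  tau <- tt - t0[seg_idx]
  v0 <- all_segs$v0[seg_idx]; v1 <- all_segs$v1[seg_idx]
  dur <- all_segs$duration[seg_idx]
  speed <- v0 + (v1 - v0) * tau / dur
  if ((cfg$speed_cv %||% 0) > 0) {
    # smooth multiplicative jitter: trial-to-trial running variability while
    # immobility (speed 0) stays exact; position stays on the nominal profile
    eta <- with_seed(stage_seed(cfg$seed, "speednoise"),
                     gauss_smooth(rnorm(length(speed)), 5))
    eta <- eta / max(sd(eta), 1e-12)
    speed <- speed * pmax(1 + cfg$speed_cv * eta, 0)
  }
  seg_d <- (all_segs$v0 + all_segs$v1) / 2 * all_segs$duration
  p0 <- cumsum(c(0, seg_d))
  position <- (p0[seg_idx] + v0 * tau + (v1 - v0) * tau^2 / (2 * dur) - 25) %% 400
  # (-25: the prelude ramp covers the final 25 cm of the wrap before lap 1)
  behavior <- tibble::tibble(time = tt, position = position, speed = speed)

  # licks: piecewise-constant Poisson rate keyed to reward windows
  lr <- cfg$lick_rates
  antic <- with_seed(stage_seed(cfg$seed, "anticipation"),
                     runif(cfg$n_laps) < cfg$anticipation_prob)
  lap_of_reward <- findInterval(reward_times, laps$start)
  pre_on <- if (cfg$performance == "expert") antic[lap_of_reward] else
    rep(lr["pre"] != lr["baseline"], length(reward_times))
  licks <- with_seed(stage_seed(cfg$seed, "licks"), {
    base <- runif(rpois(1, lr[["baseline"]] * t_end), 0, t_end)
    extra <- unlist(purrr::map(seq_along(reward_times), function(i) {
      tr <- reward_times[i]
      pre_rate <- if (pre_on[i]) lr[["pre"]] else lr[["baseline"]]
      c(runif(rpois(1, max(0, pre_rate - lr[["baseline"]]) * 2), tr - 2, tr),
        runif(rpois(1, max(0, lr[["post"]] - lr[["baseline"]]) * 2), tr, tr + 2))
    }))
    sort(c(base, extra))
  })
  events <- dplyr::bind_rows(
    tibble::tibble(time = reward_times, kind = "reward", duration = 0.5),
    tibble::tibble(time = licks, kind = "lick", duration = 0)) |>
    dplyr::arrange(.data$kind, .data$time)
  list(behavior = behavior, events = events, laps = laps,
       reward_times = reward_times, anticipatory_laps = antic)
}

# ---- spike generation -----------------------------------------------------

#' Simulate an inhomogeneous Poisson spike train by thinning
#'
#' Counts in any window W are Poisson with mean `integral of rate over W`.
#'
#' @param rate_fn Vectorized rate function of time (Hz), must be bounded by
#'   `rate_max` and non-negative.
#' @param t_range Length-2 numeric `(start, end)` in seconds.
#' @param rate_max Upper bound on the rate (Hz).
#' @param seed Integer seed.
#' @param dead_time Optional absolute refractory period (s), default 0.
#' @return Sorted spike times (s).
#' @export
generate_spike_train <- function(rate_fn, t_range, rate_max, seed,
                                 dead_time = 0) {
  stopifnot(length(t_range) == 2, rate_max >= 0)
  dur <- diff(t_range)
  if (dur <= 0 || rate_max == 0) return(numeric(0))
  with_seed(seed, {
    n <- rpois(1, rate_max * dur)
    cand <- sort(runif(n, t_range[1], t_range[2]))
    r <- rate_fn(cand)
    if (any(r < 0)) abort("rate function returned a negative rate")
    if (any(r > rate_max + 1e-9)) abort("rate function exceeds rate_max bound")
    keep <- runif(n) < r / rate_max
    st <- cand[keep]
    if (length(st) > 1) st <- st[c(TRUE, diff(st) > 0)]
    if (dead_time > 0 && length(st) > 1) {
      ok <- c(TRUE, diff(st) > dead_time)
      while (!all(ok)) {
        st <- st[ok]
        ok <- c(TRUE, diff(st) > dead_time)
      }
    }
    st
  })
}

#' Add monosynaptically driven spikes to a postsynaptic train
#'
#' Each presynaptic spike evokes one postsynaptic spike with probability
#' `efficacy`, at `latency_ms` plus Gaussian jitter; the background
#' postsynaptic train is preserved.
#'
#' @param pre_times,post_times Sorted spike times (s).
#' @param efficacy Transmission probability in (0, 1].
#' @param latency_ms Synaptic latency (ms), must be positive.
#' @param jitter_ms SD of the latency jitter (ms).
#' @param seed Integer seed.
#' @return Sorted combined postsynaptic spike times.
#' @export
inject_synapse <- function(pre_times, post_times, efficacy, latency_ms,
                           jitter_ms = 0.2, seed = 1L) {
  if (latency_ms <= 0) abort("synaptic latency must be positive")
  stopifnot(efficacy >= 0, efficacy <= 1)
  if (efficacy == 0 || !length(pre_times)) return(sort(post_times))
  with_seed(seed, {
    hit <- runif(length(pre_times)) < efficacy
    evoked <- pre_times[hit] + (latency_ms + rnorm(sum(hit), 0, jitter_ms)) / 1000
    dedupe_train(c(post_times, evoked))
  })
}

dedupe_train <- function(x, min_gap = 1e-4) {
  x <- sort(x)
  if (length(x) > 1) {
    keep <- c(TRUE, diff(x) > min_gap)
    x <- x[keep]
  }
  x
}

#' Build a light-pulse protocol and apply opsin responses to spike trains
#'
#' Schedules rectangular pulses (5 s inter-stimulus interval) at the dentate
#' gyrus and fimbria sites starting at `t_start`. ChR2 units receive a
#' deterministic first spike at their latency plus an elevated Poisson rate
#' for the pulse duration; inhibited units lose 95% of their spikes during
#' pulses; disinhibited units gain rate only from 8 ms after onset, so their
#' first light-evoked spikes come late.
#'
#' @param units Tibble with at least `unit_id`, `spike_times` (list),
#'   `baseline_rate_hz`, `is_chr2`, `chr2_latency_ms`, `is_inhibited`,
#'   `is_disinhibited`, `projects_to_fimbria`.
#' @param light Light config list (see [synth_config()]).
#' @param t_start Start time of the protocol (s).
#' @param seed Integer seed.
#' @return List with `events` (pulse table) and `spike_times` (modified list).
#' @export
apply_light_protocol <- function(units, light, t_start, seed = 1L) {
  blocks <- list(
    list(kind = "light_dg", dur = 0.050, n = light$dg_50 %||% 0),
    list(kind = "light_dg", dur = 0.250, n = light$dg_250 %||% 0),
    list(kind = "light_fimbria", dur = 0.050, n = light$fimbria_50 %||% 0),
    list(kind = "light_fimbria", dur = 0.250, n = light$fimbria_250 %||% 0))
  isi <- light$isi_s %||% 5
  t <- t_start
  ev <- list()
  for (b in blocks) {
    if (b$n > 0) {
      onsets <- t + seq_len(b$n) * isi - isi + 1
      ev <- c(ev, list(tibble::tibble(time = onsets, kind = b$kind,
                                      duration = b$dur)))
      t <- onsets[b$n] + isi
    }
  }
  events <- dplyr::bind_rows(ev)
  if (nrow(events)) {
    chk <- events |> dplyr::arrange(.data$time)
    if (any(diff(chk$time) < chk$duration[-nrow(chk)])) {
      abort("light pulses overlap")
    }
  }
  gain <- light$gain %||% 10
  trains <- units$spike_times
  for (i in seq_len(nrow(units))) {
    st <- trains[[i]]
    u <- units[i, ]
    sd_i <- stage_seed(seed, paste0("light_", u$unit_id))
    for (site in c("light_dg", "light_fimbria")) {
      pl <- events[events$kind == site, ]
      if (!nrow(pl)) next
      responds_chr2 <- isTRUE(u$is_chr2) &&
        (site == "light_dg" || isTRUE(u$projects_to_fimbria))
      st <- with_seed(stage_seed(sd_i, site), {
        if (responds_chr2) {
          g <- if (site == "light_dg") gain else gain / 2
          lat <- (u$chr2_latency_ms %||% 2) / 1000
          extra <- unlist(purrr::map2(pl$time, pl$duration, function(on, dur) {
            n <- rpois(1, (g - 1) * u$baseline_rate_hz * dur)
            c(on + lat, runif(n, on + lat, on + dur))
          }))
          dedupe_train(c(st, extra))
        } else if (isTRUE(u$is_inhibited) && site == "light_dg") {
          in_pulse <- rep(FALSE, length(st))
          for (j in seq_len(nrow(pl))) {
            in_pulse <- in_pulse | (st >= pl$time[j] & st < pl$time[j] + pl$duration[j])
          }
          drop <- in_pulse & runif(length(st)) < 0.95
          st[!drop]
        } else if (isTRUE(u$is_disinhibited) && site == "light_dg") {
          extra <- unlist(purrr::map2(pl$time, pl$duration, function(on, dur) {
            if (dur <= 0.008) return(numeric(0))
            runif(rpois(1, 3 * u$baseline_rate_hz * (dur - 0.008)),
                  on + 0.008, on + dur)
          }))
          dedupe_train(c(st, extra))
        } else st
      })
    }
    trains[[i]] <- st
  }
  list(events = events, spike_times = trains)
}

# ---- full session ---------------------------------------------------------

circ_dist <- function(a, b, L = 400) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

# Gaussian bump value from the nearest center only (centers well separated)
nearest_bump <- function(t, centers, width) {
  if (!length(centers)) return(rep(0, length(t)))
  centers <- sort(centers)
  i <- findInterval(t, centers)
  d1 <- abs(t - centers[pmax(i, 1)])
  d2 <- abs(t - centers[pmin(i + 1, length(centers))])
  exp(-pmin(d1, d2)^2 / (2 * width^2))
}

# TRUE where t falls in [event + lo, event + hi) for some event
in_event_window <- function(t, events, lo, hi) {
  if (!length(events)) return(rep(FALSE, length(t)))
  events <- sort(events)
  i <- findInterval(t, events)
  n <- length(events)
  rel_prev <- t - events[pmax(i, 1)]
  rel_next <- t - events[pmin(i + 1, n)]
  (i >= 1 & rel_prev >= lo & rel_prev < hi) |
    (i < n & rel_next >= lo & rel_next < hi)
}

#' Generate a complete synthetic session with ground truth
#'
#' Composes behavior, inhomogeneous-Poisson spike trains (reward, place and
#' locomotion modulation), burst doublets for principal cells, monosynaptic
#' injections, the optogenetic tagging protocol and an optional sensory
#' protocol. Deterministic under the config seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `session` (a `somipipe_session`) and `truth`, a list
#'   holding per-unit ground-truth labels, the synapse table, the lap
#'   anticipation vector, and the configured performance class.
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  beh <- generate_behavior(cfg)
  behavior_end <- if (nrow(beh$behavior)) max(beh$behavior$time) + cfg$dt else 0

  # sensory protocol block (after behavior)
  sens_events <- tibble::tibble(time = numeric(0), kind = character(0),
                                duration = numeric(0))
  t_cursor <- behavior_end + 10
  if (!is.null(cfg$sensory) && cfg$n_laps > 0) {
    sc <- cfg$sensory
    onsets <- t_cursor + seq_len(sc$n_each * length(sc$kinds)) * sc$isi_s
    kind_seq <- with_seed(stage_seed(cfg$seed, "sensory_order"),
                          sample(rep(sc$kinds, sc$n_each)))
    sens_events <- tibble::tibble(time = onsets, kind = kind_seq,
                                  duration = sc$duration_s) |>
      dplyr::arrange(.data$kind, .data$time)
    t_cursor <- max(onsets) + sc$isi_s
  }
  light_start <- t_cursor
  light_dur <- if (is.null(cfg$light)) 0 else {
    n_pulses <- sum(unlist(cfg$light[c("dg_50", "dg_250", "fimbria_50",
                                       "fimbria_250")]), na.rm = TRUE)
    n_pulses * (cfg$light$isi_s %||% 5) + 5
  }
  t_total_base <- light_start + light_dur  # base trains span the light block

  specs <- cfg$units
  speed_fn <- if (nrow(beh$behavior)) {
    approxfun(beh$behavior$time, beh$behavior$speed, method = "linear",
              yleft = 0, yright = 0)
  } else function(t) rep(0, length(t))
  pos_step <- if (nrow(beh$behavior)) {
    approxfun(beh$behavior$time, beh$behavior$position, method = "constant",
              yleft = 0, yright = 0)
  } else function(t) rep(0, length(t))

  rate_fn_for <- function(u) {
    force(u)
    function(t) {
      r <- rep(u$baseline_rate_hz, length(t))
      in_beh <- t < behavior_end
      if (any(in_beh)) {
        sp <- speed_fn(t[in_beh])
        loco <- switch(u$locomotion,
                       ON = 0.75 + 0.5 * pmin(sp, 25) / 25,
                       OFF = 1.25 - 0.5 * pmin(sp, 25) / 25,
                       rep(1, length(sp)))
        place <- if (!is.na(u$place_center_cm) && u$place_gain > 0) {
          1 + u$place_gain *
            exp(-circ_dist(pos_step(t[in_beh]), u$place_center_cm)^2 /
                  (2 * u$place_width_cm^2))
        } else 1
        rew <- rep(1, sum(in_beh))
        if (u$reward_profile %in% c("predictive", "consumption", "suppressed") &&
            length(beh$reward_times)) {
          bump <- nearest_bump(t[in_beh], beh$reward_times + u$peak_time_s,
                               u$width_s)
          g <- if (u$reward_profile == "suppressed") 0.2 else u$peak_gain
          rew <- 1 + (g - 1) * pmin(bump, 1)
        } else if (u$reward_profile == "boxcar" && length(beh$reward_times)) {
          inwin <- in_event_window(t[in_beh], beh$reward_times,
                                   u$boxcar_lo, u$boxcar_hi)
          rew <- ifelse(inwin, u$peak_gain, 1)
        }
        slope <- if ("speed_slope" %in% names(u)) u$speed_slope else 0
        if (is.na(slope)) slope <- 0
        r[in_beh] <- pmax(u$baseline_rate_hz * loco * place * rew +
                            slope * sp, 0)
      }
      if (nrow(sens_events) && length(u$sensory_kinds[[1]])) {
        sel <- sens_events[sens_events$kind %in% u$sensory_kinds[[1]], ]
        for (j in seq_len(nrow(sel))) {
          hit <- t >= sel$time[j] & t < sel$time[j] + sel$duration[j]
          r[hit] <- r[hit] * (cfg$sensory$gain %||% 3)
        }
      }
      r
    }
  }

  trains <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    u <- specs[i, ]
    slope <- if ("speed_slope" %in% names(u)) u$speed_slope else 0
    if (is.na(slope)) slope <- 0
    rmax <- u$baseline_rate_hz * 1.3 * (1 + max(0, u$place_gain)) *
      max(1, u$peak_gain) * max(1, cfg$sensory$gain %||% 1) +
      max(0, slope) * 50 + 1   # slope margin covers speed-noise excursions
    st <- generate_spike_train(rate_fn_for(u), c(0, t_total_base), rmax,
                               stage_seed(cfg$seed, paste0("unit_", u$unit_id)))
    if (u$burst_prob > 0 && length(st)) {
      st <- with_seed(stage_seed(cfg$seed, paste0("burst_", u$unit_id)), {
        add <- runif(length(st)) < u$burst_prob
        dedupe_train(c(st, st[add] + 0.004 + rnorm(sum(add), 0, 3e-4)))
      })
    }
    trains[[i]] <- st
  }
  names(trains) <- specs$unit_id

  # monosynaptic injections
  if (nrow(cfg$synapses)) {
    for (j in seq_len(nrow(cfg$synapses))) {
      syn <- cfg$synapses[j, ]
      trains[[syn$post]] <- inject_synapse(
        trains[[syn$pre]], trains[[syn$post]], syn$efficacy, syn$latency_ms,
        syn$jitter_ms, stage_seed(cfg$seed, paste0("syn_", j)))
    }
  }

  # light protocol
  light_events <- tibble::tibble(time = numeric(0), kind = character(0),
                                 duration = numeric(0))
  if (!is.null(cfg$light)) {
    lu <- specs
    lu$spike_times <- trains
    lp <- apply_light_protocol(lu, cfg$light, light_start,
                               stage_seed(cfg$seed, "light"))
    light_events <- lp$events
    trains <- lp$spike_times
  }

  waveforms <- purrr::map(seq_len(nrow(specs)), function(i) {
    make_waveform(specs$ttp_ms[i], seed = stage_seed(cfg$seed, paste0("wf_", i)))
  })
  units <- tibble::tibble(unit_id = specs$unit_id, spike_times = trains,
                          waveform = waveforms, fs = 30000)
  events <- dplyr::bind_rows(beh$events, sens_events, light_events) |>
    dplyr::arrange(.data$kind, .data$time)
  session <- new_session(units, beh$behavior, events, beh$laps,
                         meta = list(dt = cfg$dt))
  truth_units <- specs |>
    dplyr::mutate(
      unit_class = dplyr::case_when(
        class == "PC" ~ "PC",
        class == "FSI" ~ "FSI",
        TRUE ~ "WI"),
      opto = dplyr::case_when(
        is_chr2 ~ "SOMI",
        is_inhibited ~ "SOM_inh",
        is_disinhibited ~ "SOM_disinh",
        TRUE ~ "NONE"),
      projection = dplyr::case_when(
        is_chr2 & projects_to_fimbria ~ "proj",
        is_chr2 ~ "local",
        TRUE ~ NA_character_)) |>
    dplyr::select("unit_id", "class", "subtype", "unit_class", "opto",
                  "projection", "reward_profile", "locomotion",
                  "baseline_rate_hz", "ds_amplitude")
  list(session = session,
       truth = list(units = truth_units, synapses = cfg$synapses,
                    performance = cfg$performance,
                    anticipatory_laps = beh$anticipatory_laps))
}

# Biphasic template: Gaussian trough then a slower positive peak ttp_ms later,
# on 4 sites with an amplitude profile peaking at site 2.
make_waveform <- function(ttp_ms, fs = 30000, n_samples = 48, seed = 1L) {
  t_ms <- (seq_len(n_samples) - 1) / fs * 1000
  t_tr <- t_ms[16]
  w <- -exp(-(t_ms - t_tr)^2 / (2 * 0.09^2)) +
    0.55 * exp(-(t_ms - t_tr - ttp_ms)^2 / (2 * (ttp_ms / 2.2)^2))
  amp <- c(0.35, 1, 0.55, 0.25) * 120
  with_seed(seed, {
    m <- outer(amp, w) + matrix(rnorm(4 * n_samples, 0, 0.8), 4, n_samples)
    m
  })
}
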