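#' Per-unit light-pulse response
#'
#' Compares, pulse by pulse, spike counts during `[onset, onset + dur)` with
#' counts in the same-length pre-stimulation interval `[onset - dur, onset)`
#' (paired two-sided Wilcoxon signed-rank; direction from the median
#' difference) and collects the first-spike latency per pulse. Pulse sets of
#' different durations should be passed separately.
#'
#' @param spike_times Sorted spike times (s).
#' @param pulses Tibble with `time` and a single shared `duration`.
#' @param config A [pipeline_config()].
#' @return List: `p`, `direction` (increase/decrease/none),
#'   `median_first_latency_ms` (NaN when no pulse evoked a spike),
#'   `per_pulse` tibble (`count_during`, `count_pre`, `first_latency_ms`),
#'   `n_pulses`.
#' @export
light_response <- function(spike_times, pulses, config = pipeline_config()) {
  if (nrow(pulses) < config$min_pulses) {
    abort(paste0("only ", nrow(pulses), " pulses; at least ",
                 config$min_pulses, " required (underpowered)"))
  }
  dur <- unique(pulses$duration)
  if (length(dur) != 1) abort("pulses must share one duration; split by set")
  on <- pulses$time
  per <- tibble::tibble(
    count_during = count_in(spike_times, on, on + dur),
    count_pre = count_in(spike_times, on - dur, on),
    first_latency_ms = vapply(on, function(o) {
      f <- first_after(spike_times, o, o + dur)
      if (is.na(f)) NA_real_ else (f - o) * 1000
    }, numeric(1)))
  tst <- paired_test(per$count_during, per$count_pre, config$alpha)
  lat <- per$first_latency_ms[!is.na(per$first_latency_ms)]
  list(p = tst$p, direction = tst$direction,
       median_first_latency_ms = if (length(lat)) median(lat) else NaN,
       per_pulse = per, n_pulses = nrow(pulses))
}

# Union verdict over the available pulse-duration sets at one site:
# significant in either set with a consistent direction.
site_response <- function(spike_times, events, site_kind, config) {
  pulses <- events[events$kind == site_kind, ]
  if (!nrow(pulses)) return(NULL)
  sets <- split(pulses, pulses$duration)
  resps <- purrr::map(sets, function(p) {
    if (nrow(p) < config$min_pulses) return(NULL)
    light_response(spike_times, p, config)
  })
  resps <- purrr::compact(resps)
  if (!length(resps)) return(NULL)
  dirs <- purrr::map_chr(resps, "direction")
  sig <- dirs != "none"
  direction <- if (!any(sig)) "none"
  else if (length(unique(dirs[sig])) == 1) unique(dirs[sig])
  else "none"   # inconsistent directions across pulse sets
  lats <- purrr::map_dbl(resps, "median_first_latency_ms")
  list(direction = direction,
       p = min(purrr::map_dbl(resps, "p")),
       median_first_latency_ms = if (all(is.nan(lats))) NaN else
         median(lats[!is.nan(lats)]),
       per_set = resps)
}

#' Tag a unit from its dentate-gyrus light response
#'
#' SOMI: significant rate increase during light with median first-spike
#' latency at or below 5 ms. SOM-disinhibited: significant increase with
#' first spikes later than 5 ms. SOM-inhibited: significant decrease.
#' Otherwise NONE. An auxiliary flag marks units whose spike counts rise
#' within the first 5 ms of the pulse but fall afterwards (SOMIs inhibited
#' by other SOMIs).
#'
#' @param resp_dg A [light_response()]-style result for the DG site (the
#'   union verdict of [optotag_units()] or a single-set response).
#' @param config A [pipeline_config()].
#' @return List: `tag` in SOMI/SOM_disinh/SOM_inh/NONE, `latency_ms`, `p`.
#' @export
tag_unit <- function(resp_dg, config = pipeline_config()) {
  if (is.null(resp_dg)) return(list(tag = "NONE", latency_ms = NaN, p = NA_real_))
  lat <- resp_dg$median_first_latency_ms
  tag <- if (resp_dg$direction == "increase") {
    if (!is.nan(lat) && lat <= config$somi_latency_ms) "SOMI" else "SOM_disinh"
  } else if (resp_dg$direction == "decrease") "SOM_inh" else "NONE"
  list(tag = tag, latency_ms = lat, p = resp_dg$p)
}

#' Projection subtype from fimbria stimulation
#'
#' Identified SOMIs with a significant rate increase under fimbria
#' stimulation (antidromic activation of long-range axons) are putative
#' projection SOMIs; SOMIs without a significant change are putative local
#' SOMIs. Non-SOMIs, or sessions without a fimbria protocol, return NA.
#'
#' @param tag_dg Tag string from [tag_unit()].
#' @param resp_fimbria Fimbria-site response (or `NULL` when absent).
#' @return `"proj"`, `"local"`, or `NA`.
#' @export
subtype_projection <- function(tag_dg, resp_fimbria) {
  if (!identical(tag_dg, "SOMI") || is.null(resp_fimbria)) return(NA_character_)
  if (resp_fimbria$direction == "increase") "proj" else "local"
}

#' Optogenetic tagging of all units in a session
#'
#' Runs [light_response()] per pulse-duration set and site, combines sets by
#' the union rule, applies [tag_unit()] and [subtype_projection()].
#'
#' @param session A `somipipe_session`.
#' @param config A [pipeline_config()].
#' @return Tibble: `unit_id`, `opto` tag, `latency_ms`, `p_dg`, `p_fimbria`,
#'   `projection`, `somi_inh_flag`.
#' @export
optotag_units <- function(session, config = pipeline_config()) {
  purrr::map_dfr(seq_len(nrow(session$units)), function(i) {
    st <- session$units$spike_times[[i]]
    dg <- site_response(st, session$events, "light_dg", config)
    fim <- site_response(st, session$events, "light_fimbria", config)
    tg <- tag_unit(dg, config)
    proj <- subtype_projection(tg$tag, fim)
    tibble::tibble(unit_id = session$units$unit_id[i],
                   opto = tg$tag, latency_ms = tg$latency_ms,
                   p_dg = tg$p %||% NA_real_,
                   p_fimbria = if (is.null(fim)) NA_real_ else fim$p,
                   projection = proj,
                   somi_inh_flag = somi_inhibited_flag(st, session$events, config))
  })
}

# Auxiliary: increase in the first 5 ms of DG pulses but a decrease in the
# remainder of the pulse (candidate SOMI-inhibited-by-SOMI).
somi_inhibited_flag <- function(spike_times, events, config) {
  pulses <- events[events$kind == "light_dg", ]
  if (nrow(pulses) < config$min_pulses) return(FALSE)
  w <- config$somi_latency_ms / 1000
  on <- pulses$time
  dur <- pulses$duration
  early <- count_in(spike_times, on, on + w)
  early_pre <- count_in(spike_times, on - w, on)
  late <- count_in(spike_times, on + w, on + dur)
  late_pre <- count_in(spike_times, on - dur, on - w)
  a <- paired_test(early, early_pre, config$alpha)
  b <- paired_test(late, late_pre, config$alpha)
  a$direction == "increase" && b$direction == "decrease"
}
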