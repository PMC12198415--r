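#' Construct a recording session
#'
#' A session bundles everything one recording produces: sorted units (spike
#' times plus mean waveforms), continuous behavior traces (track position and
#' running speed on a common uniform clock), an event table (rewards, licks,
#' light pulses, sensory stimuli), and a lap table. All timestamps are seconds
#' on one common clock starting at 0.
#'
#' @param units Tibble with columns `unit_id` (character), `spike_times`
#'   (list of strictly increasing numeric vectors), `waveform` (list of
#'   site x sample matrices), `fs` (waveform sample rate, Hz). Optional
#'   feature columns are carried along.
#' @param behavior Tibble with columns `time`, `position` (cm, in
#'   `[0, track_length)`), `speed` (cm/s); `time` must be uniformly sampled.
#' @param events Tibble with columns `time`, `kind`, `duration`. Recognized
#'   kinds: reward, lick, light_dg, light_fimbria, stim_visual, stim_sound,
#'   stim_airpuff, random_reward.
#' @param laps Tibble with columns `lap`, `start`, `end` (seconds).
#' @param meta Named list; defaults fill `track_length_cm = 400`,
#'   `pre_zone_s = 2`, `post_zone_s = 2`, `baseline_window_s = c(-6, -4)`.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `somipipe_session`.
#' @export
new_session <- function(units, behavior, events, laps, meta = list(),
                        validate = TRUE) {
  meta_def <- list(track_length_cm = 400, pre_zone_s = 2, post_zone_s = 2,
                   baseline_window_s = c(-6, -4))
  meta_def[names(meta)] <- meta
  s <- structure(
    list(units = tibble::as_tibble(units),
         behavior = tibble::as_tibble(behavior),
         events = tibble::as_tibble(events),
         laps = tibble::as_tibble(laps),
         meta = meta_def),
    class = "somipipe_session")
  if (validate) validate_session(s)
  s
}

EVENT_KINDS <- c("reward", "lick", "light_dg", "light_fimbria",
                 "stim_visual", "stim_sound", "stim_airpuff", "random_reward")

#' Validate session invariants
#'
#' Checks timestamp finiteness and ordering, position range, per-kind event
#' sorting, and that every reward lies inside exactly one lap. Violations
#' abort with the offending record named.
#'
#' @param session A `somipipe_session`.
#' @return The session, invisibly.
#' @export
validate_session <- function(session) {
  s <- session
  stopifnot(inherits(s, "somipipe_session"))
  need <- c("unit_id", "spike_times", "waveform", "fs")
  if (!all(need %in% names(s$units))) {
    abort(paste("units table missing column(s):",
                paste(setdiff(need, names(s$units)), collapse = ", ")))
  }
  for (i in seq_len(nrow(s$units))) {
    st <- s$units$spike_times[[i]]
    if (length(st) && (any(!is.finite(st)) || any(st < 0))) {
      abort(paste0("unit ", s$units$unit_id[i], ": non-finite or negative spike times"))
    }
    if (length(st) > 1 && any(diff(st) <= 0)) {
      abort(paste0("unit ", s$units$unit_id[i], ": spike times not strictly increasing"))
    }
    wf <- s$units$waveform[[i]]
    if (!is.matrix(wf) || nrow(wf) < 1) {
      abort(paste0("unit ", s$units$unit_id[i], ": waveform must be a site x sample matrix"))
    }
  }
  if (nrow(s$behavior)) {
    tl <- s$meta$track_length_cm
    if (any(s$behavior$position < 0 | s$behavior$position >= tl)) {
      abort("behavior position outside [0, track_length)")
    }
    dt <- diff(s$behavior$time)
    if (length(dt) && (max(dt) - min(dt)) > 1e-6) {
      abort("behavior trace is not uniformly sampled")
    }
  }
  if (nrow(s$events)) {
    bad <- setdiff(unique(s$events$kind), EVENT_KINDS)
    if (length(bad)) abort(paste("unknown event kind(s):", paste(bad, collapse = ", ")))
    srt <- s$events |>
      dplyr::group_by(.data$kind) |>
      dplyr::summarise(ok = !is.unsorted(.data$time), .groups = "drop")
    if (any(!srt$ok)) {
      abort(paste("event timestamps unsorted for kind:",
                  paste(srt$kind[!srt$ok], collapse = ", ")))
    }
    rw <- s$events$time[s$events$kind == "reward"]
    if (length(rw) && nrow(s$laps)) {
      hits <- vapply(rw, function(t)
        sum(t >= s$laps$start & t < s$laps$end), numeric(1))
      if (any(hits != 1)) {
        abort(paste0("reward event at t = ", rw[which(hits != 1)[1]],
                     " s lies inside ", hits[which(hits != 1)[1]],
                     " laps (expected exactly 1)"))
      }
    }
  }
  invisible(session)
}

#' @export
print.somipipe_session <- function(x, ...) {
  cat("<somipipe_session>\n")
  cat("  units: ", nrow(x$units), "\n", sep = "")
  cat("  behavior samples: ", nrow(x$behavior), "\n", sep = "")
  if (nrow(x$events)) {
    tab <- table(x$events$kind)
    cat("  events: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  laps: ", nrow(x$laps), "\n", sep = "")
  invisible(x)
}

#' Write a session bundle to disk
#'
#' The bundle is a directory of columnar CSV tables (spikes, waveforms,
#' behavior, events, laps, units) plus a JSON manifest holding metadata and
#' row counts: inspectable, language-agnostic, and diff-able. Byte layout is
#' deterministic for identical input.
#'
#' @param session A validated `somipipe_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  u <- session$units
  spikes <- tibble::tibble(
    unit_id = rep(u$unit_id, lengths(u$spike_times)),
    time = unlist(u$spike_times) %||% numeric(0))
  wf <- dplyr::bind_rows(
    tibble::tibble(unit_id = character(0), site = integer(0),
                   sample = integer(0), value = numeric(0)),
    purrr::map2_dfr(u$unit_id, u$waveform, function(id, m) {
      tibble::tibble(unit_id = id,
                     site = rep(seq_len(nrow(m)), each = ncol(m)),
                     sample = rep(seq_len(ncol(m)), nrow(m)),
                     value = as.vector(t(m)))
    }))
  units_tab <- tibble::tibble(unit_id = u$unit_id, fs = u$fs)
  readr::write_csv(units_tab, file.path(path, "units.csv"))
  readr::write_csv(spikes, file.path(path, "spikes.csv"))
  readr::write_csv(wf, file.path(path, "waveforms.csv"))
  readr::write_csv(session$behavior, file.path(path, "behavior.csv"))
  readr::write_csv(session$events, file.path(path, "events.csv"))
  readr::write_csv(session$laps, file.path(path, "laps.csv"))
  manifest <- c(session$meta,
                list(n_units = nrow(u), n_events = nrow(session$events),
                     n_laps = nrow(session$laps),
                     n_behavior_samples = nrow(session$behavior)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path Bundle directory written by [write_session()].
#' @return A validated `somipipe_session`.
#' @export
read_session <- function(path) {
  need <- c("units.csv", "spikes.csv", "waveforms.csv", "behavior.csv",
            "events.csv", "laps.csv", "manifest.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    abort(paste("session bundle at", path, "missing table(s):",
                paste(missing, collapse = ", ")))
  }
  ct <- readr::cols(unit_id = readr::col_character(), .default = readr::col_double())
  units_tab <- readr::read_csv(file.path(path, "units.csv"), col_types = ct)
  spikes <- readr::read_csv(file.path(path, "spikes.csv"), col_types = ct)
  wf <- readr::read_csv(file.path(path, "waveforms.csv"), col_types = ct)
  behavior <- readr::read_csv(file.path(path, "behavior.csv"),
                              col_types = readr::cols(.default = readr::col_double()))
  events <- readr::read_csv(file.path(path, "events.csv"),
                            col_types = readr::cols(kind = readr::col_character(),
                                                    .default = readr::col_double()))
  laps <- readr::read_csv(file.path(path, "laps.csv"),
                          col_types = readr::cols(.default = readr::col_double()))
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"), simplifyVector = TRUE)
  units <- tibble::tibble(
    unit_id = units_tab$unit_id,
    spike_times = purrr::map(units_tab$unit_id,
                             ~ spikes$time[spikes$unit_id == .x]),
    waveform = purrr::map(units_tab$unit_id, function(id) {
      w <- wf[wf$unit_id == id, ]
      m <- matrix(NA_real_, nrow = max(w$site), ncol = max(w$sample))
      m[cbind(w$site, w$sample)] <- w$value
      m
    }),
    fs = units_tab$fs)
  meta_keys <- setdiff(names(manifest),
                       c("n_units", "n_events", "n_laps", "n_behavior_samples"))
  new_session(units, behavior, events, laps, meta = manifest[meta_keys])
}
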