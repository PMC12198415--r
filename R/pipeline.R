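#' Run the full analysis pipeline on a session
#'
#' Executes the stages in order: behavior -> unit classification ->
#' optogenetic tagging -> connectivity -> event responses -> encoding model
#' -> decoder. Identical `(config, session)` input yields an identical
#' report. A stage failure aborts with the stage name; the optotag, sensory,
#' encoding and decoding stages are skipped (with a flag) when the session
#' lacks the events they need.
#'
#' @param session A `somipipe_session`.
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `somipipe_report` with one element per stage plus
#'   `performance` and `timings`.
#' @export
run_pipeline <- function(session, config = pipeline_config(), quiet = TRUE) {
  validate_session(session)
  report <- list(skipped = character(0))
  timings <- c()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
    el <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- el
    if (!quiet) message(sprintf("[somipipe] %-12s %6.2f s", name, el))
    out
  }
  rewards <- session$events$time[session$events$kind == "reward"]
  licks <- session$events$time[session$events$kind == "lick"]

  report$behavior <- run_stage("behavior", {
    motion <- segment_motion(session$behavior, config)
    zr <- zone_rates(licks, session$behavior, rewards, session$laps, config)
    perf <- classify_performance(zr, config)
    trend <- if (nrow(zr) >= 5) lick_lap_trend(zr$lick_pre) else NULL
    list(motion = motion, zone_rates = zr, performance = perf,
         score = performance_score(zr), lick_trend = trend)
  })
  report$performance <- report$behavior$performance$performance

  report$units <- run_stage("classify", classify_units(session, config))

  has_light <- any(session$events$kind %in% c("light_dg", "light_fimbria"))
  if (has_light) {
    report$optotag <- run_stage("optotag", optotag_units(session, config))
  } else {
    report$optotag <- NULL
    report$skipped <- c(report$skipped, "optotag")
  }

  report$connectivity <- run_stage("connectivity", {
    pre_ids <- report$units$unit_id[report$units$class == "PC"]
    post_ids <- setdiff(session$units$unit_id, pre_ids)
    if (length(pre_ids) && length(post_ids)) {
      pairs <- tidyr::expand_grid(pre = pre_ids, post = post_ids)
      detect_connections(session, pairs, config)
    } else NULL
  })

  report$event_response <- run_stage("events", {
    transitions <- report$behavior$motion$transitions
    purrr::map_dfr(seq_len(nrow(session$units)), function(i) {
      st <- session$units$spike_times[[i]]
      rm_ <- reward_modulation(st, rewards, config)
      aligned <- align_events(st, rewards, config$align_window_s,
                              config$align_bin_s)
      delay <- if (rm_$classification != "unmodulated") {
        tryCatch(delay_to_max_change(aligned, config),
                 error = function(e) NA_real_)
      } else NA_real_
      oo <- onoff_classify(st, transitions, config)
      sr <- tryCatch(speed_regression(st, session$behavior, config),
                     error = function(e) NULL)
      tibble::tibble(unit_id = session$units$unit_id[i], rm_,
                     delay_s = delay, onoff = oo$label,
                     speed_slope = sr$slope %||% NA_real_,
                     speed_r = sr$r %||% NA_real_)
    })
  })

  stim_kinds <- intersect(unique(session$events$kind),
                          c("random_reward", "stim_visual", "stim_sound",
                            "stim_airpuff"))
  if (length(stim_kinds)) {
    report$sensory <- run_stage("sensory", {
      purrr::map_dfr(seq_len(nrow(session$units)), function(i) {
        dplyr::bind_cols(
          tibble::tibble(unit_id = session$units$unit_id[i]),
          sensory_response(session$units$spike_times[[i]], session$events,
                           stim_kinds, config))
      })
    })
  } else {
    report$skipped <- c(report$skipped, "sensory")
  }

  somi_ids <- if (!is.null(report$optotag)) {
    report$optotag$unit_id[report$optotag$opto == "SOMI"]
  } else character(0)

  if (length(somi_ids)) {
    report$glm <- run_stage("glm", {
      purrr::map(stats::setNames(somi_ids, somi_ids), function(uid) {
        design <- build_design(session, uid, config = config)
        fit <- permutation_test(design, config,
                                seed = stage_seed(config$seed, paste0("glm_", uid)))
        fit$coefficients <- glm_coefficients(design)
        fit
      })
    })
    report$decoder <- run_stage("decode", {
      dur <- max(session$behavior$time)
      trains <- session$units$spike_times[match(somi_ids, session$units$unit_id)]
      rates <- lengths(purrr::map(trains, ~ .x[.x <= dur])) / dur
      keep <- rates > config$min_rate_hz
      trains <- trains[keep]
      ids <- somi_ids[keep]
      if (!length(trains)) return(NULL)
      single <- purrr::map(stats::setNames(seq_along(ids), ids), function(i)
        decode_single(trains[[i]], rewards, config,
                      seed = stage_seed(config$seed, paste0("dec_", ids[i]))))
      pop <- decode_population(trains, rewards, L = 1.5, config = config,
                               seed = stage_seed(config$seed, "decpop"))
      list(single = single, population = pop, unit_ids = ids)
    })
  } else {
    report$skipped <- c(report$skipped, "glm", "decode")
  }

  report$timings <- timings
  report$seed <- config$seed
  class(report) <- "somipipe_report"
  report
}

#' Full-data coefficients of the encoding model
#'
#' @param design A [build_design()] tibble.
#' @return Named coefficient vector (intercept dropped).
#' @export
glm_coefficients <- function(design) {
  X <- cbind(1, as.matrix(design[predictor_cols(design)]))
  fit <- lm.fit(X, design$rate)
  b <- fit$coefficients[-1]
  names(b) <- predictor_cols(design)
  ifelse(is.na(b), 0, b)
}

#' @export
print.somipipe_report <- function(x, ...) {
  cat("<somipipe_report> performance:", x$performance, "\n")
  if (!is.null(x$optotag)) {
    cat("  SOMIs tagged:", sum(x$optotag$opto == "SOMI"), "\n")
  }
  if (length(x$skipped)) cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a pipeline report to JSON + CSV tables
#'
#' @param report A `somipipe_report`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$units, file.path(path, "unit_features.csv"))
  if (!is.null(report$optotag)) {
    readr::write_csv(report$optotag, file.path(path, "optotag.csv"))
  }
  if (!is.null(report$connectivity)) {
    readr::write_csv(report$connectivity, file.path(path, "connections.csv"))
  }
  readr::write_csv(report$event_response, file.path(path, "event_response.csv"))
  summ <- list(performance = report$performance,
               score = report$behavior$score,
               p_lick = report$behavior$performance$p_lick,
               p_speed = report$behavior$performance$p_speed,
               skipped = report$skipped, seed = report$seed)
  jsonlite::write_json(summ, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
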