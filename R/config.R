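#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown keys are
#' rejected so that a typo in a config file cannot silently fall back to a
#' default. Defaults follow the analysis conventions of the recordings this
#' pipeline targets: a 4 m circular track, 2 s pre/post reward zones, a
#' baseline window 4-6 s before reward, and the classification thresholds
#' described in the package vignette.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `somipipe_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, n_perm = 100)
#' cfg$seed
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # behavior
    immobility_thresh = 0.5,      # cm/s
    locomotion_thresh = 3,        # cm/s
    min_immobility_s = 3,
    max_transition_s = 3,
    pre_zone_s = 2,
    post_zone_s = 2,
    baseline_window_s = c(-6, -4),
    alpha = 0.05,
    # unit classification
    ac_bin_ms = 1,
    ac_max_lag_ms = 300,
    bi_threshold = 3,
    ttp_threshold_ms = 0.45,
    kmeans_restarts = 50L,
    # optogenetic tagging
    min_pulses = 20L,
    somi_latency_ms = 5,
    # connectivity
    ccg_bin_ms = 0.5,
    ccg_max_lag_ms = 50,
    ccg_sigma_ms = 10,
    ccg_hollow_fraction = 0.6,
    causal_window_ms = c(1.2, 4),
    poisson_quantile = 0.999,
    # event-aligned responses
    align_window_s = c(-5, 5),
    align_bin_s = 0.1,
    smooth_sigma_bins = 1,
    delay_search_s = c(-2, 2),
    onoff_immobile_s = c(-3, -1),
    onoff_moving_s = c(1, 3),
    min_transitions = 8L,
    min_stim = 15L,
    min_trials = 10L,
    # encoding model
    glm_window_s = c(-3, 3),
    glm_bins = 24L,
    cv_folds = 5L,
    n_perm = 500L,
    perm_quantile = 0.95,
    # decoder
    kde_bandwidth_s = 0.2,
    kde_grid_s = 0.05,
    lik_bin_s = 0.25,
    rate_floor_hz = 0.1,
    expectation_window_s = c(-1.5, 1.5),
    baseline_period_s = c(-4.25, -1.5),
    decode_lengths_s = seq(0.25, 2.75, by = 0.25),
    n_shuffle = 500L,
    shuffle_quantile = 0.99,
    subset_draws = 50L,
    min_rate_hz = 1 / 1.5          # decoder inclusion: >1 spike / 1.5 s
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(over)] <- over
  }
  structure(defaults, class = "somipipe_config")
}

#' Write / read a pipeline configuration
#'
#' Flat YAML key-value serialization with round-trip identity.
#'
#' @param config A `somipipe_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` a config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "somipipe_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  int_keys <- c("seed", "kmeans_restarts", "min_pulses", "min_transitions",
                "min_stim", "min_trials", "glm_bins", "cv_folds", "n_perm",
                "n_shuffle", "subset_draws")
  vals[int_keys] <- lapply(vals[int_keys], as.integer)
  do.call(pipeline_config, vals)
}

#' @export
print.somipipe_config <- function(x, ...) {
  cat("<somipipe_config> with", length(x), "keys; seed =", x$seed, "\n")
  invisible(x)
}
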