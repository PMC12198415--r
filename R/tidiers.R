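#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col geom_hline labs theme_minimal scale_fill_viridis_c
NULL

#' Tidy an encoding-model fit
#'
#' One row per behavioral variable with its importance (EV drop when the
#' variable is permuted).
#'
#' @param x A `glm_fit`.
#' @param ... Unused.
#' @return A tibble with `variable` and `delta_ev`.
#' @export
tidy.glm_fit <- function(x, ...) x$importance

#' One-row summary of an encoding-model fit
#'
#' @param x A `glm_fit`.
#' @param ... Unused.
#' @return A tibble with `ev`, `null_threshold`, `significant`, `n_perm`.
#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(ev = x$ev, null_threshold = x$threshold,
                 significant = x$significant, n_perm = x$n_perm)
}

#' Tidy event-aligned activity into long format
#'
#' @param x An `aligned_activity`.
#' @param ... Unused.
#' @return Tibble with `trial`, `t`, `value`.
#' @export
tidy.aligned_activity <- function(x, ...) {
  tibble::tibble(trial = rep(seq_len(nrow(x$counts)), times = ncol(x$counts)),
                 t = rep(x$centers, each = nrow(x$counts)),
                 value = as.vector(x$counts))
}

#' @export
tidy.decode_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(unclass(x)), character(0))])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot event-aligned activity
#'
#' Trial-averaged peri-event trace with a per-trial heat map.
#'
#' @param object An `aligned_activity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aligned_activity <- function(object, ...) {
  d <- tidy.aligned_activity(object)
  ggplot(d, aes(x = .data$t, y = .data$trial, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = if (object$zscored) "z" else "count") +
    labs(x = "time from event (s)", y = "trial") +
    theme_minimal()
}

#' Plot a decoding-accuracy curve
#'
#' Accuracy versus decoding-window length (single-cell results) or versus
#' the number of cells (population results), with the chance level marked.
#'
#' @param object A `decode_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decode_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  xvar <- if ("L" %in% names(d)) "L" else "n_cells"
  xlab <- if (xvar == "L") "decoding window (s)" else "number of cells"
  ggplot(d, aes(x = .data[[xvar]], y = .data$accuracy)) +
    geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = xlab, y = "accuracy") +
    theme_minimal()
}

#' Plot a cross-correlogram with its hollow-Gaussian baseline
#'
#' @param ccg Output of [cross_correlogram()].
#' @param lambda Optional baseline from [hollow_baseline()].
#' @param config A [pipeline_config()]; marks the causal window.
#' @return A ggplot object.
#' @export
plot_ccg <- function(ccg, lambda = NULL, config = pipeline_config()) {
  d <- tibble::as_tibble(ccg)
  p <- ggplot(d, aes(x = .data$lag_ms, y = .data$count)) +
    geom_col(width = diff(d$lag_ms[1:2]), fill = "grey35") +
    labs(x = "lag (ms)", y = "pair count") +
    theme_minimal()
  if (!is.null(lambda)) {
    d$lambda <- lambda
    p <- p + geom_line(data = d, aes(y = .data$lambda), colour = "red")
  }
  p
}
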