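#' Build the peri-reward encoding-model design
#'
#' For every rewarded trial, bins the window (default -3 to +3 s, 24 bins of
#' 0.25 s) of: unit firing rate (response), lick rate, mean speed,
#' acceleration (first difference of binned speed over the bin width, first
#' bin padded with 0), and a binary reward signal that turns active at the
#' bin containing reward onset. Trials truncated by the recording edge are
#' dropped with a flag.
#'
#' @param session A `somipipe_session`.
#' @param unit_id Unit to model.
#' @param window Length-2 window (s).
#' @param n_bins Number of bins.
#' @param include_reward Include the reward step column.
#' @param config A [pipeline_config()].
#' @return Tibble of class `glm_design` with columns `trial`, `bin`, `t`,
#'   `rate`, `lick`, `speed`, `accel` (+ `reward`); attribute `n_dropped`.
#' @export
build_design <- function(session, unit_id, window = NULL, n_bins = NULL,
                         include_reward = TRUE, config = pipeline_config()) {
  window <- window %||% config$glm_window_s
  n_bins <- n_bins %||% config$glm_bins
  bw <- diff(window) / n_bins
  st <- session$units$spike_times[[match(unit_id, session$units$unit_id)]]
  if (is.null(st)) abort(paste("unknown unit", unit_id))
  rewards <- session$events$time[session$events$kind == "reward"]
  licks <- session$events$time[session$events$kind == "lick"]
  if (length(rewards) < config$min_trials) {
    abort(paste0("only ", length(rewards), " rewarded trials; at least ",
                 config$min_trials, " required"))
  }
  t_lo <- min(session$behavior$time)
  t_hi <- max(session$behavior$time)
  keep <- rewards + window[1] >= t_lo & rewards + window[2] <= t_hi
  n_dropped <- sum(!keep)
  rewards <- rewards[keep]
  sp_fn <- approxfun(session$behavior$time, session$behavior$speed, rule = 2)
  rows <- purrr::map_dfr(seq_along(rewards), function(i) {
    tr <- rewards[i]
    edges <- tr + window[1] + bw * (0:n_bins)
    centers <- edges[-1] - bw / 2
    rate <- bin_counts(st, edges) / bw
    lick <- bin_counts(licks, edges) / bw
    speed <- vapply(seq_len(n_bins), function(b) {
      mean(sp_fn(seq(edges[b], edges[b + 1] - bw / 8, length.out = 5)))
    }, numeric(1))
    accel <- c(0, diff(speed)) / bw
    out <- tibble::tibble(trial = i, bin = seq_len(n_bins),
                          t = centers - tr, rate = rate, lick = lick,
                          speed = speed, accel = accel)
    if (include_reward) {
      out$reward <- as.numeric(centers - tr >= floor((0 - window[1]) / bw) * bw + window[1])
    }
    out
  })
  structure(rows, class = c("glm_design", class(rows)), n_dropped = n_dropped)
}

predictor_cols <- function(design) {
  intersect(c("lick", "speed", "accel", "reward"), names(design))
}

# Pooled held-out explained variance of a linear model, folds split by trial.
# Normal equations with an lm.fit fallback for rank-deficient designs.
cv_ev <- function(y, X, fold) {
  yhat <- numeric(length(y))
  for (f in unique(fold)) {
    test <- fold == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    b <- tryCatch(solve(crossprod(Xtr), crossprod(Xtr, ytr)),
                  error = function(e) {
                    fit <- lm.fit(Xtr, ytr)
                    cf <- fit$coefficients
                    matrix(ifelse(is.na(cf), 0, cf))
                  })
    yhat[test] <- X[test, , drop = FALSE] %*% b
  }
  1 - var(y - yhat) / var(y)
}

#' Cross-validated explained variance of the encoding model
#'
#' Ordinary least squares with intercept in a five-fold cross-validation
#' regime; folds split whole trials so within-trial autocorrelation cannot
#' leak between training and test. EV = 1 - Var(residual)/Var(response),
#' pooled over all held-out rows. Collinear (constant) columns are dropped
#' per fold with a zero coefficient.
#'
#' @param design A [build_design()] tibble.
#' @param k Number of folds.
#' @return Explained variance (scalar, at most 1).
#' @export
fit_cv <- function(design, k = 5) {
  trials <- unique(design$trial)
  if (length(trials) < k) abort("need at least k trials for k-fold CV")
  fold <- ((match(design$trial, trials) - 1) %% k) + 1
  X <- cbind(1, as.matrix(design[predictor_cols(design)]))
  cv_ev(design$rate, X, fold)
}

#' Permutation significance and single-variable importance of the model
#'
#' Each permutation shuffles whole-trial predictor blocks across trials and
#' applies an independent random circular bin shift within every trial
#' (response fixed, 500 iterations): block shuffling and rotation preserve
#' each predictor's within-trial temporal structure while destroying its
#' alignment with the response — including for predictors that are identical
#' on every trial (the reward step), which block shuffling alone cannot
#' disturb. The model is significant when the actual EV exceeds the 95th
#' percentile of the null. Per-variable importance applies the same scheme
#' to only that variable and reports
#' `delta_ev = EV_full - mean(EV_permuted)`.
#'
#' @param design A [build_design()] tibble.
#' @param config A [pipeline_config()] (permutation count, quantile, folds).
#' @param seed Seed for the permutations.
#' @param importance Also compute per-variable importance (default `TRUE`).
#' @return Object of class `glm_fit`: `ev`, `null_ev`, `threshold`,
#'   `significant`, `importance` tibble, `n_perm`.
#' @export
permutation_test <- function(design, config = pipeline_config(), seed = 1L,
                             importance = TRUE) {
  n_perm <- config$n_perm
  if (n_perm < 100) warn("fewer than 100 permutations: unstable null")
  k <- config$cv_folds
  trials <- unique(design$trial)
  nt <- length(trials)
  ord <- order(design$trial, design$bin)
  design <- design[ord, ]
  fold <- ((match(design$trial, trials) - 1) %% k) + 1
  pcols <- predictor_cols(design)
  X <- cbind(1, as.matrix(design[pcols]))
  y <- design$rate
  ev <- cv_ev(y, X, fold)
  nb <- nrow(design) / nt
  row_of_trial <- matrix(seq_len(nrow(design)), nrow = nb)  # col = trial
  perm_ev <- function(perm, shifts, cols_idx) {
    Xp <- X
    rot <- (outer(seq_len(nb) - 1L, shifts, "+") %% nb) + 1L  # nb x nt
    rows_new <- row_of_trial[cbind(as.vector(rot), rep(perm, each = nb))]
    Xp[, cols_idx + 1] <- X[rows_new, cols_idx + 1]
    cv_ev(y, Xp, fold)
  }
  all_idx <- seq_along(pcols)
  res <- with_seed(stage_seed(seed, "glm_perm"), {
    null_ev <- vapply(seq_len(n_perm), function(j)
      perm_ev(sample(nt), sample.int(nb, nt, replace = TRUE) - 1, all_idx),
      numeric(1))
    imp <- if (!importance) NULL else purrr::map_dfr(seq_along(pcols), function(ci) {
      evs <- vapply(seq_len(n_perm), function(j)
        perm_ev(sample(nt), sample.int(nb, nt, replace = TRUE) - 1, ci),
        numeric(1))
      tibble::tibble(variable = pcols[ci], delta_ev = ev - mean(evs))
    })
    list(null_ev = null_ev, imp = imp)
  })
  thr <- unname(quantile(res$null_ev, config$perm_quantile))
  structure(list(ev = ev, null_ev = res$null_ev, threshold = thr,
                 significant = ev > thr, importance = res$imp,
                 n_perm = n_perm),
            class = "glm_fit")
}

#' Anticipatory-window encoding model
#'
#' The same permutation-tested model restricted to the 3 s before reward
#' onset (12 bins) with predictors lick, speed and acceleration only: the
#' reward signal is constant zero there and is not included.
#'
#' @param session,unit_id,config,seed As for [build_design()] /
#'   [permutation_test()].
#' @return A `glm_fit`.
#' @export
anticipatory_variant <- function(session, unit_id,
                                 config = pipeline_config(), seed = 1L) {
  w <- c(config$glm_window_s[1], 0)
  if (diff(w) <= 0) abort("empty anticipatory window")
  design <- build_design(session, unit_id, window = w,
                         n_bins = as.integer(config$glm_bins / 2),
                         include_reward = FALSE, config = config)
  permutation_test(design, config, seed)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> EV =", signif(x$ev, 3), "| null 95th pct =",
      signif(x$threshold, 3), "| significant:", x$significant, "\n")
  invisible(x)
}
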