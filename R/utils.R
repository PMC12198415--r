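#' @importFrom rlang %||% abort warn .data
#' @importFrom stats approx approxfun cor cor.test dnorm lm coef kmeans median
#'   ppois prcomp qpois quantile rnorm rpois runif sd setNames var wilcox.test
#'   lm.fit
#' @importFrom utils head tail
NULL

# Half-open interval membership [a, b)
`%inwin%` <- function(x, w) x >= w[1] & x < w[2]

#' Derive a reproducible child seed for a named pipeline stage
#'
#' All stochastic stages draw from their own stream so that re-running a
#' single stage reproduces its output independently of stage order.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name (e.g. `"synth"`, `"glm"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stream) {
  m <- 2147483629
  h <- 0
  for (c in utf8ToInt(stream)) h <- (h * 131 + c) %% m
  as.integer(((as.numeric(seed) %% m) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  force(seed)  # before snapshotting the RNG state: the seed expression may draw
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Number of sorted spike times in [a, b); vectorized over a/b.
count_in <- function(st, a, b) {
  findInterval(b, st, left.open = TRUE) - findInterval(a, st, left.open = TRUE)
}

# First spike time at or after `a` (NA if none before `b`).
first_after <- function(st, a, b = Inf) {
  i <- findInterval(a, st, left.open = TRUE) + 1L
  if (i > length(st) || st[i] >= b) NA_real_ else st[i]
}

# Counts of x falling in half-open bins [edges[i], edges[i+1])
bin_counts <- function(x, edges) {
  idx <- findInterval(x, edges, left.open = FALSE, rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx <= length(edges) - 1 & x < edges[length(edges)]]
  tabulate(idx, nbins = length(edges) - 1)
}

# Discrete Gaussian smoothing along a vector with edge renormalization.
gauss_smooth <- function(x, sigma_bins = 1) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- dnorm(seq(-half, half), sd = sigma_bins)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- k[j - i + half + 1L]
    out[i] <- sum(x[j] * w) / sum(w)
  }
  out
}

# Paired two-sided Wilcoxon signed-rank with direction from the median
# (falling back to the mean when the median difference is exactly zero).
paired_test <- function(a, b, alpha = 0.05) {
  d <- a - b
  if (length(d) < 2 || all(d == 0)) {
    return(list(p = 1, direction = "none", stat = NA_real_))
  }
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
  md <- median(d)
  if (md == 0) md <- mean(d)
  dir <- if (wt$p.value < alpha) {
    if (md > 0) "increase" else if (md < 0) "decrease" else "none"
  } else "none"
  list(p = unname(wt$p.value), direction = dir, stat = unname(wt$statistic))
}
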