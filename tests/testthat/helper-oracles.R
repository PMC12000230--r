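# Independent oracles used by the unit and acceptance tests.

# Exhaustive sample-by-sample threshold-crossing scan with greedy dead-time
# pruning: a plain stateful loop over every sample, deliberately unlike the
# vectorized implementation.
oracle_spike_scan <- function(x, fs, threshold, dead_time) {
  times <- numeric(0)
  below <- TRUE
  last <- -Inf
  for (i in seq_along(x)) {
    if (below && x[i] >= threshold) {
      t <- (i - 1) / fs
      if (t - last >= dead_time) {
        times <- c(times, t)
        last <- t
      }
      below <- FALSE
    } else if (x[i] < threshold) {
      below <- TRUE
    }
  }
  times
}

# Hand sums-of-squares decomposition for the subject-blocked one-way ANOVA.
oracle_rm_anova_F <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_stage <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_resid <- ss_total - ss_stage - ss_subj
  (ss_stage / (k - 1)) / (ss_resid / ((k - 1) * (n - 1)))
}

# Textbook Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Textbook paired t statistic.
oracle_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Small fast scenarios shared across tests.
quiet_analyze <- function(bundle, config = run_config(), ...) {
  suppressMessages(suppressWarnings(analyze_recording(bundle, config, ...)))
}

tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixtures("tiny", seed = 42)
    cache
  }
})

bench_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixtures("default", seed = 7)
    cache
  }
})
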