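#' Zero-phase bandpass filter for the nerve channel
#'
#' Fourth-order Butterworth bandpass (default 400--1200 Hz, the conventional
#' band for multiunit renal nerve recordings) applied forward and backward
#' (`signal::filtfilt`) so no phase shift is introduced; the DC component is
#' removed by the passband. Requires `fs > 2 * high`; recordings sampled too
#' slowly for the band (e.g. 1 kHz) must be treated as pre-filtered and this
#' step skipped.
#'
#' @param x Numeric vector, sampled nerve signal (a.u.).
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz (defaults 400 and 1200).
#' @param order Butterworth order (default 4).
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass_nerve <- function(x, fs, low = 400, high = 1200, order = 4) {
  stopifnot(is.numeric(x), fs > 0, low > 0, high > low)
  if (fs <= 2 * high)
    stop(sprintf(paste("sampling rate %g Hz is too low for a %g-%g Hz bandpass;",
                       "treat the signal as pre-filtered and skip this step"),
                 fs, low, high))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Median-absolute-deviation threshold for spike discrimination
#'
#' Convenience for the operator-judged "just above background" criterion:
#' `k` times the MAD of the filtered signal (default `k = 4`).
#'
#' @param x Filtered nerve signal.
#' @param k Multiplier (default 4).
#' @return Threshold in signal units.
#' @export
auto_threshold <- function(x, k = 4) {
  stopifnot(k > 0)
  k * stats::mad(x)
}

#' Detect spikes by upward threshold crossing
#'
#' A spike is registered at each sample where the signal first reaches or
#' exceeds `+threshold` from below (positive polarity by default;
#' `polarity = "absolute"` rectifies first). Further crossings within
#' `dead_time` of an accepted spike are suppressed, preventing double counts
#' of biphasic waveforms.
#'
#' @param x Filtered nerve signal.
#' @param fs Sampling rate, Hz.
#' @param threshold Discrimination threshold (> 0, signal units).
#' @param dead_time Refractory time in seconds (default 0.002).
#' @param polarity `"positive"` (default) or `"absolute"`.
#' @param t0 Time of the first sample, s (default 0).
#' @return Object of class `"spike_train"`: list with `times` (s, strictly
#'   increasing), `threshold`, `dead_time`, `n`.
#' @export
detect_spikes <- function(x, fs, threshold, dead_time = 0.002,
                          polarity = c("positive", "absolute"), t0 = 0) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(x), fs > 0, threshold > 0, dead_time >= 0)
  if (polarity == "absolute") x <- abs(x)
  n <- length(x)
  times <- numeric(0)
  if (n >= 2) {
    above <- x >= threshold
    cross <- which(above[-1] & !above[-n]) + 1L
    if (length(cross)) {
      tt <- t0 + (cross - 1) / fs
      keep <- logical(length(tt))
      last <- -Inf
      for (i in seq_along(tt)) {
        if (tt[i] - last >= dead_time) {
          keep[i] <- TRUE
          last <- tt[i]
        }
      }
      times <- tt[keep]
    }
  }
  structure(list(times = times, threshold = threshold,
                 dead_time = dead_time, n = length(times)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes, threshold %.3g, dead time %.3g s\n",
              x$n, x$threshold, x$dead_time))
  invisible(x)
}

#' Raw RSNA rate per beat
#'
#' Counts the spikes whose time falls in each beat's half-open window
#' `[t0, t0 + period)` (the "between diastolic pressures" convention) and
#' divides by the heart period, giving a rate in spikes/s per cardiac cycle.
#' Spikes falling outside every beat are counted nowhere and reported via a
#' message.
#'
#' @param spikes A `"spike_train"` (or numeric vector of spike times, s).
#' @param beats A `"beat_table"` (needs `t0` and `period`).
#' @return The beat table with added integer `n_spikes` and numeric
#'   `rsna_raw` (spikes/s) columns.
#' @export
rsna_per_beat <- function(spikes, beats) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else
    as.numeric(spikes)
  stopifnot(all(c("t0", "period") %in% names(beats)))
  edges <- c(beats$t0, beats$t0[nrow(beats)] + beats$period[nrow(beats)])
  bin <- findInterval(times, edges, left.open = FALSE, rightmost.closed = FALSE)
  inside <- bin >= 1 & bin <= nrow(beats) &
    times < edges[pmin(bin + 1L, length(edges))]
  # beats are contiguous in generated data but may have gaps in general
  idx_in <- which(inside)
  bad <- idx_in[times[idx_in] >= beats$t0[bin[idx_in]] + beats$period[bin[idx_in]]]
  inside[bad] <- FALSE
  n_out <- sum(!inside)
  if (n_out > 0)
    message(n_out, " spike(s) outside all beats; counted nowhere")
  counts <- tabulate(bin[inside], nbins = nrow(beats))
  beats$n_spikes <- counts
  beats$rsna_raw <- counts / beats$period
  beats
}

#' Estimate the background noise floor
#'
#' The baroreflex-independent background rate is taken as the mean raw rate
#' during the highest-dose phenylephrine window, when reflex sympathetic
#' activity is abolished by the induced pressure rise. The returned value is
#' subtracted from all raw rates downstream (clamped at zero).
#'
#' @param beats Beat table with `rsna_raw` (see [rsna_per_beat()]).
#' @param windows Stage windows from [stage_windows()].
#' @param tail_s Use only the final `tail_s` seconds of the top-dose stage
#'   (default 30), so the estimate is taken after the pressure response to
#'   the last dose step has settled.
#' @return Numeric noise floor (spikes/s) with attributes `stage` and
#'   `n_beats`.
#' @export
noise_floor <- function(beats, windows, tail_s = 30) {
  phe <- windows[windows$kind == "phenylephrine_dose", , drop = FALSE]
  if (!nrow(phe))
    stop("no phenylephrine stage annotated; supply a noise floor manually")
  top <- phe[which.max(phe$magnitude), , drop = FALSE]
  w0 <- max(top$start, top$end - tail_s)
  sel <- beats$t0 >= w0 & beats$t0 < top$end
  if (sum(sel) < 5)
    stop("highest-dose phenylephrine window overlaps fewer than 5 beats")
  structure(mean(beats$rsna_raw[sel]),
            stage = top$stage, n_beats = sum(sel))
}

#' Noise-floor-corrected rates
#'
#' @param raw Numeric raw rates (spikes/s).
#' @param floor Noise floor (spikes/s).
#' @return `pmax(raw - floor, 0)`; never negative.
#' @export
correct_rsna <- function(raw, floor) {
  stopifnot(floor >= 0)
  pmax(raw - floor, 0)
}

#' Express corrected RSNA as percent of a baseline window
#'
#' The 100% reference is the mean corrected rate over the baseline window --
#' by convention a 2-min window immediately before the phenylephrine
#' infusion (30 min post-embolization in an infarct protocol, the resting
#' period in controls).
#'
#' @param beats Beat table with `rsna_raw`.
#' @param baseline_window Numeric `c(start, end)`, s.
#' @param floor Noise floor (spikes/s), e.g. from [noise_floor()].
#' @return The beat table with `rsna_corrected` and `rsna_percent` columns,
#'   plus attributes `rsna_baseline` (spikes/s, corrected) and
#'   `noise_floor`. Errors if the window holds fewer than 5 beats or the
#'   baseline mean is zero.
#' @export
percent_of_baseline <- function(beats, baseline_window, floor) {
  stopifnot("rsna_raw" %in% names(beats), length(baseline_window) == 2)
  beats$rsna_corrected <- correct_rsna(beats$rsna_raw, floor)
  sel <- beats$t0 >= baseline_window[1] & beats$t0 < baseline_window[2]
  if (sum(sel) < 5)
    stop("baseline window overlaps fewer than 5 beats")
  ref <- mean(beats$rsna_corrected[sel])
  if (ref <= 0)
    stop("baseline corrected RSNA is zero; percent of baseline undefined")
  beats$rsna_percent <- 100 * beats$rsna_corrected / ref
  attr(beats, "rsna_baseline") <- ref
  attr(beats, "noise_floor") <- as.numeric(floor)
  beats
}
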