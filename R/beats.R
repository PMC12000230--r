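#' Detect cardiac cycles from the arterial pressure waveform
#'
#' Beat boundaries are placed at diastolic troughs: local minima of the
#' pressure series, subject to a refractory period (`min_period`, so the
#' maximum admissible heart rate is `60/min_period` bpm) and a prominence
#' requirement (the systolic maximum before the next trough must exceed the
#' trough by at least `prominence` mmHg). Within a refractory window the
#' deeper trough wins; flat ties resolve to the earliest sample. Sample
#' indices are 1-based, following R convention.
#'
#' @param bp Numeric vector, uniformly sampled arterial pressure (mmHg).
#' @param fs Sampling rate, Hz.
#' @param min_period Minimum beat period in seconds (default 0.3 s, i.e. a
#'   200 bpm ceiling).
#' @param prominence Minimum systolic excursion above the trough, mmHg
#'   (default 5).
#' @return Integer vector of trough sample indices (possibly empty, with a
#'   warning, when no beats are found).
#' @export
detect_beats <- function(bp, fs, min_period = 0.3, prominence = 5) {
  stopifnot(is.numeric(bp), fs > 0, min_period > 0, prominence >= 0)
  n <- length(bp)
  if (n < 3) {
    warning("no diastolic troughs found")
    return(integer(0))
  }
  # candidate local minima; strict drop from the left, non-increase to the
  # right, so the earliest sample of a flat trough is taken
  i <- 2:(n - 1)
  cand <- i[bp[i] < bp[i - 1] & bp[i] <= bp[i + 1]]
  if (!length(cand)) {
    warning("no diastolic troughs found")
    return(integer(0))
  }
  refr <- min_period * fs
  kept <- integer(length(cand))
  m <- 0L
  for (ci in cand) {
    if (m > 0L && ci - kept[m] < refr) {
      if (bp[ci] < bp[kept[m]]) kept[m] <- ci  # deeper trough replaces
    } else {
      m <- m + 1L
      kept[m] <- ci
    }
  }
  kept <- kept[seq_len(m)]
  # prominence: each inter-boundary segment must rise above trough + prominence
  ok <- logical(length(kept))
  for (j in seq_along(kept)) {
    to <- if (j < length(kept)) kept[j + 1L] else n
    ok[j] <- max(bp[kept[j]:to]) >= bp[kept[j]] + prominence
  }
  kept <- kept[ok]
  if (!length(kept)) warning("no diastolic troughs found")
  kept
}

#' Per-beat hemodynamic and renal-flow features
#'
#' Extracts the standard beat-wise features over half-open windows
#' `[trough, next trough)`: SBP (maximum pressure), DBP (pressure at the
#' trough), MAP (time average of the waveform by default), pulse pressure
#' `PP = SBP - DBP`, beat-averaged renal blood flow, flow extrema, renal
#' resistive index `RRI = (max flow - min flow)/max flow`, heart period and
#' rate. Beats shorter than 3 samples are dropped with a message.
#'
#' @param bp,flow Numeric vectors on the same uniform time grid: arterial
#'   pressure (mmHg) and renal flow (ml/min).
#' @param boundaries Trough indices from [detect_beats()].
#' @param fs Sampling rate, Hz.
#' @param map_mode `"waveform"` (time average, default) or `"formula"`
#'   (`DBP + PP/3`).
#' @return A `data.frame` of class `"beat_table"` with one row per beat:
#'   `beat`, `start` (sample index), `t0` (s), `period` (s), `sbp`, `dbp`,
#'   `map`, `pp` (mmHg), `rbf`, `flow_max`, `flow_min` (ml/min), `rri`,
#'   `hr` (bpm).
#' @export
beat_features <- function(bp, flow, boundaries, fs,
                          map_mode = c("waveform", "formula")) {
  map_mode <- match.arg(map_mode)
  stopifnot(length(bp) == length(flow), fs > 0)
  boundaries <- as.integer(boundaries)
  if (length(boundaries) < 2)
    stop("need at least 2 beat boundaries")
  K <- length(boundaries) - 1L
  lens <- diff(boundaries)
  keep <- lens >= 3L
  if (any(!keep))
    message(sum(!keep), " beat(s) shorter than 3 samples dropped")
  rows <- which(keep)
  out <- data.frame(beat = seq_along(rows), start = boundaries[rows],
                    t0 = (boundaries[rows] - 1) / fs,
                    period = lens[rows] / fs,
                    sbp = NA_real_, dbp = NA_real_, map = NA_real_,
                    pp = NA_real_, rbf = NA_real_, flow_max = NA_real_,
                    flow_min = NA_real_, rri = NA_real_, hr = NA_real_)
  for (j in seq_along(rows)) {
    k <- rows[j]
    w <- boundaries[k]:(boundaries[k + 1L] - 1L)
    sb <- max(bp[w]); db <- bp[boundaries[k]]
    fx <- max(flow[w]); fn <- min(flow[w])
    out$sbp[j] <- sb
    out$dbp[j] <- db
    out$pp[j] <- sb - db
    out$map[j] <- if (map_mode == "waveform") mean(bp[w]) else db + (sb - db) / 3
    out$rbf[j] <- mean(flow[w])
    out$flow_max[j] <- fx
    out$flow_min[j] <- fn
    out$rri[j] <- if (fx > 0) (fx - fn) / fx else 0
  }
  out$hr <- 60 / out$period
  class(out) <- c("beat_table", "data.frame")
  out
}

#' Protocol stage windows for averaging
#'
#' Partitions the recording into protocol stages delimited by the annotated
#' events (baseline before the first event; each event opens a stage that
#' closes at the next event or at `duration`) and returns, for each stage,
#' the analysis window: the final `window` seconds of the stage, matching the
#' convention of averaging two minutes of continuous data at the end of each
#' pump-support stage. A stage shorter than `window` yields its full extent
#' with a warning.
#'
#' @param annotations List of [protocol_event()]s (or a data.frame with
#'   `time`, `kind`, `magnitude`).
#' @param duration Total recording duration, s.
#' @param window Window length, s (default 120).
#' @param warn_short Warn when a stage is shorter than `window` (default
#'   `TRUE`); the full stage is used either way.
#' @return A `data.frame` with columns `stage` (label: `baseline`,
#'   `post_embolization`, `phe_<dose>`, `P<level>`), `kind`, `magnitude`,
#'   `start`, `end` (window, s) and `stage_start`, `stage_end`.
#' @export
stage_windows <- function(annotations, duration, window = 120,
                          warn_short = TRUE) {
  ann <- annotations_frame(annotations)
  ann <- ann[order(ann$time), , drop = FALSE]
  starts <- c(0, ann$time)
  ends <- c(ann$time, duration)
  labels <- c("baseline", ifelse(
    ann$kind == "embolization", "post_embolization",
    ifelse(ann$kind == "phenylephrine_dose", paste0("phe_", ann$magnitude),
           paste0("P", ann$magnitude))))
  kinds <- c("baseline", ann$kind)
  mags <- c(NA_real_, ann$magnitude)
  w_start <- pmax(ends - window, starts)
  short <- ends - starts < window
  if (warn_short && any(short))
    warning("stage(s) shorter than the averaging window; using full stage: ",
            paste(labels[short], collapse = ", "))
  data.frame(stage = labels, kind = kinds, magnitude = mags,
             start = w_start, end = ends,
             stage_start = starts, stage_end = ends,
             stringsAsFactors = FALSE)
}

#' Summarize beats over a time interval
#'
#' Unweighted means of the beat-wise features over all beats whose start time
#' lies in the half-open interval `[start, end)`. At least 5 beats are
#' required.
#'
#' @param beat_table A `"beat_table"` (optionally carrying RSNA columns
#'   `rsna_raw`, `rsna_corrected`, `rsna_percent`).
#' @param interval Numeric length-2 `c(start, end)` in seconds.
#' @return One-row `data.frame` with `n_beats` and the means of `map`, `pp`,
#'   `sbp`, `dbp`, `hr`, `rbf`, `rri` and any RSNA columns present.
#' @export
summarize_stage <- function(beat_table, interval) {
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  sel <- beat_table$t0 >= interval[1] & beat_table$t0 < interval[2]
  if (sum(sel) < 5)
    stop(sprintf("interval [%.1f, %.1f) overlaps only %d beats (>= 5 required)",
                 interval[1], interval[2], sum(sel)))
  b <- beat_table[sel, , drop = FALSE]
  out <- data.frame(n_beats = nrow(b), map = mean(b$map), pp = mean(b$pp),
                    sbp = mean(b$sbp), dbp = mean(b$dbp),
                    hr = mean(60 / b$period), rbf = mean(b$rbf),
                    rri = mean(b$rri))
  for (cl in c("rsna_raw", "rsna_corrected", "rsna_percent"))
    if (cl %in% names(b)) out[[cl]] <- mean(b[[cl]])
  out
}

#' Stage summary table with deltas against a reference stage
#'
#' Applies [summarize_stage()] to every window and appends the differences of
#' each variable from a named reference stage (e.g. pump level `"P0"`),
#' mirroring the layout of stage-wise results tables. The RSNA delta is
#' reported as the percent change of the corrected rate relative to the
#' reference stage.
#'
#' @param beat_table A `"beat_table"` with RSNA columns when available.
#' @param windows Output of [stage_windows()].
#' @param reference Stage label to difference against (default `"P0"`;
#'   `NULL` for no deltas).
#' @return `data.frame`, one row per stage, with `d_<var>` delta columns and
#'   `d_rsna_pct` when applicable.
#' @export
stage_summaries <- function(beat_table, windows, reference = "P0") {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    s <- summarize_stage(beat_table, c(windows$start[i], windows$end[i]))
    cbind(stage = windows$stage[i], s)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    if (!reference %in% out$stage)
      stop("reference stage '", reference, "' not present")
    ref <- out[out$stage == reference, , drop = FALSE]
    for (v in c("map", "pp", "sbp", "dbp", "hr", "rbf", "rri"))
      out[[paste0("d_", v)]] <- out[[v]] - ref[[v]]
    if ("rsna_corrected" %in% names(out) && ref$rsna_corrected > 0)
      out$d_rsna_pct <- 100 * (out$rsna_corrected / ref$rsna_corrected - 1)
  }
  rownames(out) <- NULL
  out
}
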