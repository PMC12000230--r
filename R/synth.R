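`%||%` <- function(a, b) if (is.null(a)) b else a

# derived RNG streams so generate/render/counts can be called separately yet
# jointly deterministic for a given scenario seed
.stream_seed <- function(seed, k) as.integer((abs(seed) + k * 104729) %% 2147483647)

#' Generate the per-beat parameter sequence for a scenario
#'
#' Simulates the cardiac-cycle-resolved ground truth of a scenario: one row
#' per beat with its start time, heart period, target systolic/diastolic
#' pressure, renal blood flow, renal resistive index and expected RSNA firing
#' rate. Protocol events set new targets which the state approaches
#' exponentially with time constant `scenario$tau`; inter-beat variability is
#' applied as multiplicative Gaussian jitter per channel. The expected RSNA
#' rate of each beat is
#' `noise_floor + gain * baro_logistic(baro, DBP_beat) * (1 - decoupling)`,
#' evaluated at the beat's realized (jittered) DBP so the generated activity
#' is exactly baroreflex-consistent.
#'
#' Pump-level and phenylephrine targets are referenced to the state captured
#' just before the first phenylephrine dose (the post-embolization plateau in
#' an AMI protocol), so pump level 0 returns the hemodynamics to that
#' reference, as in the experimental protocol.
#'
#' @param scenario A [scenario()] object.
#' @return A `data.frame` of class `"beat_sequence"` with columns `beat`,
#'   `t0`, `period`, `dbp`, `sbp`, `pp`, `rbf`, `rri`, `rate`, `gain`,
#'   `decoupling`, `stage`.
#' @export
generate_beat_sequence <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  base <- list(dbp = sc$baseline$dbp, pp = sc$baseline$sbp - sc$baseline$dbp,
               rbf = sc$baseline$rbf, rri = sc$baseline$rri)

  targ <- c(base, list(gain = 1, decoupling = 0))
  state <- targ
  ramp_ref <- NULL   # captured at first phenylephrine dose
  stage <- "baseline"

  events <- sc$events
  ev_t <- vapply(events, `[[`, numeric(1), "time")
  next_ev <- 1L

  n_guess <- ceiling(sc$duration / (sc$baseline$period * 0.8)) + 10L
  out <- matrix(NA_real_, nrow = n_guess, ncol = 10)
  stages <- character(n_guess)
  clamped <- FALSE

  t0 <- 0
  k <- 0L
  repeat {
    # apply any events that have started
    while (next_ev <= length(events) && ev_t[next_ev] <= t0) {
      e <- events[[next_ev]]
      if (e$kind == "embolization") {
        ddbp <- e$extra$ddbp %||% e$magnitude
        dsbp <- e$extra$dsbp %||% e$magnitude
        pct <- e$extra$rsna_percent %||% 67.5
        old_dbp <- targ$dbp
        old_gain <- targ$gain
        targ$dbp <- base$dbp + ddbp
        targ$pp <- max(base$pp + (dsbp - ddbp), 1)
        targ$rbf <- max(base$rbf + (e$extra$drbf %||% 0), 1)
        targ$rri <- min(max(base$rri + (e$extra$drri %||% 0), 0), 0.98)
        # sympathetic gain reset: meet the target percent change of the
        # noise-corrected rate at the new steady-state pressure
        targ$gain <- (1 + pct / 100) * old_gain *
          baro_logistic(sc$baro, old_dbp) / baro_logistic(sc$baro, targ$dbp)
        stage <- "post_embolization"
      } else if (e$kind == "phenylephrine_dose") {
        if (is.null(ramp_ref)) ramp_ref <- targ
        ddbp <- e$extra$ddbp %||% (sc$dose_slope * e$magnitude)
        targ$dbp <- ramp_ref$dbp + ddbp
        targ$pp <- max(ramp_ref$pp + (e$extra$dpp %||% 0), 1)
        targ$rbf <- max(ramp_ref$rbf + (e$extra$drbf %||% 0), 1)
        targ$rri <- min(max(ramp_ref$rri + (e$extra$drri %||% 0), 0), 0.98)
        stage <- paste0("phe_", e$magnitude)
      } else { # pump_level
        ref <- ramp_ref %||% targ
        if (is.null(ramp_ref)) ramp_ref <- ref
        pe <- sc$pump_effects
        frac <- e$magnitude / pe$max_level
        targ$dbp <- ref$dbp + (e$extra$ddbp %||% (frac * pe$ddbp))
        targ$pp <- max(ref$pp + (e$extra$dpp %||% (frac * pe$dpp)), 1)
        targ$rbf <- max(ref$rbf + (e$extra$drbf %||% (frac * pe$drbf)), 1)
        targ$rri <- min(max(ref$rri + (e$extra$drri %||% (frac * pe$drri)), 0), 0.98)
        targ$decoupling <- e$extra$decoupling %||% (frac * pe$decoupling)
        stage <- paste0("P", e$magnitude)
      }
      next_ev <- next_ev + 1L
    }

    period <- sc$baseline$period * (1 + sc$cv$period * stats::rnorm(1))
    period <- max(period, 0.2)
    if (t0 + period > sc$duration) break

    # exponential approach of the state toward the current targets
    a <- exp(-period / sc$tau)
    for (nm in names(targ)) state[[nm]] <- targ[[nm]] + (state[[nm]] - targ[[nm]]) * a

    dbp <- state$dbp * (1 + sc$cv$dbp * stats::rnorm(1))
    pp <- max(state$pp * (1 + sc$cv$pp * stats::rnorm(1)), 1)
    rbf <- max(state$rbf * (1 + sc$cv$rbf * stats::rnorm(1)), 1)
    rri <- min(max(state$rri * (1 + sc$cv$rri * stats::rnorm(1)), 0), 0.98)
    rate <- sc$noise_floor +
      state$gain * baro_logistic(sc$baro, dbp) * (1 - state$decoupling)
    if (rate < 0) {
      rate <- 0
      clamped <- TRUE
    }

    k <- k + 1L
    out[k, ] <- c(t0, period, dbp, dbp + pp, pp, rbf, rri, rate,
                  state$gain, state$decoupling)
    stages[k] <- stage
    t0 <- t0 + period
  }

  if (clamped) warning("negative RSNA rates clamped to 0")
  bt <- as.data.frame(out[seq_len(k), , drop = FALSE])
  names(bt) <- c("t0", "period", "dbp", "sbp", "pp", "rbf", "rri", "rate",
                 "gain", "decoupling")
  bt <- cbind(beat = seq_len(k), bt, stage = stages[seq_len(k)])
  class(bt) <- c("beat_sequence", "data.frame")
  bt
}

#' Render continuous waveforms from a beat sequence
#'
#' Turns the per-beat targets of [generate_beat_sequence()] into sampled
#' arterial pressure, renal flow and nerve channels. Each beat's pressure
#' rises from the diastolic trough with a quarter-sine systolic upstroke to
#' the target SBP and decays exponentially toward the next beat's DBP; the
#' flow waveform is scaled so its within-beat maximum and minimum realize the
#' beat's target resistive index exactly and its time average equals the
#' target renal blood flow. The nerve channel is the sum of stereotyped
#' biphasic spike templates at spike times drawn from an inhomogeneous
#' Poisson process (piecewise-constant rate per beat) plus Gaussian
#' background noise.
#'
#' @param beat_table Output of [generate_beat_sequence()].
#' @param scenario The [scenario()] the table was generated from.
#' @return An object of class `"signal_bundle"`: a list with `time`, `bp`,
#'   `flow`, `nerve` (equal-length numeric vectors), `fs`, `annotations`
#'   (the scenario events), and a `truth` record holding the per-beat table
#'   (with rendered MAP, flow extrema and spike counts) and the exact spike
#'   times.
#' @export
render_waveforms <- function(beat_table, scenario) {
  stopifnot(inherits(beat_table, "data.frame"), inherits(scenario, "scenario"))
  fs <- scenario$fs
  if (fs * scenario$noise$spike_width < 2)
    stop("sampling rate too low to render spikes; need fs * spike_width >= 2")
  set.seed(.stream_seed(scenario$seed, 1L))

  bt <- beat_table
  K <- nrow(bt)
  bounds <- round(bt$t0 * fs) + 1L
  bounds <- c(bounds, round((bt$t0[K] + bt$period[K]) * fs) + 1L)
  N <- bounds[K + 1L] - 1L

  bp <- numeric(N)
  flow <- numeric(N)
  map <- numeric(K)
  fmax <- numeric(K)
  fmin <- numeric(K)
  nsp <- integer(K)
  spike_times <- vector("list", K)

  for (k in seq_len(K)) {
    s0 <- bounds[k]; s1 <- bounds[k + 1L]
    n <- s1 - s0
    ip <- min(max(2L, round(0.3 * n)), n - 2L)
    i <- seq_len(n) - 1L
    up <- i <= ip
    shape_bp <- numeric(n)
    shape_fl <- numeric(n)
    shape_bp[up] <- sin(pi / 2 * i[up] / ip)
    shape_fl[up] <- shape_bp[up]
    shape_bp[!up] <- exp(-(i[!up] - ip) / (0.2 * n))
    shape_fl[!up] <- exp(-(i[!up] - ip) / (0.15 * n))

    dbp_next <- if (k < K) bt$dbp[k + 1L] else bt$dbp[k]
    seg <- numeric(n)
    seg[up] <- bt$dbp[k] + (bt$sbp[k] - bt$dbp[k]) * shape_bp[up]
    seg[!up] <- dbp_next + (bt$sbp[k] - dbp_next) * shape_bp[!up]
    bp[s0:(s1 - 1L)] <- seg
    map[k] <- mean(seg)

    m <- mean(shape_fl)
    fx <- bt$rbf[k] / (1 - bt$rri[k] * (1 - m))
    fn <- fx * (1 - bt$rri[k])
    flow[s0:(s1 - 1L)] <- fn + (fx - fn) * shape_fl
    fmax[k] <- fx; fmin[k] <- fn

    lam <- bt$rate[k] * bt$period[k]
    nk <- stats::rpois(1, lam)
    nsp[k] <- nk
    if (nk > 0)
      spike_times[[k]] <- sort(bt$t0[k] + stats::runif(nk, 0, bt$period[k]))
  }

  spikes <- unlist(spike_times) %||% numeric(0)
  if (is.null(spikes)) spikes <- numeric(0)

  L <- max(2L, min(3L, round(scenario$noise$spike_width * fs)))
  template <- scenario$noise$spike_amp * c(1, -0.6, 0.15)[seq_len(L)]
  nerve <- stats::rnorm(N, 0, scenario$noise$sd)
  if (length(spikes)) {
    idx <- pmin(floor(spikes * fs) + 1L, N - L + 1L)
    for (o in seq_len(L))
      nerve <- nerve + template[o] * tabulate(idx + o - 1L, nbins = N)
  }

  bt$map <- map
  bt$flow_max <- fmax
  bt$flow_min <- fmin
  bt$n_spikes <- nsp

  structure(list(time = (seq_len(N) - 1) / fs,
                 bp = bp, flow = flow, nerve = nerve, fs = fs,
                 annotations = scenario$events,
                 truth = list(beats = bt, spikes = spikes),
                 level = "waveform",
                 seed = scenario$seed),
            class = "signal_bundle")
}

#' Draw per-beat spike counts without rendering waveforms
#'
#' Fast beat-level counterpart of [render_waveforms()]: draws the Poisson
#' spike count of each beat directly from its expected rate, skipping the
#' continuous channels. Useful for simulation studies where only beat-wise
#' quantities are analyzed.
#'
#' @inheritParams render_waveforms
#' @return A `"signal_bundle"` with `level = "beats"`: no continuous
#'   channels, but a truth record whose beat table carries `n_spikes` and a
#'   formulaic MAP (`dbp + pp/3`).
#' @export
simulate_beat_counts <- function(beat_table, scenario) {
  stopifnot(inherits(beat_table, "data.frame"), inherits(scenario, "scenario"))
  set.seed(.stream_seed(scenario$seed, 2L))
  bt <- beat_table
  bt$n_spikes <- stats::rpois(nrow(bt), bt$rate * bt$period)
  bt$map <- bt$dbp + bt$pp / 3
  bt$flow_max <- bt$rbf / (1 - bt$rri * 0.5)
  bt$flow_min <- bt$flow_max * (1 - bt$rri)
  structure(list(time = NULL, bp = NULL, flow = NULL, nerve = NULL,
                 fs = scenario$fs,
                 annotations = scenario$events,
                 truth = list(beats = bt, spikes = NULL),
                 level = "beats",
                 seed = scenario$seed),
            class = "signal_bundle")
}

#' Simulate a complete synthetic recording
#'
#' Convenience wrapper: [generate_beat_sequence()] followed by
#' [render_waveforms()] (`level = "waveform"`) or [simulate_beat_counts()]
#' (`level = "beats"`). The scenario seed fully determines the result.
#'
#' @param scenario A [scenario()] object.
#' @param level `"waveform"` for full sampled channels, `"beats"` for the
#'   fast beat-level simulation.
#' @return A `"signal_bundle"`.
#' @export
#' @examples
#' sc <- study_protocol("control", seed = 3, baseline_s = 10, dose_s = 6,
#'                      stage_s = 10, levels = c(0, 6), tau = 2)
#' b <- simulate_recording(sc, level = "beats")
#' head(b$truth$beats)
simulate_recording <- function(scenario, level = c("waveform", "beats")) {
  level <- match.arg(level)
  bt <- generate_beat_sequence(scenario)
  if (level == "waveform") render_waveforms(bt, scenario)
  else simulate_beat_counts(bt, scenario)
}

#' @export
print.signal_bundle <- function(x, ...) {
  nb <- nrow(x$truth$beats)
  if (identical(x$level, "waveform")) {
    cat(sprintf("Synthetic recording: %.1f s at %g Hz, %d beats, %d spikes\n",
                length(x$bp) / x$fs, x$fs, nb, length(x$truth$spikes)))
  } else {
    cat(sprintf("Synthetic recording (beat level): %d beats, %d spikes\n",
                nb, sum(x$truth$beats$n_spikes)))
  }
  invisible(x)
}
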