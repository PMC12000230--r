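#' Protocol event
#'
#' A timed intervention in a synthetic recording scenario. Three kinds are
#' supported, mirroring the experimental protocol of an acute myocardial
#' infarction (AMI) / mechanical circulatory support study:
#'
#' * `"embolization"`: coronary microsphere embolization. `magnitude` is the
#'   target mean arterial pressure change in mmHg (negative). Optional
#'   `extra` overrides: `ddbp`, `dsbp` (target DBP/SBP changes, mmHg; default
#'   both equal to `magnitude`), `drbf` (ml/min), `drri` (resistive-index
#'   change), `rsna_percent` (target percent change of noise-corrected RSNA
#'   at the new steady state, default +67.5).
#' * `"pump_level"`: transvalvular pump support level. `magnitude` is the
#'   integer level 0..8. Hemodynamic effects scale linearly with
#'   level/max_level using the scenario's `pump_effects`; `extra` may
#'   override `ddbp`, `dpp`, `drbf`, `drri`, `decoupling` for this event.
#' * `"phenylephrine_dose"`: vasoconstrictor infusion step. `magnitude` is
#'   the pump rate in ml/hr; the induced DBP rise is
#'   `dose_slope * magnitude` (see [scenario()]). `extra` may override
#'   `ddbp`, `dpp`, `drbf`, `drri`.
#'
#' @param time Event time in seconds (>= 0).
#' @param kind One of `"embolization"`, `"pump_level"`,
#'   `"phenylephrine_dose"`.
#' @param magnitude Kind-specific magnitude (see Details).
#' @param extra Named list of kind-specific effect overrides.
#' @return An object of class `"protocol_event"`.
#' @export
protocol_event <- function(time,
                           kind = c("embolization", "pump_level",
                                    "phenylephrine_dose"),
                           magnitude, extra = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time), length(time) == 1L, time >= 0,
            is.numeric(magnitude), length(magnitude) == 1L,
            is.list(extra))
  if (kind == "pump_level") {
    if (magnitude != round(magnitude) || magnitude < 0 || magnitude > 8)
      stop("pump level must be an integer in 0..8")
    magnitude <- as.integer(magnitude)
  }
  if (kind == "phenylephrine_dose" && magnitude <= 0)
    stop("phenylephrine dose must be > 0 ml/hr")
  structure(list(time = time, kind = kind, magnitude = magnitude,
                 extra = extra),
            class = "protocol_event")
}

#' Synthetic recording scenario
#'
#' Full configuration of a synthetic multichannel recording: per-beat baseline
#' hemodynamics, the baroreflex curve driving renal sympathetic nerve activity
#' (RSNA), the noise model, the ordered protocol events and the seed. A
#' scenario (including its seed) fully determines the generated recording.
#'
#' The generator models RSNA as
#' `rate = noise_floor + gain * baro_logistic(baro, DBP) * (1 - decoupling)`,
#' where `gain` is a sympathetic activation factor (reset by embolization to
#' meet its target percent change) and `decoupling` is the pump-level-dependent
#' fraction of baroreflex-driven activity suppressed beyond what the pressure
#' change itself predicts.
#'
#' If `baro` is omitted, a curve is constructed with `bp50` placed
#' `bp50_offset` mmHg above the ramp-reference DBP (the post-embolization DBP
#' if an embolization event is present, else the baseline DBP), `bottom = 0`,
#' and `top` scaled so the baseline noise-corrected rate matches
#' `baseline$rsna - noise_floor`.
#'
#' @param fs Sampling rate in Hz (default 1000; nerve spikes are 2--3 ms
#'   biphasic templates so 1 kHz is the floor, 2 kHz available).
#' @param duration Total recording duration in seconds.
#' @param baseline Named list of per-beat means: `dbp`, `sbp` (mmHg), `rbf`
#'   (ml/min), `rri` (dimensionless in \[0, 1)), `period` (s), `rsna`
#'   (raw baseline rate, spikes/s).
#' @param baro Optional [baro_params()] in spikes/s vs absolute DBP.
#' @param bp50_offset mmHg above the ramp-reference DBP at which the default
#'   curve is centred (default 25).
#' @param slope_width Logistic width of the default curve (mmHg, default 1.5).
#' @param noise_floor Baroreflex-independent background rate, spikes/s
#'   (default 2).
#' @param tau Time constant of the exponential approach to new targets after
#'   each event, seconds (default 10).
#' @param dose_slope DBP rise per unit phenylephrine dose, mmHg/(ml/hr)
#'   (default 0.085).
#' @param pump_effects Named list with the hemodynamic effects of full pump
#'   support: `max_level`, `ddbp`, `dpp` (mmHg), `drbf` (ml/min), `drri`,
#'   `decoupling` (fraction at `max_level`). Effects scale linearly with
#'   level/max_level.
#' @param cv Named list of inter-beat coefficients of variation: `dbp`, `pp`,
#'   `rbf`, `rri`, `period`.
#' @param noise Named list for the nerve channel: `sd` (Gaussian background,
#'   a.u.), `spike_amp` (template peak, a.u.), `spike_width` (s).
#' @param events List of [protocol_event()]s, strictly increasing in time.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `"scenario"`.
#' @seealso [study_protocol()] for ready-made study scenarios,
#'   [simulate_recording()] to run the generator.
#' @export
scenario <- function(fs = 1000,
                     duration = 60,
                     baseline = list(dbp = 78.08, sbp = 104.10, rbf = 239.56,
                                     rri = 0.72, period = 60 / 91.35,
                                     rsna = 16),
                     baro = NULL,
                     bp50_offset = 25,
                     slope_width = 1.5,
                     noise_floor = 2,
                     tau = 10,
                     dose_slope = 0.085,
                     pump_effects = list(max_level = 8, ddbp = 19.64,
                                         dpp = -10.51, drbf = 32.57,
                                         drri = -0.27, decoupling = 0.2),
                     cv = list(dbp = 0.015, pp = 0.03, rbf = 0.03,
                               rri = 0.015, period = 0.02),
                     noise = list(sd = 1, spike_amp = 10, spike_width = 0.002),
                     events = list(),
                     seed = 1L) {
  stopifnot(fs > 0, duration > 0, noise_floor >= 0, tau > 0)
  need <- c("dbp", "sbp", "rbf", "rri", "period", "rsna")
  if (!all(need %in% names(baseline)))
    stop("baseline must contain: ", paste(need, collapse = ", "))
  if (baseline$sbp <= baseline$dbp) stop("baseline SBP must exceed DBP")
  if (baseline$rri < 0 || baseline$rri >= 1)
    stop("baseline RRI must be in [0, 1)")
  if (any(unlist(baseline[c("rbf", "period", "rsna")]) <= 0))
    stop("baseline rbf, period and rsna must be > 0")
  if (baseline$rsna < noise_floor)
    stop("baseline rsna must be >= noise_floor")
  if (fs * noise$spike_width < 2)
    stop("sampling rate too low to render spikes; need fs * spike_width >= 2")

  events <- lapply(events, function(e) {
    if (!inherits(e, "protocol_event")) stop("events must be protocol_event objects")
    e
  })
  if (length(events) > 1L) {
    tt <- vapply(events, `[[`, numeric(1), "time")
    if (any(diff(tt) <= 0))
      stop("events must be strictly increasing in time (overlapping events rejected)")
  }
  if (length(events) &&
      max(vapply(events, `[[`, numeric(1), "time")) >= duration)
    stop("all events must occur before 'duration'")

  if (is.null(baro)) {
    # anchor bp50 to the DBP from which the phenylephrine ramp departs
    ramp_dbp <- baseline$dbp
    for (e in events) {
      if (e$kind == "embolization") {
        dd <- if (!is.null(e$extra$ddbp)) e$extra$ddbp else e$magnitude
        ramp_dbp <- baseline$dbp + dd
      }
    }
    bp50 <- ramp_dbp + bp50_offset
    frac0 <- 1 / (1 + exp((baseline$dbp - bp50) / slope_width))
    top <- (baseline$rsna - noise_floor) / frac0
    baro <- baro_params(top = top, bottom = 0, bp50 = bp50,
                        slope_width = slope_width)
  }
  stopifnot(inherits(baro, "baro_params"))

  structure(list(fs = fs, duration = duration, baseline = baseline,
                 baro = baro, noise_floor = noise_floor, tau = tau,
                 dose_slope = dose_slope, pump_effects = pump_effects,
                 cv = cv, noise = noise, events = events,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Synthetic recording scenario: %.0f s at %g Hz, %d events, seed %d\n",
              x$duration, x$fs, length(x$events), x$seed))
  cat(sprintf("  baseline: DBP %.1f / SBP %.1f mmHg, RBF %.0f ml/min, RRI %.2f, HR %.0f bpm, RSNA %.1f spikes/s\n",
              x$baseline$dbp, x$baseline$sbp, x$baseline$rbf, x$baseline$rri,
              60 / x$baseline$period, x$baseline$rsna))
  for (e in x$events)
    cat(sprintf("  t=%7.1f s  %-18s magnitude %.4g\n", e$time, e$kind, e$magnitude))
  invisible(x)
}

#' Ready-made study scenario for one synthetic subject
#'
#' Builds a full-protocol [scenario()] for one subject of the AMI or control
#' group: a resting baseline; for AMI, coronary embolization followed by an
#' observation period; a graded phenylephrine ramp (doses 50, 100, 200, 300,
#' 400 ml/hr at `dose_s` intervals) to trace the baroreflex curve and abolish
#' RSNA at the top dose; then incremental pump support stages (levels 0..8 for
#' AMI, 0..6 for controls by default). Baseline hemodynamics and stage effect
#' sizes default to the magnitudes observed in instrumented sheep (DBP/SBP
#' around 78/104 mmHg pre-infarct, embolization dropping MAP by ~19 mmHg and
#' raising noise-corrected RSNA by ~67%, full AMI pump support raising DBP by
#' ~20 mmHg while cutting pulse pressure by ~10 mmHg).
#'
#' Mild subject-level variation (`subject_cv`, default 5% on baseline values)
#' is drawn deterministically from `seed`, so two calls with the same
#' arguments give identical scenarios.
#'
#' @param group `"ami"` or `"control"`.
#' @param seed Integer seed for subject-level variation and the generator.
#' @param baseline_s Pre-intervention baseline duration, s (default 1800).
#' @param post_embolization_s Observation time between embolization and the
#'   phenylephrine ramp, s (AMI only; default 1800).
#' @param dose_s Duration of each phenylephrine dose step, s (default 60).
#' @param stage_s Duration of each pump-support stage, s (default 180).
#' @param levels Integer vector of pump levels to visit in order (default
#'   0:8 for AMI, 0:6 for controls).
#' @param decoupling Fraction of baroreflex-driven RSNA suppressed at full
#'   pump support beyond the pressure-predicted change (default 0.2 for AMI,
#'   0 for controls).
#' @param subject_cv Coefficient of variation for subject-level jitter of
#'   baseline values (default 0.05).
#' @param effect_cv Coefficient of variation for subject-level jitter of
#'   intervention effect sizes (embolization response, pump-stage deltas,
#'   decoupling; default 0.15), giving realistic between-animal spread of
#'   the stage deltas.
#' @param fs Sampling rate, Hz.
#' @param ... Further arguments passed to [scenario()].
#' @return A [scenario()] object.
#' @export
#' @examples
#' sc <- study_protocol("control", seed = 7, baseline_s = 20,
#'                      dose_s = 10, stage_s = 20, levels = c(0, 6))
#' print(sc)
study_protocol <- function(group = c("ami", "control"),
                           seed = 1L,
                           baseline_s = 1800,
                           post_embolization_s = 1800,
                           dose_s = 60,
                           stage_s = 180,
                           levels = NULL,
                           decoupling = NULL,
                           subject_cv = 0.05,
                           effect_cv = 0.15,
                           fs = 1000,
                           ...) {
  group <- match.arg(group)
  seed <- as.integer(seed)
  ami <- group == "ami"
  if (is.null(levels)) levels <- if (ami) 0:8 else 0:6
  if (is.null(decoupling)) decoupling <- if (ami) 0.2 else 0

  base <- if (ami) {
    list(dbp = 78.08, sbp = 104.10, rbf = 239.56, rri = 0.72,
         period = 60 / 91.35, rsna = 16)
  } else {
    list(dbp = 83.53, sbp = 109.34, rbf = 191.88, rri = 0.51,
         period = 60 / 99.13, rsna = 16)
  }
  pe <- if (ami) {
    list(max_level = 8, ddbp = 19.64, dpp = -10.51, drbf = 32.57,
         drri = -0.27, decoupling = decoupling)
  } else {
    # control effects reach their Table-like magnitudes at level 6
    list(max_level = 6, ddbp = 15.96, dpp = -9.86, drbf = 16.26,
         drri = -0.15, decoupling = decoupling)
  }

  emb <- list(magnitude = -19.1, ddbp = -16.78, dsbp = -20.77,
              drbf = -65.2, drri = 0.40, rsna_percent = 67.5)
  if (subject_cv > 0 || effect_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed((seed * 2654435761) %% 2147483647)
    z <- stats::rnorm(6, 0, subject_cv)
    pp0 <- (base$sbp - base$dbp) * (1 + z[2])
    base$dbp <- base$dbp * (1 + z[1])
    base$sbp <- base$dbp + max(pp0, 5)
    base$rbf <- base$rbf * (1 + z[3])
    base$rri <- min(max(base$rri * (1 + z[4]), 0.05), 0.95)
    base$period <- base$period * (1 + z[5])
    base$rsna <- max(base$rsna * (1 + z[6]), 4)
    u <- stats::rnorm(8, 0, effect_cv)
    for (j in seq_along(emb)) emb[[j]] <- emb[[j]] * (1 + u[1])
    emb$rsna_percent <- 67.5 * (1 + u[2])
    pe$ddbp <- pe$ddbp * (1 + u[3])
    pe$dpp <- pe$dpp * (1 + u[4])
    pe$drbf <- pe$drbf * (1 + u[5])
    pe$drri <- pe$drri * (1 + u[6])
    pe$decoupling <- max(pe$decoupling * (1 + u[7]), 0)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }

  events <- list()
  t <- baseline_s
  if (ami) {
    events <- c(events, list(protocol_event(
      time = t, kind = "embolization", magnitude = emb$magnitude,
      extra = emb[c("ddbp", "dsbp", "drbf", "drri", "rsna_percent")])))
    t <- t + post_embolization_s
  }
  for (dose in c(50, 100, 200, 300, 400)) {
    events <- c(events, list(protocol_event(
      time = t, kind = "phenylephrine_dose", magnitude = dose)))
    t <- t + dose_s
  }
  for (lv in levels) {
    events <- c(events, list(protocol_event(
      time = t, kind = "pump_level", magnitude = lv)))
    t <- t + stage_s
  }

  scenario(fs = fs, duration = t, baseline = base, pump_effects = pe,
           events = events, seed = seed, ...)
}
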