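#' Write a signal bundle as delimited text
#'
#' Writes `signals.csv` (`time,bp,flow,nerve`, one row per sample),
#' `annotations.csv` (`time,kind,magnitude`) and, when ground truth is
#' present, `truth_beats.csv` and `truth_spikes.csv` sidecars.
#'
#' @param bundle A `"signal_bundle"` (see [simulate_recording()]).
#' @param dir Output directory; created if missing.
#' @return Invisibly, the paths written.
#' @export
write_signal_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "signal_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (identical(bundle$level, "waveform")) {
    p <- file.path(dir, "signals.csv")
    utils::write.csv(data.frame(time = bundle$time, bp = bundle$bp,
                                flow = bundle$flow, nerve = bundle$nerve),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  ann <- annotations_frame(bundle$annotations)
  p <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(bundle$truth)) {
    p <- file.path(dir, "truth_beats.csv")
    utils::write.csv(bundle$truth$beats, p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(bundle$truth$spikes)) {
      p <- file.path(dir, "truth_spikes.csv")
      utils::write.csv(data.frame(time = bundle$truth$spikes), p,
                       row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

annotations_frame <- function(events) {
  if (inherits(events, "data.frame")) return(events)
  data.frame(time = vapply(events, `[[`, numeric(1), "time"),
             kind = vapply(events, `[[`, character(1), "kind"),
             magnitude = vapply(events, function(e) as.numeric(e$magnitude),
                                numeric(1)))
}

events_from_frame <- function(ann) {
  lapply(seq_len(nrow(ann)), function(i)
    protocol_event(ann$time[i], ann$kind[i], ann$magnitude[i]))
}

#' Read a signal bundle written by [write_signal_bundle()]
#'
#' @param dir Directory containing `signals.csv` and `annotations.csv`.
#' @return A `"signal_bundle"`. The sampling rate is inferred from the time
#'   column; truth sidecars are loaded when present.
#' @export
read_signal_bundle <- function(dir) {
  sp <- file.path(dir, "signals.csv")
  ann <- utils::read.csv(file.path(dir, "annotations.csv"))
  truth <- NULL
  tb <- file.path(dir, "truth_beats.csv")
  if (file.exists(tb)) {
    truth <- list(beats = utils::read.csv(tb), spikes = NULL)
    ts <- file.path(dir, "truth_spikes.csv")
    if (file.exists(ts)) truth$spikes <- utils::read.csv(ts)$time
  }
  if (file.exists(sp)) {
    sig <- utils::read.csv(sp)
    dt <- diff(sig$time)
    if (max(abs(dt - dt[1])) > dt[1] * 1e-6)
      stop("non-uniform sampling in signals.csv")
    structure(list(time = sig$time, bp = sig$bp, flow = sig$flow,
                   nerve = sig$nerve, fs = 1 / dt[1],
                   annotations = events_from_frame(ann),
                   truth = truth, level = "waveform", seed = NA_integer_),
              class = "signal_bundle")
  } else {
    structure(list(time = NULL, bp = NULL, flow = NULL, nerve = NULL,
                   fs = NA_real_, annotations = events_from_frame(ann),
                   truth = truth, level = "beats", seed = NA_integer_),
              class = "signal_bundle")
  }
}

#' Write / read a scenario as a YAML config
#'
#' Human-readable round-trip of a [scenario()]; events are stored as a list
#' of `time`/`kind`/`magnitude`/`extra` entries.
#'
#' @param sc A [scenario()].
#' @param path File path (`.yaml`).
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns the reconstructed [scenario()].
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  x <- unclass(sc)
  x$baro <- unclass(x$baro)
  x$events <- lapply(x$events, unclass)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  scenario(fs = x$fs, duration = x$duration, baseline = x$baseline,
           baro = do.call(baro_params, x$baro),
           noise_floor = x$noise_floor, tau = x$tau,
           dose_slope = x$dose_slope, pump_effects = x$pump_effects,
           cv = x$cv, noise = x$noise,
           events = lapply(x$events, function(e)
             protocol_event(e$time, e$kind, e$magnitude,
                            e$extra %||% list())),
           seed = x$seed)
}
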