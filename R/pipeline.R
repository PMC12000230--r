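#' Analysis configuration
#'
#' All tunable parameters of the analysis pipeline with their documented
#' defaults. The configuration round-trips losslessly through its YAML form
#' ([write_config()]/[read_config()]) and is hashed into every report row by
#' [config_hash()].
#'
#' @param threshold Spike discrimination threshold in signal units; `NULL`
#'   (default) selects `threshold_k` x MAD automatically
#'   ([auto_threshold()]).
#' @param threshold_k MAD multiplier for the automatic threshold (default 4).
#' @param dead_time Spike refractory time, s (default 0.002).
#' @param min_period Minimum beat period for trough detection, s (default
#'   0.3).
#' @param prominence Minimum systolic excursion for a valid beat, mmHg
#'   (default 5).
#' @param window Stage averaging window, s (default 120).
#' @param bin_width Baroreflex bin width, mmHg (default 2).
#' @param settle_s Beats within this time after each phenylephrine dose step
#'   are excluded from the curve (default 10 s).
#' @param map_mode MAP definition, `"waveform"` or `"formula"`.
#' @param bandpass Nerve filter band, Hz (default `c(400, 1200)`); applied
#'   only when the sampling rate supports it, otherwise the channel is
#'   treated as pre-filtered.
#' @param predict_mode `"fit"` or `"bins"` (see [predict_rsna_change()]).
#' @param correction Post-hoc multiplicity correction (default `"holm"`).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(threshold = NULL, threshold_k = 4, dead_time = 0.002,
                       min_period = 0.3, prominence = 5, window = 120,
                       bin_width = 2, settle_s = 10,
                       map_mode = "waveform", bandpass = c(400, 1200),
                       predict_mode = "fit", correction = "holm") {
  structure(list(threshold = threshold, threshold_k = threshold_k,
                 dead_time = dead_time, min_period = min_period,
                 prominence = prominence, window = window,
                 bin_width = bin_width, settle_s = settle_s,
                 map_mode = map_mode, bandpass = bandpass,
                 predict_mode = predict_mode, correction = correction),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `"run_config"` (or any list).
#' @param path File path for the YAML form.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @rdname run_config
#' @return `config_hash()` returns the MD5 hash (character) of the canonical
#'   YAML serialization; any parameter change changes the hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis on one recording
#'
#' End-to-end single-subject analysis: beat detection and feature extraction
#' from the pressure and flow channels (or the truth beat table for
#' beat-level bundles), nerve filtering (when the sampling rate supports the
#' band) and threshold-crossing spike detection, per-beat RSNA rates,
#' noise-floor estimation from the highest phenylephrine dose, percent of
#' baseline (window ending at ramp onset), stage summaries with deltas vs
#' pump level 0, the baroreflex curve from the ramp, and the
#' predicted-vs-observed RSNA change at the highest pump level.
#'
#' @param bundle A `"signal_bundle"` ([simulate_recording()],
#'   [read_signal_bundle()]).
#' @param config A [run_config()].
#' @param verbose Emit one progress line (default `FALSE`).
#' @return List of class `"rsna_analysis"`: `beats` (annotated beat table),
#'   `windows`, `floor`, `summaries`, `curve` ([baro_curve()]),
#'   `observed` / `predicted` (% change at the top pump level),
#'   `delta_dbp` (pressure rise P0 to top level), `top_stage`, `config`.
#' @export
analyze_recording <- function(bundle, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(bundle, "signal_bundle"))
  cfg <- config

  if (identical(bundle$level, "waveform")) {
    fs <- bundle$fs
    duration <- length(bundle$bp) / fs
    bounds <- detect_beats(bundle$bp, fs, cfg$min_period, cfg$prominence)
    bt <- beat_features(bundle$bp, bundle$flow, bounds, fs,
                        map_mode = cfg$map_mode)
    nerve <- if (fs > 2 * cfg$bandpass[2])
      bandpass_nerve(bundle$nerve, fs, cfg$bandpass[1], cfg$bandpass[2])
    else bundle$nerve
    thr <- cfg$threshold %||% auto_threshold(nerve, cfg$threshold_k)
    spikes <- detect_spikes(nerve, fs, thr, cfg$dead_time)
    bt <- rsna_per_beat(spikes, bt)
  } else {
    tb <- bundle$truth$beats
    duration <- tb$t0[nrow(tb)] + tb$period[nrow(tb)]
    bt <- data.frame(beat = seq_len(nrow(tb)), start = NA_integer_,
                     t0 = tb$t0, period = tb$period, sbp = tb$sbp,
                     dbp = tb$dbp, map = tb$map, pp = tb$pp, rbf = tb$rbf,
                     flow_max = tb$flow_max, flow_min = tb$flow_min,
                     rri = tb$rri, hr = 60 / tb$period)
    class(bt) <- c("beat_table", "data.frame")
    bt$n_spikes <- tb$n_spikes
    bt$rsna_raw <- tb$n_spikes / tb$period
  }

  windows <- stage_windows(bundle$annotations, duration, cfg$window,
                           warn_short = FALSE)
  floor <- noise_floor(bt, windows)

  # baseline = the stage immediately before the first phenylephrine dose
  phe_rows <- which(windows$kind == "phenylephrine_dose")
  if (!length(phe_rows)) stop("protocol has no phenylephrine ramp")
  base_row <- min(phe_rows) - 1L
  if (base_row < 1L) stop("no stage precedes the phenylephrine ramp")
  baseline_window <- c(windows$start[base_row], windows$end[base_row])
  bt <- percent_of_baseline(bt, baseline_window, floor)

  pump_rows <- which(windows$kind == "pump_level")
  reference <- if (length(pump_rows) && "P0" %in% windows$stage) "P0" else NULL
  summaries <- stage_summaries(bt, windows, reference = reference)

  # baroreflex curve over the ramp, excluding post-step settling time
  sel <- rep(FALSE, nrow(bt))
  for (i in phe_rows) {
    sel <- sel | (bt$t0 >= windows$stage_start[i] + cfg$settle_s &
                    bt$t0 < windows$stage_end[i])
  }
  base_dbp <- mean(bt$dbp[bt$t0 >= baseline_window[1] &
                            bt$t0 < baseline_window[2]])
  curve <- baro_curve(bt$dbp[sel] - base_dbp, bt$rsna_percent[sel],
                      bin_width = cfg$bin_width)

  observed <- predicted <- delta_dbp <- NA_real_
  top_stage <- NA_character_
  if (!is.null(reference)) {
    pump <- summaries[summaries$stage %in% windows$stage[pump_rows], ]
    top <- pump[which.max(windows$magnitude[pump_rows][
      match(pump$stage, windows$stage[pump_rows])]), ]
    top_stage <- top$stage
    observed <- top$d_rsna_pct
    delta_dbp <- max(top$d_dbp, 0)
    predicted <- suppressWarnings(
      predict_rsna_change(curve, delta_dbp, mode = cfg$predict_mode))
  }

  if (verbose)
    message(sprintf("analyzed %.0f s, %d beats, floor %.2f spikes/s, %s",
                    duration, nrow(bt), floor,
                    if (is.na(observed)) "no pump stages" else
                      sprintf("%s observed %.1f%% predicted %.1f%%",
                              top_stage, observed, predicted)))

  structure(list(beats = bt, windows = windows, floor = floor,
                 baseline_window = baseline_window,
                 summaries = summaries, curve = curve,
                 observed = observed, predicted = predicted,
                 delta_dbp = delta_dbp, top_stage = top_stage,
                 config = cfg),
            class = "rsna_analysis")
}

#' @export
print.rsna_analysis <- function(x, ...) {
  cat(sprintf("RSNA analysis: %d beats, noise floor %.2f spikes/s\n",
              nrow(x$beats), x$floor))
  if (!is.na(x$observed))
    cat(sprintf("  %s: observed %.1f%%, baroreflex-predicted %.1f%% (dDBP %.1f mmHg)\n",
                x$top_stage, x$observed, x$predicted, x$delta_dbp))
  print(x$curve)
  invisible(x)
}

.subject_seed <- function(seed, idx) as.integer((abs(seed) * 100003 + idx * 7919) %% 2147483647)

#' Simulate and analyze a full two-group study
#'
#' Simulates `n_ami` infarct and `n_control` control subjects with the
#' standard protocol (compressed stage durations, pump levels 0/2/4/6/8 for
#' AMI and 0/2/4/6 for controls by default), runs the complete analysis on
#' each, and assembles the group-level results: stage summary tables with
#' deltas vs pump level 0, repeated-measures ANOVA and post-hoc contrasts
#' for the main variables, the per-group paired comparison of observed vs
#' baroreflex-predicted RSNA change at the top pump level, the
#' pulse-pressure vs RSNA trajectory and the pooled RSNA-RRI correlation.
#' Fully deterministic for a given seed and configuration; every output row
#' carries the seed and the configuration hash.
#'
#' @param n_ami,n_control Subjects per group (>= 3 each; set one to 0 to
#'   skip a group).
#' @param seed Master seed; subject seeds are derived deterministically.
#' @param out_dir Optional directory: writes `stage_summaries.csv`,
#'   `comparison.csv`, `statistics.csv`, `correlations.csv` and
#'   `summary.txt`.
#' @param level Simulation level, `"beats"` (fast, default) or
#'   `"waveform"`.
#' @param config A [run_config()].
#' @param protocol Named list of arguments forwarded to [study_protocol()]
#'   (durations, pump levels, sampling rate).
#' @param verbose One log line per subject (default `TRUE`).
#' @return List of class `"replication_report"`.
#' @export
run_replication <- function(n_ami = 6, n_control = 6, seed = 1,
                            out_dir = NULL, level = "beats",
                            config = run_config(),
                            protocol = list(baseline_s = 120,
                                            post_embolization_s = 180,
                                            dose_s = 60, stage_s = 140),
                            verbose = TRUE) {
  if (n_ami > 0 && n_ami < 3) stop("need n >= 3 per simulated group")
  if (n_control > 0 && n_control < 3) stop("need n >= 3 per simulated group")
  groups <- c(rep("ami", n_ami), rep("control", n_control))
  if (!length(groups)) stop("no subjects requested")
  hash <- config_hash(list(config = unclass(config), protocol = protocol,
                           n_ami = n_ami, n_control = n_control,
                           level = level, seed = seed))

  results <- list()
  summaries <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    args <- protocol
    if (is.null(args$levels))
      args$levels <- if (g == "ami") c(0, 2, 4, 6, 8) else c(0, 2, 4, 6)
    sc <- do.call(study_protocol,
                  c(list(group = g, seed = .subject_seed(seed, i)), args))
    bundle <- simulate_recording(sc, level = level)
    res <- analyze_recording(bundle, config)
    if (verbose)
      message(sprintf("subject %s-%d: %d beats, floor %.2f, observed %.1f%% predicted %.1f%%",
                      g, i, nrow(res$beats), res$floor, res$observed,
                      res$predicted))
    results[[i]] <- res
    summaries[[i]] <- cbind(group = g, subject = i, res$summaries)
  }
  summary_tab <- do.call(rbind, summaries)
  summary_tab$seed <- seed
  summary_tab$config <- hash

  per_group <- function(g) which(groups == g)
  comparison <- list()
  stats_tab <- list()
  correlations <- list()
  for (g in unique(groups)) {
    idx <- per_group(g)
    obs <- vapply(results[idx], `[[`, numeric(1), "observed")
    pred <- vapply(results[idx], `[[`, numeric(1), "predicted")
    comparison[[g]] <- predicted_vs_observed(pred, obs)

    stage_names <- unique(summary_tab$stage[summary_tab$group == g &
                                              grepl("^P", summary_tab$stage)])
    for (v in c("map", "pp", "rri", "rsna_percent")) {
      m <- sapply(stage_names, function(s)
        vapply(idx, function(i) {
          r <- results[[i]]$summaries
          r[[v]][r$stage == s]
        }, numeric(1)))
      rownames(m) <- paste0("subj", idx)
      an <- rm_anova(m)
      ph <- posthoc_vs_reference(m, "P0", correction = config$correction)
      stats_tab[[paste(g, v)]] <- data.frame(
        group = g, variable = v, contrast = c("ANOVA", ph$stage),
        estimate = c(NA, ph$estimate), sem = c(NA, ph$sem),
        statistic = c(an$F, ph$t), df = c(an$df2, ph$df),
        p_raw = c(an$p, ph$p_raw), p_adj = c(NA, ph$p_adj),
        n = c(an$n, ph$n))
    }

    # group-mean PP vs RSNA% trajectory across pump stages
    gm <- stats::aggregate(summary_tab[summary_tab$group == g &
                                         grepl("^P", summary_tab$stage),
                                       c("pp", "rsna_percent", "rri",
                                         "d_rsna_pct")],
                           by = list(stage = summary_tab$stage[
                             summary_tab$group == g &
                               grepl("^P", summary_tab$stage)]),
                           FUN = mean)
    tr <- tryCatch(rsna_pp_relation(gm$pp, gm$rsna_percent, gm$stage),
                   error = function(e) NULL)
    # pooled RSNA change vs RRI over subjects and stages
    pool <- summary_tab[summary_tab$group == g &
                          grepl("^P", summary_tab$stage), ]
    rr <- tryCatch(rsna_pp_relation(pool$rri, pool$d_rsna_pct),
                   error = function(e) NULL)
    correlations[[g]] <- list(pp_rsna = tr, rri_rsna = rr)
  }

  report <- structure(list(summaries = summary_tab, comparison = comparison,
                           statistics = do.call(rbind, stats_tab),
                           correlations = correlations,
                           results = results, groups = groups,
                           seed = seed, config = config,
                           config_hash = hash),
                      class = "replication_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("Study replication: %d AMI + %d control subjects, seed %d, config %s\n",
              sum(x$groups == "ami"), sum(x$groups == "control"),
              x$seed, substr(x$config_hash, 1, 8)))
  for (g in names(x$comparison)) {
    cat("\n[", g, "]\n", sep = "")
    print(x$comparison[[g]])
  }
  invisible(x)
}

#' Write a replication report as plain text tables
#'
#' @param report A `"replication_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num <- function(v) signif(v, 8)  # stable text form for byte-identical runs
  p1 <- file.path(dir, "stage_summaries.csv")
  st <- report$summaries
  st[vapply(st, is.numeric, TRUE)] <-
    lapply(st[vapply(st, is.numeric, TRUE)], num)
  utils::write.csv(st, p1, row.names = FALSE)

  comp <- do.call(rbind, lapply(names(report$comparison), function(g) {
    cc <- report$comparison[[g]]
    data.frame(group = g, n = cc$n,
               mean_observed = num(cc$mean_observed),
               sem_observed = num(cc$sem_observed),
               mean_predicted = num(cc$mean_predicted),
               sem_predicted = num(cc$sem_predicted),
               mean_diff = num(cc$mean_diff), t = num(cc$t), df = cc$df,
               p = num(cc$p), seed = report$seed,
               config = report$config_hash)
  }))
  p2 <- file.path(dir, "comparison.csv")
  utils::write.csv(comp, p2, row.names = FALSE)

  stt <- report$statistics
  stt$seed <- report$seed
  stt$config <- report$config_hash
  stt[vapply(stt, is.numeric, TRUE)] <-
    lapply(stt[vapply(stt, is.numeric, TRUE)], num)
  p3 <- file.path(dir, "statistics.csv")
  utils::write.csv(stt, p3, row.names = FALSE)

  cors <- do.call(rbind, lapply(names(report$correlations), function(g) {
    cc <- report$correlations[[g]]
    data.frame(group = g,
               relation = c("pp_vs_rsna", "rri_vs_drsna"),
               r = num(c(cc$pp_rsna$r %||% NA, cc$rri_rsna$r %||% NA)),
               p = num(c(cc$pp_rsna$p %||% NA, cc$rri_rsna$p %||% NA)),
               n = c(cc$pp_rsna$n %||% NA, cc$rri_rsna$n %||% NA),
               seed = report$seed, config = report$config_hash)
  }))
  p4 <- file.path(dir, "correlations.csv")
  utils::write.csv(cors, p4, row.names = FALSE)

  p5 <- file.path(dir, "summary.txt")
  con <- file(p5, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(c(p1, p2, p3, p4, p5))
}

#' Deterministic test fixtures
#'
#' Packaged small synthetic recordings with truth sidecars for tests and
#' examples. `"tiny"` is a ~57 s compressed AMI protocol (fast transitions,
#' two pump levels, 5 s averaging windows) on which the full pipeline runs
#' in seconds; `"default"` is a ~16 min protocol with standard 120 s windows
#' and pump levels 0/4/8.
#'
#' @param size `"tiny"` or `"default"`.
#' @param seed Integer seed (default 1).
#' @return List with `scenario`, `bundle` (waveform level) and a matching
#'   `config`.
#' @export
make_fixtures <- function(size = c("tiny", "default"), seed = 1) {
  size <- match.arg(size)
  if (size == "tiny") {
    sc <- study_protocol("ami", seed = seed, baseline_s = 6,
                         post_embolization_s = 6, dose_s = 5, stage_s = 10,
                         levels = c(0, 8), tau = 1.5)
    cfg <- run_config(window = 5, settle_s = 1)
  } else {
    sc <- study_protocol("ami", seed = seed, baseline_s = 120,
                         post_embolization_s = 150, dose_s = 60,
                         stage_s = 140, levels = c(0, 4, 8))
    cfg <- run_config()
  }
  list(scenario = sc, bundle = simulate_recording(sc, "waveform"),
       config = cfg)
}
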