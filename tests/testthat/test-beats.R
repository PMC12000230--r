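test_that("trough detection counts beats of a periodic pressure wave", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  bp <- 95 + 15 * sin(2 * pi * 1.5 * t)   # 90 bpm
  bounds <- detect_beats(bp, fs)
  expect_gte(length(bounds), 89)
  expect_lte(length(bounds), 91)
  expect_true(all(diff(bounds) >= 0.3 * fs))
  # a pulseless signal has no beats
  expect_warning(z <- detect_beats(rep(80, 5000), fs), "no diastolic troughs")
  expect_identical(z, integer(0))
  # oscillation below the prominence threshold is ignored
  expect_warning(z2 <- detect_beats(95 + 2 * sin(2 * pi * 1.5 * t), fs),
                 "no diastolic troughs")
  expect_identical(z2, integer(0))
})

test_that("detected beat starts align with generator truth", {
  b <- bench_fixture()$bundle
  bounds <- detect_beats(b$bp, b$fs)
  det_t <- (bounds - 1) / b$fs
  truth_t <- b$truth$beats$t0
  # match each truth trough to the nearest detection
  off <- vapply(truth_t, function(tt) min(abs(det_t - tt)), numeric(1))
  expect_lt(stats::median(off), 0.010)
  expect_lt(abs(length(bounds) - 1 - nrow(b$truth$beats)), 3)
})

test_that("per-beat features satisfy the defining identities", {
  b <- tiny_fixture()$bundle
  bounds <- detect_beats(b$bp, b$fs)
  bt <- beat_features(b$bp, b$flow, bounds, b$fs)
  expect_identical(bt$pp, bt$sbp - bt$dbp)            # PP = SBP - DBP exactly
  expect_true(all(bt$sbp > bt$dbp))
  expect_true(all(bt$map >= bt$dbp & bt$map <= bt$sbp))
  expect_true(all(bt$rri >= 0 & bt$rri <= 1))
  expect_equal(bt$hr, 60 / bt$period)
  # formulaic MAP option
  btf <- beat_features(b$bp, b$flow, bounds, b$fs, map_mode = "formula")
  expect_equal(btf$map, btf$dbp + btf$pp / 3)
})

test_that("constant flow within a beat gives zero resistive index", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  bp <- 90 + 20 * pmax(sin(2 * pi * t), 0)
  flow <- rep(3.5, length(t))
  bounds <- detect_beats(bp, fs, prominence = 5)
  bt <- beat_features(bp, flow, bounds, fs)
  expect_true(all(bt$rri == 0))
  expect_true(all(bt$flow_max == bt$flow_min))
})

test_that("beats shorter than 3 samples are dropped with a message", {
  fs <- 100
  bp <- rep(c(80, 100, 90, 85), 10)
  bounds <- c(1L, 4L, 6L, 26L)   # second window has 2 samples
  expect_message(bt <- beat_features(bp, rep(1, length(bp)), bounds, fs),
                 "dropped")
  expect_identical(nrow(bt), 2L)
})

test_that("stage windows follow the two-minute averaging rule", {
  ev <- lapply(0:8, function(l) protocol_event(120 + l * 180, "pump_level", l))
  w <- stage_windows(ev, duration = 120 + 9 * 180, window = 120)
  pump <- w[w$kind == "pump_level", ]
  expect_identical(nrow(pump), 9L)
  expect_equal(pump$end - pump$start, rep(120, 9))
  expect_equal(pump$end, pump$stage_end)
  # short stage: full extent with a warning
  ev2 <- list(protocol_event(50, "pump_level", 0))
  expect_warning(w2 <- stage_windows(ev2, duration = 140, window = 120),
                 "shorter")
  expect_equal(w2$end[2] - w2$start[2], 90)
  # embolization observation window sits immediately before the ramp
  sc <- study_protocol("ami", seed = 1, baseline_s = 300,
                       post_embolization_s = 600, dose_s = 60, stage_s = 140)
  w3 <- stage_windows(sc$events, sc$duration, 120, warn_short = FALSE)
  pe <- w3[w3$stage == "post_embolization", ]
  first_dose <- min(w3$stage_start[w3$kind == "phenylephrine_dose"])
  expect_equal(pe$end, first_dose)
  expect_equal(pe$end - pe$start, 120)
})

test_that("stage summaries average beats and difference against a reference", {
  bt <- data.frame(t0 = seq(0, 59, by = 1), period = 1, sbp = 100, dbp = 80,
                   map = 88, pp = 20, rbf = 200, rri = 0.5)
  class(bt) <- c("beat_table", "data.frame")
  s <- summarize_stage(bt, c(0, 30))
  expect_equal(s$map, 88)
  expect_equal(s$pp, 20)
  expect_identical(s$n_beats, 30L)
  expect_error(summarize_stage(bt, c(0, 4)), ">= 5")

  w <- data.frame(stage = c("P0", "P2"), kind = "pump_level",
                  magnitude = c(0, 2), start = c(0, 30), end = c(30, 60),
                  stage_start = c(0, 30), stage_end = c(30, 60))
  out <- stage_summaries(bt, w, reference = "P0")
  expect_equal(out$d_map, c(0, 0))      # identical stages: all deltas zero
  expect_equal(out$d_rri, c(0, 0))
  expect_error(stage_summaries(bt, w, reference = "P9"), "not present")
})

test_that("a programmed MAP step vs P0 is recovered from the waveforms", {
  # pump effect expressed as a parallel DBP shift so the MAP target is +13
  sc <- scenario(duration = 560, seed = 6,
                 pump_effects = list(max_level = 8, ddbp = 13, dpp = 0,
                                     drbf = 0, drri = 0, decoupling = 0),
                 events = list(protocol_event(100, "phenylephrine_dose", 50),
                               protocol_event(160, "pump_level", 0),
                               protocol_event(360, "pump_level", 8)),
                 dose_slope = 0)
  b <- simulate_recording(sc, "waveform")
  bounds <- detect_beats(b$bp, b$fs)
  bt <- beat_features(b$bp, b$flow, bounds, b$fs)
  w <- stage_windows(sc$events, sc$duration, 120, warn_short = FALSE)
  out <- stage_summaries(bt, w, reference = "P0")
  expect_equal(out$d_map[out$stage == "P8"], 13, tolerance = 1)
  expect_equal(out$d_dbp[out$stage == "P8"], 13, tolerance = 1)
})
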