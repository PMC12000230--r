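---
title: "Models and methods behind renalsym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind renalsym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

renalsym quantifies renal sympathetic nerve activity (RSNA), hemodynamics
and renal flow across an acute-infarct / mechanical-circulatory-support
protocol, and ships a generator that produces synthetic recordings with the
statistical structure the analysis assumes. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot tell you about real recordings.

## The measurement model

**Beats.** Cardiac cycles are delimited at diastolic troughs of the
arterial pressure waveform; windows are half-open `[trough, next trough)`,
so they partition time and every spike belongs to exactly one beat. This
matches the convention of counting nerve spikes "between diastolic
pressures". Trough detection uses a local-minimum search with a refractory
period (`min_period`, default 0.3 s, i.e. a 200 bpm ceiling — well above
ovine heart rates around 90–100 bpm) and a prominence requirement
(`prominence`, default 5 mmHg) so diastolic ripple is not segmented. Flat
ties resolve to the earliest sample; within a refractory window the deeper
trough wins. Indices are 1-based, following R convention.

**Per-beat features.** SBP is the window maximum, DBP the pressure at the
trough, `PP = SBP − DBP` exactly, and MAP is the *time average* of the
waveform over the beat. The formulaic alternative `DBP + PP/3` is available
(`map_mode = "formula"`) because offline analyses sometimes use it; the
time average is the direct definition when the full waveform is available
and is the default. The renal resistive index is
`RRI = (max flow − min flow)/max flow` over the same window, using flow as
measured; RRI is in [0, 1] whenever flow stays non-negative and equals 0
iff flow is constant within the beat.

**RSNA.** The multiunit nerve signal is bandpassed 400–1200 Hz (zero-phase
Butterworth) when the sampling rate supports it (`fs > 2 × 1200 Hz`);
slower recordings are treated as pre-filtered and the step is skipped.
Spikes are upward crossings of a positive threshold with a refractory dead
time (default 2 ms) to avoid double-counting biphasic waveforms. The
discriminator polarity of the original hardware is operator-dependent, so a
rectify-then-threshold mode (`polarity = "absolute"`) is provided; positive
crossings are the default. Threshold choice is operator-judged ("just above
background"); `auto_threshold()` offers `k × MAD` (default `k = 4`) as a
documented convenience. The per-beat rate is the spike count in the beat
divided by the heart period (spikes/s). Summing `rate × period` over beats
returns the integer spike count exactly — a conservation identity the test
suite asserts.

**Noise floor.** The baroreflex-independent background rate is estimated as
the mean raw rate during the top phenylephrine dose, when reflex activity
is abolished by the induced pressure rise; only the final `tail_s`
(default 30 s) of that stage is used so the estimate is taken after the
pressure response has settled. The floor is subtracted from all raw rates
and the result clamped at zero (reported rates are non-negative).

**Baseline and percent.** The 100% reference is the mean corrected rate
over a 2-minute window ending at phenylephrine onset — 30 min
post-embolization in the infarct protocol, the resting period in controls —
consistent with the 2-minute stage-averaging rule used throughout
(`window`, default 120 s; stages shorter than the window use their full
extent with a warning).

## The baroreflex curve

Per-beat DBP changes from baseline during the ramp are sorted into
contiguous half-open 2-mmHg bins from 0 upward (beats with negative change
are excluded; positive = pressure rise), and the mean RSNA% of each bin is
fitted with the standard four-parameter decreasing logistic

$$\mathrm{RSNA}\%(\Delta\mathrm{DBP}) = bottom +
\frac{top - bottom}{1 + \exp((\Delta\mathrm{DBP} - bp_{50})/w)},$$

which is monotone non-increasing for $w > 0$ — the property the reflex
demands. The source analyses display binned curves without naming a fitted
equation; the logistic is this package's parameterization, chosen because
it is the field-standard sigmoid for baroreflex function curves.

Numerical choices:

* **Occupancy-weighted least squares.** Bins holding one or two beats carry
  Poisson noise of tens of percent; weighting by bin count makes the fit
  equivalent to per-beat least squares and prevents sparse bins from
  dominating.
* **Multi-start Levenberg–Marquardt.** The weighted SSE surface has wide
  shallow local minima (a very wide logistic can chase plateau noise);
  several width/midpoint starts are tried and the best kept. The floor is
  constrained non-negative.
* **Fallback.** If no start converges to a decreasing curve, the bin means
  are replaced by their antitonic regression and interpolated linearly; the
  `diagnostics$method` field records which route was taken.
* **Prediction.** `predict_rsna_change(curve, d)` returns
  `fit(d) − fit(0)`, so the prediction at zero pressure change is exactly
  zero; beyond the fitted range the curve is clamped to its last bin with a
  warning. Whether the original predicted values came from a fitted curve
  or raw bin lookup is unstated in the source, so both are provided
  (`mode = "fit"` / `"bins"`).
* **Settling exclusion.** Beats within `settle_s` (default 10 s) of each
  dose step are excluded from the curve. Later transition beats are kept:
  the generated activity tracks each beat's own DBP, so mid-transition
  beats are valid curve points and usefully populate the steep region.

The observed pump-induced change is computed from the 2-minute stage
windows with pump level P0 as reference; the predicted change evaluates the
subject's own curve at the measured DBP rise. `predicted_vs_observed()`
runs a paired two-tailed t-test across subjects (n ≥ 3 required).

## Statistics

The stage comparisons use a subject-blocked one-way ANOVA
(`F = MS_{stage}/MS_{residual}` with `(k−1, (k−1)(n−1))` df), because the
pump levels are within-animal measurements; a plain between-cell one-way
ANOVA is available (`design = "oneway"`) for faithfulness to analyses that
ignored blocking. The normality check is Shapiro–Wilk (standard at these
sample sizes); the post-hoc contrasts against P0 are paired t-tests with
Holm step-down correction by default (Bonferroni or none selectable — the
original correction is unnamed, so the choice is surfaced rather than
guessed silently). Unpaired comparisons default to Welch's unequal-variance
form. Missing stages are handled complete-case per analysis with the
retained n reported. Degenerate inputs follow documented rules: a table
with zero residual variance returns `F = 0, p = 1` when the stage effect is
also zero and `F = ∞, p = 0` otherwise; identical paired arms return
`t = 0, p = 1`.

## The synthetic-recording generator

The generator exists so that every stage of the pipeline can be tested
against ground truth. It works at two levels:

1. `generate_beat_sequence()` — the cardiac-cycle-resolved truth: each
   protocol event sets new hemodynamic targets (DBP, PP, RBF, RRI) which
   the state approaches exponentially (time constant `tau`, default 10 s;
   the source traces show gradual transitions but give no kinetics), with
   multiplicative Gaussian inter-beat jitter per channel. The expected
   firing rate of each beat is
   `noise_floor + gain × baro(DBP_beat) × (1 − decoupling)`, evaluated at
   the beat's realized DBP, so the generated activity is exactly
   baroreflex-consistent.
2. `render_waveforms()` — sampled channels: a quarter-sine systolic
   upstroke to the target SBP with exponential diastolic decay toward the
   next trough; a flow waveform scaled so each beat's extrema realize its
   target RRI exactly and its time average equals the target RBF; and a
   nerve trace summing stereotyped biphasic spike templates at times drawn
   from an inhomogeneous Poisson process (piecewise-constant per beat) over
   Gaussian background noise. Spike trains as counts per heart period make
   Poisson the minimal consistent model. `simulate_beat_counts()` skips
   rendering and draws the per-beat counts directly — the fast "beat level"
   used for large simulation studies.

Default conditions mirror the instrumented-sheep magnitudes: AMI baseline
DBP/SBP 78/104 mmHg, RBF 240 ml/min, RRI 0.72, 91 bpm, raw RSNA
16 spikes/s over a 2 spikes/s floor (the floor is defined operationally,
not numerically, in the source; 2 spikes/s is this package's default);
embolization drops DBP/SBP by 16.8/20.8 mmHg, RBF by 65 ml/min, raises RRI
by 0.40 and corrected RSNA by 67.5%; full pump support (P8) raises DBP by
19.6 mmHg, cuts PP by 10.5 mmHg, adds 32.6 ml/min RBF and removes 0.27 of
RRI, scaled linearly with pump level; controls use the corresponding
level-6 magnitudes and start from DBP/SBP 84/109 mmHg, RBF 192 ml/min,
RRI 0.51.

Two generator parameters deserve explanation:

* **Decoupling fraction** (default 0.2 at P8, linear in level, 0 in
  controls): the fraction of baroreflex-driven RSNA suppressed beyond what
  the pressure rise predicts. It is this package's free parameter — the
  phenomenon under study, not a measured quantity — and its default makes
  the synthetic AMI cohort reproduce an observed ≈ −22% vs predicted ≈ −3%
  contrast at P8.
* **Curve position** (`bp50_offset` 25 mmHg above the ramp-baseline DBP,
  `slope_width` 1.5 mmHg): chosen once so that (a) pump-range pressure
  rises (ΔDBP ≈ 20 mmHg) sit on the shallow shoulder and predict only a
  few percent inhibition, while (b) the top phenylephrine dose
  (ΔDBP ≈ 34 mmHg at the default 0.085 mmHg per ml/hr dose sensitivity)
  drives the reflex component below 0.1 spikes/s, making "RSNA abolished at
  the highest dose" literally true so the noise floor is recoverable.
  These two constraints jointly force a curve that is flat through the
  pump range and falls steeply above it.
* **Embolization and RSNA.** A pressure drop alone moves activity *along*
  the curve, which cannot yield a +67% rise with a shallow pump-range
  shoulder; sympathetic activation after infarction resets the curve. The
  generator implements this as an explicit gain on the baroreflex-driven
  component, computed so the corrected rate at the new steady state meets
  the event's target percent change.

Subject-level realism: `study_protocol()` jitters baselines (CV 5%) and
intervention effect sizes (CV 15%) deterministically from the subject
seed, giving between-animal spread of the stage deltas comparable to the
reported SEMs. Everything — beat jitter, spike times, background noise —
derives from the scenario seed, so identical scenarios produce
byte-identical recordings.

**What the generator does not emulate.** No ECG or electrophysiology (beat
timing only; ST changes are not simulated); no pump hydraulics or suction
re-positioning (levels act through their programmed hemodynamic effects);
no respiratory or Mayer-wave variability, arrhythmia, ectopy, electrode
drift, or movement artifact; spike waveforms are stereotyped rather than
multi-unit mixtures; RRI is capped at 0.98 because the rendered flow stays
non-negative, whereas severely impeded kidneys can show reverse diastolic
flow and RRI above 1. Passing tests therefore demonstrate that the
pipeline recovers truth under the stated statistical model, not that it is
robust to every artifact of live recordings.

## Problem sizes

The packaged fixtures and simulation studies use compressed protocols —
stage durations of 60–180 s with pump levels {0, 2, 4, 6, 8} (AMI) or
{0, 2, 4, 6} (controls), 1 kHz sampling — rather than the full ~90-minute
protocol, which `study_protocol()`'s defaults still encode (30 min
baseline and observation, 3-min stages, levels 0–8). The compressed runs
keep every structural element (embolization, five-dose ramp, settled
2-minute-rule windows) while letting parameter-recovery studies span many
seeds; cohort power checks run at beat level, and the waveform path is
exercised end to end by the fixture-based tests and the acceptance script.
At 1 kHz the 400–1200 Hz bandpass cannot apply (Nyquist 500 Hz), so the
synthetic nerve channel is analyzed in pre-filtered mode; the filter
itself is tested at 5 kHz. Spike templates are 2–3 ms, so 1 kHz is the
rendering floor (2 kHz is available via `fs`).

## Known limitations

* The logistic is fitted to bin means, so subjects whose ramp never leaves
  the plateau yield poorly identified `bp50`; the diagnostics (`rms`,
  `method`, `n_bins`) should be inspected before trusting per-subject
  parameters.
* The noise-floor estimate assumes the top dose truly abolishes reflex
  activity; a curve centred far above the achieved pressure rise would
  bias the floor upward. The `tail_s` window mitigates transition
  contamination but cannot detect an unsaturated ramp.
* Beat-level simulation uses the formulaic MAP (`DBP + PP/3`), which runs
  1–2 mmHg above the waveform time average for these pulse shapes; stage
  *deltas* are essentially unaffected.
* `rsna_pp_relation()` reports plain Pearson correlations; pooled
  subject-by-stage correlations ignore within-subject clustering, as in
  the analyses they mirror.
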