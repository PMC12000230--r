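Package: renalsym
Title: Simulation and Analysis of Renal Sympathetic Nerve Activity Under
    Mechanical Circulatory Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying renal sympathetic nerve activity (RSNA),
    hemodynamics and renal blood flow from multichannel physiological
    recordings under acute myocardial infarction and incremental left
    ventricular assist device support. Provides beat detection from the
    arterial pressure waveform, per-beat hemodynamic and renal-flow feature
    extraction (SBP, DBP, MAP, pulse pressure, renal resistive index),
    threshold-crossing spike quantification of the renal nerve signal with
    noise-floor correction, baroreflex function curves fitted as a
    four-parameter decreasing logistic over binned diastolic pressure
    changes during a phenylephrine ramp, prediction of reflex-mediated RSNA
    changes and paired comparison against observed pump-induced changes,
    repeated-measures statistics, and a deterministic synthetic-recording
    generator that emulates the full experimental protocol with ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
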