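Package: duetgamma
Title: Turn-Taking Vocal Interaction Metrics and Low-Gamma LFP Auditory
    Response Scoring for Songbird Telemetry
Version: 0.1.0
Authors@R:
    person("Duetgamma", "Developers", email = "duetgamma@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for synchronized vocal and neural recordings
    of freely behaving songbirds. Computes turn-taking statistics (reply
    strength and reply latency) from time-stamped call-event tables, scores
    local field potential (LFP) traces with a 10-200 Hz first-order
    Butterworth filter bank to obtain the baseline-corrected Auditory
    Response Strength (ARS) and its low-gamma band of interest, supports
    pseudorandomized playback experiments, and summarizes linear
    mixed-model fits with flat-prior posterior draws, 95% credible
    intervals and a posterior-probability decision rule. Includes a
    synthetic-data generator emulating multi-bird call streams and
    stimulus-locked low-gamma LFP bursts so the whole pipeline is testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
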