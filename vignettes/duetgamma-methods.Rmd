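---
title: "duetgamma: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duetgamma: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package computes

`duetgamma` analyses synchronized vocal and neural telemetry from
group-living songbirds (the target system is the zebra finch, whose
repertoire comprises the contact calls stack/tet/distance, the breeding
calls kackle/whine, hat calls, and — in males — song). Two kinds of raw
data enter the pipeline:

* **call-event tables** — one row per vocalization with emitter, call
  type, onset, duration, day and treatment (non-breeding `NB` vs
  breeding `B`), and
* **LFP traces** — single-channel local field potential recordings from
  the caudomedial nidopallium (NCM), a secondary auditory area, sharing
  the session clock of the events.

From these it computes:

1. **Turn-taking metrics.** A call of bird 2 is an *answer* to a call of
   bird 1 when its onset falls within the 500 ms answer window after
   bird 1's onset. *Reply latency* (RL) is the onset-to-onset gap of the
   first answer. *Reply strength* is the normalized count contrast

   RS = (Nresponse − Nbaseline) / (Nresponse + Nbaseline),

   where Nresponse and Nbaseline count the focal bird's calls in the
   500 ms after, respectively before, each reference onset, accumulated
   over all reference calls of a given type. RS lies in [−1, 1] and is
   missing (never NaN arithmetic) when both counts are zero.
2. **Auditory Response Strength (ARS).** The trace is passed through a
   bank of first-order Butterworth band-pass filters covering 10–200 Hz
   in 10 Hz bands. For every heard call and band,
   ARS = RMS(stimulus fragment) − RMS(baseline fragment), where the
   stimulus fragment spans the call `[onset, onset + duration)` and the
   baseline is the equal-length window immediately before the onset.
   ARS is normalized to [−1, 1] within each bird, and bands are ranked
   per bird by the mean of log(ARS²) to select the band of interest
   (top 3 by default — the low-gamma bands labelled 30/40/50 Hz, which
   span 30–60 Hz).
3. **Playback support.** Peak normalization of stimuli to −5 dB re full
   scale, pseudorandomized schedules (every stimulus exactly
   `repetitions` times, no immediate repeats), and per-stimulus ARS
   aggregation across repetitions.
4. **Decision machinery.** Linear (mixed) models are point-fitted by
   REML; 10,000 draws are then taken from the flat-prior joint posterior
   of the coefficients; each contrast is summarized by its mean, 95%
   credible interval (2.5–97.5 percentiles) and the directional
   posterior probability, and called *meaningful* when that probability
   exceeds 95%.

## Conventions that matter

* **Time base.** Session-relative seconds; events and traces share one
  clock. Synchrony of the transmitters is an input assumption — the
  package does not align clocks.
* **Half-open intervals.** An event occupies `[onset, onset+duration)`.
  The answer window is onset-exclusive and end-inclusive, `(t, t+0.5]`:
  a call starting exactly with the reference is simultaneous, not an
  answer. The RS baseline window is `[t−0.5, t)`.
* **Multiple answers.** All answers count toward Nresponse ("total
  number of calls"); only the first defines the latency of a reference.
* **Call contexts.** Relative to the focal (implanted) bird, a heard
  call is `isolated` when no other sound of any bird overlaps the open
  window (onset − 5 s, offset + 5 s); otherwise `answer_by_focal` when
  the focal calls within 0.5 s after it, else `answered_by_partner`
  when it itself starts within 0.5 s of a focal call, else `other`.
  The source description of the two non-isolated categories is
  internally inconsistent (its 0.5 s/5 s windows and before/after
  directions do not line up with the 500 ms answer convention used
  everywhere else), so this package fixes the rule above explicitly
  rather than guessing intent; the windows sit in
  `interaction_config()` and are configurable.
* **Band labels.** Bands are labelled by their lower edge, so "bands
  30, 40 and 50" cover 30–60 Hz — consistent with the low-gamma band
  definition. The labelling convention is not stated in the source and
  is fixed here.
* **Zero-phase filtering.** Band-pass filters are applied
  forward–backward (with odd-reflection padding), so RMS windows align
  with call boundaries without group delay; the effective amplitude
  response is |H|². A forward-only mode exists (`zero_phase = FALSE`).
  Note that zero-phase filtering smears a small amount of burst energy
  backward in time, which slightly elevates the baseline RMS of strong
  responses.
* **Baseline contamination.** Events overlapping the baseline window do
  not exclude a record by default; an optional strict mode can be built
  on the context labels. Under closely spaced stimulation this produces real
  contamination: if a long stimulus's baseline reaches into the
  previous presentation, treatment-dependent responses leak into the
  baseline and can bias contrasts. The playback default of 8–12 s
  inter-trial gaps avoids this for stimuli up to several seconds.
* **log(x²) transform.** Applied with an epsilon floor of 1e−12 on
  |ARS|; floored records are excluded from band ranking and counted.
  The per-bird band ranking by *mean* log(ARS²) is a deliberately
  simple stand-in for per-bird mixed models on the same response scale,
  whose exact random structure would be protocol-specific.

## The posterior-draw decision rule

For an OLS fit the flat-prior posterior (p(β) ∝ 1, p(σ²) ∝ 1/σ²) is the
standard conjugate form: σ² is drawn as σ̂²·df/χ²(df) and β as
multivariate normal around β̂ with the fit covariance rescaled by
σ²/σ̂². For mixed fits the variance components beyond the residual are
fixed at their REML estimates and β is drawn from MVN(β̂, V̂) — a stated
approximation, configurable in scope, matching common practice for this
"pseudo-Bayesian" style of summarizing REML fits. Under a true null and
an OLS fit the rule "directional posterior probability > 95%" is
numerically identical to a one-sided 5% test per direction, so its
false-positive behaviour is ~5% per direction / ~10% two-directionally;
the package deliberately applies no multiplicity correction and
reports the number of contrasts so users can judge. `prob_direction` reports the larger directional fraction with
the direction attached, and both directional fractions are returned.

`run_paper_contrasts()` fits `response ~ treatment × type` (optionally
with random intercepts) and reports the B − NB contrast within each
type level. Levels observed under only one treatment are dropped with a
notice — they cannot support the contrast and would alias the
interaction design. Random-effect structures that fail to converge on
small data are dropped term by term, with a notice, down to OLS.

## The synthetic world

No recordings are distributed with the package; every downstream stage
is exercised against `simulate_vocal_session()`, `simulate_lfp()` and
`simulate_experiment()`. The generator's defaults state a world, chosen
once:

* **Vocal streams.** Per bird and call type, baseline calls are a
  homogeneous Poisson process; each heard partner call is answered with
  probability p at a latency drawn from Uniform(0.05, 0.45) s (or a
  truncated exponential), within the 500 ms window. Answers suppress
  nothing (no refractoriness) and only baseline calls trigger answers —
  the simplest generative model of turn-taking.
* **LFP traces.** Gaussian noise (white, sd 1 for daytime; a 1/f option
  exists) plus one amplitude-enveloped narrow-band burst per heard
  call, spanning exactly the call window, with 10 ms raised-cosine
  ramps (to avoid spectral splatter), random phase, and a carrier drawn
  uniformly from f_c ± bandwidth/2. The default response is centred at
  45 Hz with 30 Hz bandwidth, i.e. a 30–60 Hz low-gamma response, the
  band where NCM auditory responses are maximal. Burst amplitude 0.4 makes
  the burst's power twice the noise power of one 10 Hz band (the SNR at
  which band recovery is specified).
* **Night playbacks** use noise sd 0.3: night recordings in a silent
  aviary are free of the movement and wing-flap artifacts of daytime
  soundscapes, so they are much cleaner; and at daytime noise levels the
  strongly unequal stimulus durations (100 ms white-noise control vs
  1.5 s song) make the pooled-variance model anticonservative for the
  shortest stimuli.
* **Simulation rate 500–1000 Hz**, not the 44.1 kHz of the real
  acquisition: the analysis bank tops at 200 Hz, so anything ≥ 400 Hz
  is faithful and fast. The readers accept real-rate files.

What the generator does **not** emulate: acoustically realistic calls,
movement or wing-flap artifacts, 50 Hz line noise, electrode drift,
sleep/arousal state, or hormone dynamics. A green recovery test
therefore establishes that the pipeline measures what this generative
model produces — not that the biological effect sizes of any particular
study are reproduced.

## Numerical notes

* Filter coefficients come from the bilinear transform with edge
  prewarping; they agree with standard signal-processing references to
  machine precision (tested against an independent implementation).
* First-order 10 Hz-wide bands have gentle skirts; a tone at a band
  edge passes two bands at ~−3 dB each (−6 dB after the zero-phase
  double pass). Energy "within" a band must be read with this leakage
  in mind.
* RMS over a window of length T in a band of width B has roughly 2·B·T
  degrees of freedom; windowed ARS of very short calls is accordingly
  noisy, and the 100 ms white-noise control is the noisiest score in
  the set.
* The turn-taking window counts use `findInterval()` on sorted onsets
  (O(log n) per reference); brute-force all-pairs reimplementations are
  kept in the test suite as oracles.
* Chance coincidences contribute links to the latency measurement; with
  reference calls sparser than ~1 per 25 s the contamination is
  negligible, while at high calling rates adjacent answer windows begin
  to collide and bias the measured latency slightly downward. The
  acceptance check of latency recovery is run in the sparse regime.

## Known limitations

* The variance-component posterior for mixed fits is approximated
  (components fixed at REML estimates); fully Bayesian hierarchical
  sampling is out of scope.
* The per-bird band-ranking statistic is a stand-in (see above).
* WAV support covers mono PCM16/PCM32/float32 — the subset the
  telemetry pipeline needs.
* The context-classification convention resolves a contradiction in the
  source description; results for the non-isolated categories depend on
  that convention.
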