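# duetgamma

Turn-taking vocal interaction metrics and low-gamma LFP auditory
response scoring for songbird telemetry.

`duetgamma` is an R package for analysing synchronized vocal and neural
recordings of freely behaving songbirds (the target system is the
zebra finch): miniature backpack microphones yield per-bird
call-event tables, and a chronically implanted electrode in the
caudomedial nidopallium (NCM, a secondary auditory area) yields a local
field potential (LFP) trace on the same clock. The package is written
for neuroethologists who want to quantify, in one reproducible
pipeline, how vocal turn-taking and auditory responsiveness change
across life-history stages (non-breeding `NB` vs breeding `B`).

## The statistics at its core

**Reply strength (RS).** For a pair of birds and a pair of call types,
count the focal bird's calls in the 500 ms after each reference onset
(N<sub>response</sub>) and in the 500 ms before (N<sub>baseline</sub>):

    RS = (N_response − N_baseline) / (N_response + N_baseline)  ∈  [−1, 1]

**Reply latency (RL).** Onset-to-onset gap of the first answer within
the 500 ms window, averaged per call interaction.

**Auditory Response Strength (ARS).** The LFP trace is filtered by a
bank of first-order Butterworth band-passes, 10–200 Hz in 10 Hz bands;
for each heard call and band,

    ARS = RMS(band-filtered trace during the call)
        − RMS(equal-length window immediately before the call onset)

ARS is normalized to [−1, 1] within each bird. Bands are ranked per
bird by mean log(ARS²); the top three — the low-gamma bands labelled
30/40/50 Hz, spanning 30–60 Hz — form the band of interest.

**Decision rule.** Linear (mixed) models are point-fitted by REML;
10,000 draws are taken from the flat-prior joint posterior of the
coefficients (p(β) ∝ 1, p(σ²) ∝ 1/σ²); each contrast is summarized by
its mean, 95% credible interval (2.5–97.5 percentiles of the draws) and
directional posterior probability, and flagged *meaningful* when that
probability exceeds 95%.

A first-class synthetic-data generator (Poisson call streams with
context-dependent reply probability/latency; LFP noise plus
stimulus-locked low-gamma bursts with treatment/call-type/emitter
gains) makes every stage testable without recordings.

## Worked example

One simulated morning of a mated pair (the female answers 60% of the
male's stack calls within 500 ms), then four pooled mornings of LFP
scoring (runs in about a minute):

```r
library(duetgamma)
cfg <- interaction_config()       # 0.5 s answer window, 5 s isolation gap

p <- vocal_sim_params(
  bird_ids = c("female", "male"), session_length_s = 3600,
  rates = list(female = c(stack = 0.03), male = c(stack = 0.08)),
  reply = data.frame(responder = "female", ref_type = "stack",
                     prob = 0.6, answer_type = "stack"),
  latency = list(family = "uniform", min = 0.05, max = 0.45), seed = 11)
session <- simulate_vocal_session(p)

reply_strength(session$female, session$male, c("stack", "stack"), cfg)
#> <reply_strength> stack answering stack: RS = 0.882 (Nresp 175, Nbase 11, 274 refs)
reply_latency(find_answers(session$male, session$female, cfg))
#>   n_links mean_latency_s
#> 1     168      0.2427893
```

RS = 0.882 means the female called almost exclusively *after* the
male's calls rather than before them; the mean latency of 243 ms sits
mid-window, matching the generating Uniform(0.05, 0.45) s latencies.

```r
bank <- design_filter_bank(500)   # 19 bands, 10-200 Hz, order 1
#> <filter_bank> 19 order-1 Butterworth bands, 10-200 Hz @ 500 Hz

all_recs <- list()
for (day in 1:4) {                # the band ranking pools days
  p$day_index <- day; p$seed <- 10 + day
  session <- simulate_vocal_session(p)
  heard <- session$male$events
  lp <- lfp_sim_params(fs_hz = 500, duration_s = 3600,
                       noise = list(model = "white", sd = 1),
                       f_c = 45, bandwidth = 30, base_amplitude = 0.4,
                       seed = 20 + day)
  trace <- simulate_lfp(heard, lp, bird_id = "female")
  all_recs[[day]] <- compute_ars(trace, heard, bank)
}
recs <- normalize_within_bird(do.call(rbind, all_recs))
select_band_of_interest(recs, k = 3)
#> <band_selection> bands of interest: 30, 40, 50 Hz
#>   female: top bands 50, 30, 40
```

The injected 30–60 Hz bursts are recovered as the 30/40/50 Hz band of
interest. (A single morning of 100 ms stack calls is not enough: the
selection then comes back flagged `[no dominant band]` — the ranking
needs the pooled data, which is why the flag exists.)

Treatment contrasts run through the posterior machinery:

```r
report <- run_paper_contrasts(recs_with_both_treatments, response = "ars")
#   one row per call type: mean, cri_low, cri_high, prob_direction,
#   decision ("meaningful" iff prob_direction > 0.95)
write_contrast_report(report, "report/")
```

## Command line

A thin CLI ships under `inst/cli/duetgamma`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/duetgamma", package = "duetgamma"))')" \
    validate events.csv trace.wav config.yaml
# subcommands: validate | simulate | interactions | ars | report
```

## File formats

* events: CSV with `emitter_id, call_type, onset_s, duration_s,
  day_index, treatment`
* traces: mono WAV (PCM16/PCM32/float32)
* schedules: CSV with `stimulus_label, emitter, onset_s, duration_s`
* configuration: YAML (`answer_window_s`, `peri_window_s`,
  `bin_width_s`, `isolation_gap_s`)

See `vignettes/duetgamma-methods.Rmd` for the model conventions, the
synthetic world, numerical choices and known limitations.
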