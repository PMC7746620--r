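# The generator is first-class: determinism, Poisson baseline, answer
# insertion, burst placement and the experiment-level manifest.

test_that("vocal simulation is reproducible under a fixed seed", {
  p <- vocal_sim_params(session_length_s = 120, seed = 99)
  s1 <- simulate_vocal_session(p)
  s2 <- simulate_vocal_session(p)
  expect_equal(s1, s2)
})

test_that("param validation rejects invalid rates, probs, latencies", {
  expect_error(vocal_sim_params(rates = c(stack = -1)), "rates")
  expect_error(vocal_sim_params(
    reply = data.frame(responder = "f", ref_type = "stack", prob = 1.5,
                       answer_type = "stack")), "\\[0, 1\\]")
  expect_error(vocal_sim_params(
    latency = list(family = "uniform", min = 0.1, max = 0.9)),
    "answer_window")
  expect_error(lfp_sim_params(fs_hz = 200), ">= 400")
  expect_error(lfp_sim_params(noise = list(model = "white", sd = 0)),
               "sd must be")
})

test_that("lambda = 0 with p = 1 yields exactly one answer per seeded call", {
  p <- vocal_sim_params(
    bird_ids = c("f", "m"), session_length_s = 60,
    rates = list(f = c(stack = 0), m = c(stack = 0)),
    reply = data.frame(responder = "f", ref_type = "stack", prob = 1,
                       answer_type = "tet", stringsAsFactors = FALSE),
    seed = 5)
  # seed one partner call by hand: simulate, then inject and re-run answer
  # logic through a session where only m calls once
  p$rates$m <- c(stack = 1 / 60)   # expect ~1 call; force determinism by seed
  repeat {
    s <- simulate_vocal_session(p)
    if (nrow(s$m$events) == 1L) break
    p$seed <- p$seed + 1L
  }
  ans <- s$f$events
  expect_equal(nrow(ans), 1L)
  expect_equal(ans$call_type, "tet")
  lat <- ans$onset_s - s$m$events$onset_s
  expect_true(lat > 0 && lat <= 0.5)
})

test_that("with p = 0 the streams are pure Poisson at the nominal rate", {
  lam <- 0.4; T <- 200; k <- 30
  counts <- numeric(k)
  near <- 0L; refs <- 0L
  for (i in 1:k) {
    p <- vocal_sim_params(bird_ids = c("f", "m"), session_length_s = T,
                          rates = c(stack = lam), reply = NULL,
                          seed = 1000 + i)
    s <- simulate_vocal_session(p)
    counts[i] <- nrow(s$f$events)
    # chance-level "answers": f calls within 0.5 s after an m call
    links <- find_answers(s$m, s$f, interaction_config())
    near <- near + nrow(links)
    refs <- refs + nrow(s$m$events)
  }
  # mean count ~ lam*T within 4 MC standard errors
  se <- sqrt(lam * T / k)
  expect_lt(abs(mean(counts) - lam * T), 4 * se)
  # chance rate of in-window calls ~ lam * 0.5 per reference call
  expect_lt(abs(near / refs - lam * 0.5), 4 * sqrt(lam * 0.5 / refs))
})

test_that("generated answer latencies recover the generating mean", {
  lats <- numeric(0)
  for (i in 1:20) {
    p <- vocal_sim_params(
      bird_ids = c("f", "m"), session_length_s = 300,
      rates = list(f = c(stack = 0.005), m = c(stack = 0.1)),
      reply = data.frame(responder = "f", ref_type = "stack", prob = 1,
                         answer_type = "stack", stringsAsFactors = FALSE),
      latency = list(family = "uniform", min = 0.05, max = 0.45),
      seed = 2000 + i)
    s <- simulate_vocal_session(p)
    links <- find_answers(s$m, s$f, interaction_config())
    rl <- reply_latency(links)
    lats <- c(lats, rep(rl$mean_latency_s, rl$n_links))
  }
  se <- 0.1155 / sqrt(length(lats))   # sd of U(0.05, 0.45)
  expect_lt(abs(mean(lats) - 0.25), 3 * se)
})

test_that("truncated-exponential latencies stay inside the window", {
  p <- vocal_sim_params(
    bird_ids = c("f", "m"), session_length_s = 300,
    rates = list(f = c(stack = 0), m = c(stack = 0.2)),
    reply = data.frame(responder = "f", ref_type = "stack", prob = 1,
                       answer_type = "stack", stringsAsFactors = FALSE),
    latency = list(family = "exp_trunc", rate = 10, max = 0.5),
    seed = 77)
  s <- simulate_vocal_session(p)
  links <- find_answers(s$m, s$f, interaction_config())
  expect_gt(nrow(links), 0)
  expect_true(all(links$latency_s > 0 & links$latency_s <= 0.5))
})

test_that("zero gain gives pure noise: mean ARS ~ 0 over many calls", {
  ev <- call_events(rep("m", 40), "tet", seq(2, 81, by = 2), 0.25)
  lp <- lfp_sim_params(fs_hz = 500, duration_s = 85,
                       noise = list(model = "white", sd = 1),
                       gain = 0, seed = 20)
  trc <- simulate_lfp(ev, lp)
  bank <- design_filter_bank(500)
  recs <- compute_ars(trc, ev, bank)
  burst_band <- recs$ars[recs$band_hz == 40]
  expect_lt(abs(mean(burst_band)), 3 * sd(burst_band) / sqrt(40))
})

test_that("a clean 40 Hz burst has stimulus RMS ~ A/sqrt(2) in its band", {
  A <- 0.8
  ev <- call_events("m", "tet", 5, 0.5)
  lp <- lfp_sim_params(fs_hz = 1000, duration_s = 10,
                       noise = list(model = "white", sd = 1e-9),
                       f_c = 40, base_amplitude = A, ramp_s = 0.01,
                       seed = 21)
  trc <- simulate_lfp(ev, lp)
  stim <- extract_fragments(trc, 5, 0.5)
  # raw (unfiltered) burst RMS: A/sqrt(2) shaved slightly by the 10 ms ramps
  expect_equal(rms(stim$stimulus), A / sqrt(2), tolerance = 0.05)
  expect_lt(rms(stim$baseline), 1e-6)
  # band-filtered: within the 30-50 Hz bands, scaled by the filter gain
  bank <- design_filter_bank(1000)
  recs <- compute_ars(trc, ev, bank)
  expect_gt(recs$ars[recs$band_hz == 30], 0.2)
  expect_lt(recs$ars[recs$band_hz == 120], 0.01)
})

test_that("burst energy concentrates near f_c (spectral placement)", {
  ev <- call_events("m", "tet", 2, 1)
  lp <- lfp_sim_params(fs_hz = 500, duration_s = 5,
                       noise = list(model = "white", sd = 1e-12),
                       f_c = 45, base_amplitude = 1, seed = 22)
  trc <- simulate_lfp(ev, lp)
  sp <- stats::spec.pgram(stats::ts(trc$samples, frequency = 500),
                          taper = 0, plot = FALSE)
  inband <- sp$freq >= 35 & sp$freq <= 55    # f_c +/- 10 Hz
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.9)
})

test_that("one-over-f noise has more low than high frequency power", {
  lp <- lfp_sim_params(fs_hz = 500, duration_s = 20,
                       noise = list(model = "one_over_f", sd = 1),
                       gain = 0, seed = 23)
  trc <- simulate_lfp(call_events("m", "tet", 5, 0.2), lp)
  sp <- stats::spec.pgram(stats::ts(trc$samples, frequency = 500),
                          taper = 0, plot = FALSE, spans = 15)
  lo <- mean(sp$spec[sp$freq > 1 & sp$freq < 10])
  hi <- mean(sp$spec[sp$freq > 100 & sp$freq < 200])
  expect_gt(lo, 5 * hi)
})

test_that("gain tables match on treatment, call type and emitter", {
  gain <- data.frame(treatment = c("B", NA), call_type = c("tet", "tet"),
                     emitter_id = NA, gain = c(2, 1),
                     stringsAsFactors = FALSE)
  ev_b <- call_events("m", "tet", 1, 0.1, treatment = "B")
  ev_nb <- call_events("m", "tet", 1, 0.1, treatment = "NB")
  ev_other <- call_events("m", "song", 1, 0.1, treatment = "B")
  expect_equal(duetgamma:::burst_gain(ev_b[1, ], gain), 2)
  expect_equal(duetgamma:::burst_gain(ev_nb[1, ], gain), 1)
  expect_equal(duetgamma:::burst_gain(ev_other[1, ], gain), 1)  # fallback
})

test_that("simulate_experiment is deterministic and records the truth", {
  cfg <- list(session_length_s = 60, n_days_nb = 1L, n_days_b = 1L,
              seed = 42)
  e1 <- suppressMessages(simulate_experiment(cfg))
  e2 <- suppressMessages(simulate_experiment(cfg))
  expect_equal(e1$streams, e2$streams)
  expect_equal(e1$traces[["female.1"]]$trace$samples,
               e2$traces[["female.1"]]$trace$samples)
  expect_true(e1$manifest$null_effect)    # default: equal gains
  cfg$gain_b <- data.frame(call_type = "tet", gain = 2)
  e3 <- suppressMessages(simulate_experiment(cfg))
  expect_false(e3$manifest$null_effect)
  expect_equal(e3$manifest$gain_b$call_type, "tet")
})

test_that("simulate_experiment writes a loadable on-disk dataset", {
  out <- file.path(tempdir(), "simdata_test")
  withr::defer(unlink(out, recursive = TRUE))
  cfg <- list(session_length_s = 30, n_days_nb = 1L, n_days_b = 1L,
              seed = 7, fs_hz = 500)
  suppressMessages(simulate_experiment(cfg, out_dir = out))
  expect_true(file.exists(file.path(out, "events.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  streams <- read_events(file.path(out, "events.csv"))
  expect_gt(length(streams), 0)
  tr <- read_trace(file.path(out, "trace_female.1.wav"))
  expect_equal(tr$fs_hz, 500)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 7)
})
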