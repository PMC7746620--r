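# Filter bank design, zero-phase band-pass filtering, fragment
# extraction, RMS, ARS records, per-bird normalization and band-of-
# interest selection. scipy (via the image's python) serves as the
# independent signal-processing oracle.

test_that("the default bank has 19 contiguous 10 Hz bands from 10 to 200", {
  bank <- design_filter_bank(1000)
  expect_length(bank$bands, 19L)
  expect_equal(bank$bands[[1]]$low_hz, 10)
  expect_equal(bank$bands[[1]]$high_hz, 20)
  expect_equal(bank$bands[[19]]$low_hz, 190)
  expect_equal(bank$bands[[19]]$high_hz, 200)
  labels <- vapply(bank$bands, function(b) b$label_hz, numeric(1))
  expect_equal(labels, seq(10, 190, by = 10))
})

test_that("a sampling rate at or below twice the top edge is rejected", {
  expect_error(design_filter_bank(300), "Nyquist")
  expect_error(design_filter_bank(400), "Nyquist")
})

test_that("band coefficients equal scipy's first-order Butterworth design", {
  bank <- design_filter_bank(1000)
  out <- run_python(paste(
    "from scipy.signal import butter",
    "for lo in range(10, 200, 10):",
    "    b, a = butter(1, [lo/500, (lo+10)/500], 'bandpass')",
    "    print(' '.join(repr(float(v)) for v in list(b)+list(a)))",
    sep = "\n"))
  for (i in seq_along(bank$bands)) {
    vals <- as.numeric(strsplit(out[i], " ")[[1]])
    expect_equal(bank$bands[[i]]$b, vals[1:3], tolerance = 1e-12)
    expect_equal(bank$bands[[i]]$a, vals[4:6], tolerance = 1e-12)
  }
})

test_that("zero-phase filtering agrees with scipy filtfilt away from edges", {
  set.seed(7)
  x <- rnorm(5000)
  bank <- design_filter_bank(1000)
  y <- bandpass(lfp_trace(x, 1000), bank$bands[[3]])$samples
  fx <- tempfile(fileext = ".txt")
  withr::defer(unlink(fx))
  writeLines(sprintf("%.17g", x), fx)
  out <- run_python(sprintf(paste(
    "import numpy as np",
    "from scipy.signal import butter, filtfilt",
    "x = np.loadtxt('%s')",
    "b, a = butter(1, [30/500, 40/500], 'bandpass')",
    "np.savetxt('%s.out', filtfilt(b, a, x))", sep = "\n"), fx, fx))
  yp <- scan(paste0(fx, ".out"), quiet = TRUE)
  withr::defer(unlink(paste0(fx, ".out")))
  expect_lt(max(abs(y - yp)[500:4500]), 1e-6)
})

test_that("filters are stable: impulse response energy is finite over 10 s", {
  bank <- design_filter_bank(1000)
  impulse <- c(1, rep(0, 9999))
  for (b in bank$bands) {
    h <- bandpass(impulse, b, zero_phase = FALSE)
    expect_true(is.finite(sum(h^2)))
    expect_lt(max(abs(h[9000:10000])), 1e-6)   # decayed by 9 s
  }
})

test_that("band-pass kills DC and is linear", {
  bank <- design_filter_bank(1000)
  dc <- rep(1, 2000)
  y <- bandpass(lfp_trace(dc, 1000), bank$bands[[1]])$samples
  expect_lt(max(abs(y[200:1800])), 1e-6)
  set.seed(1)
  x <- rnorm(1000)
  b <- bank$bands[[4]]
  expect_equal(bandpass(3.7 * x, b), 3.7 * bandpass(x, b),
               tolerance = 1e-12)
})

test_that("40 Hz sine band ordering matches the analytic magnitude response", {
  fs <- 1000
  t <- (0:9999) / fs
  s <- sin(2 * pi * 40 * t)
  bank <- design_filter_bank(fs)
  pick <- function(lab) bank$bands[[which(vapply(bank$bands,
    function(b) b$label_hz, numeric(1)) == lab)]]
  measured <- vapply(c(30, 40, 120), function(lab)
    rms(bandpass(lfp_trace(s, fs), pick(lab))$samples), numeric(1))
  # zero-phase filtering applies |H|^2
  analytic <- vapply(c(30, 40, 120), function(lab)
    band_magnitude(pick(lab), 40, fs)^2 / sqrt(2), numeric(1))
  expect_equal(measured, analytic, tolerance = 1e-3)
  expect_gt(measured[1], measured[3])
  expect_gt(measured[2], measured[3])
})

test_that("rms closed forms and brute-force equivalence", {
  expect_equal(rms(rep(0, 100)), 0)
  t <- (0:999) / 1000
  expect_equal(rms(sin(2 * pi * 10 * t)), 1 / sqrt(2), tolerance = 1e-6)
  expect_error(rms(numeric(0)), "empty")
  set.seed(5)
  x <- rnorm(137)
  acc <- 0
  for (v in x) acc <- acc + v^2
  expect_equal(rms(x), sqrt(acc / 137), tolerance = 1e-12)
})

test_that("fragment extraction uses equal-length abutting windows", {
  tr <- lfp_trace(seq_len(20000), 1000)
  fr <- extract_fragments(tr, 10, 0.2)
  expect_equal(fr$stimulus, 10001:10200)
  expect_equal(fr$baseline, 9801:10000)
  # call too close to the start is skipped with a notice
  expect_message(fr2 <- extract_fragments(tr, 0.05, 0.2), "skipped")
  expect_null(fr2)
  # property: equal lengths for random calls
  set.seed(6)
  for (i in 1:200) {
    on <- runif(1, 1, 18); du <- runif(1, 0.01, 1)
    fr <- extract_fragments(tr, on, du)
    expect_equal(length(fr$baseline), length(fr$stimulus))
  }
})

test_that("ARS is positive in burst bands and ~0 off-band (clean burst)", {
  ev <- call_events("m", "tet", 5, 0.5)
  lp <- lfp_sim_params(fs_hz = 1000, duration_s = 10,
                       noise = list(model = "white", sd = 1e-8),
                       f_c = 40, base_amplitude = 1, seed = 2)
  trc <- simulate_lfp(ev, lp)
  bank <- design_filter_bank(1000)
  recs <- compute_ars(trc, ev, bank)
  expect_equal(nrow(recs), 19L)
  expect_equal(recs$ars, recs$rms_stimulus - recs$rms_baseline)
  expect_gt(recs$ars[recs$band_hz == 30], 0.1)
  expect_gt(recs$ars[recs$band_hz == 40], 0.1)
  expect_lt(abs(recs$ars[recs$band_hz == 120]), 0.01)
})

test_that("a periodic trace gives ARS ~ 0 (stimulus equals baseline)", {
  fs <- 1000
  t <- (0:19999) / fs
  tr <- lfp_trace(sin(2 * pi * 40 * t), fs)
  ev <- call_events("m", "tet", 10, 0.5)   # 0.5 s = whole periods of 40 Hz
  bank <- design_filter_bank(fs)
  recs <- compute_ars(tr, ev, bank)
  expect_true(all(abs(recs$ars) < 1e-6))
})

test_that("ARS scales linearly with the trace and with burst gain", {
  ev <- call_events("m", "tet", c(3, 6), 0.4)
  bank <- design_filter_bank(500)
  lp1 <- lfp_sim_params(fs_hz = 500, duration_s = 10,
                        noise = list(model = "white", sd = 1e-8),
                        f_c = 40, base_amplitude = 1, gain = 1, seed = 3)
  lp2 <- lfp_sim_params(fs_hz = 500, duration_s = 10,
                        noise = list(model = "white", sd = 1e-8),
                        f_c = 40, base_amplitude = 1, gain = 2, seed = 3)
  r1 <- compute_ars(simulate_lfp(ev, lp1), ev, bank)
  r2 <- compute_ars(simulate_lfp(ev, lp2), ev, bank)
  burst <- r1$band_hz %in% c(30, 40)
  expect_equal(r2$ars[burst], 2 * r1$ars[burst], tolerance = 1e-4)
  # whole-trace scaling: every ars scales exactly
  tr <- simulate_lfp(ev, lp1)
  tr3 <- tr; tr3$samples <- 3 * tr$samples
  r3 <- compute_ars(tr3, ev, bank)
  expect_equal(r3$ars, 3 * r1$ars, tolerance = 1e-9)
})

test_that("calls too close to trace edges are skipped and reported", {
  tr <- lfp_trace(rnorm(2000), 1000)
  ev <- call_events(c("m", "m"), "tet", c(0.05, 1), c(0.2, 0.2))
  bank <- design_filter_bank(1000)
  expect_message(recs <- compute_ars(tr, ev, bank), "skipped")
  expect_equal(attr(recs, "skipped"), 1L)
  expect_equal(nrow(recs), 19L)
})

test_that("per-bird normalization rescales to max |ars| = 1", {
  recs <- data.frame(bird_id = "f", ars = c(-2, 1, 4))
  out <- normalize_within_bird(recs)
  expect_equal(out$ars_norm, c(-0.5, 0.25, 1))
  zero <- normalize_within_bird(data.frame(bird_id = "f", ars = c(0, 0)))
  expect_equal(zero$ars_norm, c(0, 0))
  set.seed(8)
  for (i in 1:20) {
    df <- data.frame(bird_id = sample(c("a", "b"), 30, replace = TRUE),
                     ars = rnorm(30))
    out <- normalize_within_bird(df)
    for (b in c("a", "b")) {
      expect_equal(max(abs(out$ars_norm[out$bird_id == b])), 1)
    }
    expect_true(all(out$ars_norm >= -1 & out$ars_norm <= 1))
  }
})

test_that("log_sq floors tiny values and is monotone in |x| above it", {
  v <- log_sq(c(1e-15, -2, 2, 3))
  expect_true(is.na(v[1]))
  expect_equal(attr(v, "n_floored"), 1L)
  expect_equal(v[2], v[3])
  expect_lt(v[3], v[4])
})

test_that("band selection recovers an injected 45 Hz burst band", {
  set.seed(9)
  ev <- call_events(rep("m", 30), "tet", seq(2, 60, by = 2), 0.25)
  lp <- lfp_sim_params(fs_hz = 500, duration_s = 65,
                       noise = list(model = "white", sd = 0.3),
                       f_c = 45, base_amplitude = 0.5, seed = 10)
  trc <- simulate_lfp(ev, lp)
  bank <- design_filter_bank(500)
  recs <- compute_ars(trc, ev, bank)
  sel <- select_band_of_interest(recs, k = 3)
  expect_true(all(sel$bands %in% c(30, 40, 50)))
  # k = 1 on single-band data names the burst's band
  sel1 <- select_band_of_interest(recs, k = 1)
  expect_equal(sel1$bands, 40)
})

test_that("flat white noise yields a 'no dominant band' flag", {
  set.seed(12)
  ev <- call_events(rep("m", 40), "tet", seq(2, 81, by = 2), 0.25)
  tr <- lfp_trace(rnorm(85 * 500), 500, bird_id = "m")
  bank <- design_filter_bank(500)
  recs <- compute_ars(tr, ev, bank)
  sel <- select_band_of_interest(recs, k = 3)
  expect_true(any(sel$no_dominant_band))
  expect_error(select_band_of_interest(recs, k = 25), "need >= k")
})
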