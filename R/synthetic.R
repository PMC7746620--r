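# Synthetic-data generator: multi-bird call streams with context-dependent
# reply probability/latency, and LFP traces containing stimulus-locked
# narrow-band (low-gamma by default) bursts whose amplitude depends on
# treatment, call type and emitter. The generator defines the "stated
# world" that all recovery tests are run against; it does not attempt
# acoustically realistic call synthesis.

# default call durations (s) used when the caller does not override them
DEFAULT_DURATIONS <- c(stack = 0.10, tet = 0.08, distance = 0.30,
                       kackle = 0.15, whine = 0.45, hat = 0.10,
                       song = 1.50, noise = 0.10)

#' Parameters of the vocal-session simulator
#'
#' Each bird emits baseline calls of each type as independent homogeneous
#' Poisson processes; additionally, for every heard partner call matched
#' by a reply rule, the responder inserts an "answer" with the rule's
#' probability, at the reference onset plus a latency drawn from the
#' latency spec. Answers do not suppress baseline events or other answers
#' (no refractoriness), and answers are only triggered by baseline calls.
#'
#' @param bird_ids character vector of bird names.
#' @param session_length_s session duration (default 600 s).
#' @param rates either one named numeric vector (calls/s per call type,
#'   applied to every bird) or a named list of such vectors per bird.
#' @param reply data.frame of reply rules with columns `responder`,
#'   `ref_type` (call type of the heard reference call), `prob`
#'   (in `[0, 1]`), `answer_type`; `NULL` means no answering.
#' @param latency latency distribution: `list(family = "uniform", min, max)`
#'   or `list(family = "exp_trunc", rate, max)` (truncated exponential);
#'   support must lie in `(0, answer_window_s]`.
#' @param durations named numeric of call durations in seconds.
#' @param day_index,treatment session metadata.
#' @param answer_window_s window the latencies must respect (default 0.5).
#' @param seed optional integer seed; fixed seed gives identical streams.
#' @return Object of class `vocal_sim_params`.
#' @export
vocal_sim_params <- function(bird_ids = c("female", "male"),
                             session_length_s = 600,
                             rates = c(stack = 0.05, tet = 0.05),
                             reply = NULL,
                             latency = list(family = "uniform",
                                            min = 0.05, max = 0.45),
                             durations = DEFAULT_DURATIONS,
                             day_index = 1L, treatment = "NB",
                             answer_window_s = 0.5, seed = NULL) {
  if (!is.list(rates)) {
    rates <- stats::setNames(rep(list(rates), length(bird_ids)), bird_ids)
  }
  for (b in bird_ids) {
    r <- rates[[b]]
    if (is.null(r)) rates[[b]] <- numeric(0)
    else {
      if (any(r < 0) || !all(names(r) %in% CALL_TYPES)) {
        stop("rates must be >= 0 and named by repertoire call types",
             call. = FALSE)
      }
    }
  }
  if (!is.null(reply)) {
    stopifnot(all(c("responder", "ref_type", "prob", "answer_type") %in%
                    names(reply)))
    if (any(reply$prob < 0 | reply$prob > 1)) {
      stop("reply probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  lat_max <- switch(latency$family,
                    uniform = latency$max,
                    exp_trunc = latency$max,
                    stop("unknown latency family '", latency$family, "'",
                         call. = FALSE))
  lat_min <- if (latency$family == "uniform") latency$min else 0
  if (lat_min < 0 || lat_max > answer_window_s || lat_max <= 0) {
    stop("latency support must lie in (0, answer_window_s]", call. = FALSE)
  }
  structure(list(bird_ids = bird_ids, session_length_s = session_length_s,
                 rates = rates, reply = reply, latency = latency,
                 durations = durations, day_index = as.integer(day_index),
                 treatment = treatment, answer_window_s = answer_window_s,
                 seed = seed),
            class = "vocal_sim_params")
}

draw_latency <- function(n, spec) {
  switch(spec$family,
         uniform = stats::runif(n, spec$min, spec$max),
         exp_trunc = {
           # inverse-CDF sampling of Exp(rate) truncated to (0, max]
           u <- stats::runif(n)
           -log(1 - u * (1 - exp(-spec$rate * spec$max))) / spec$rate
         })
}

#' Simulate one multi-bird vocal session
#'
#' @param params a [vocal_sim_params()].
#' @return List of [event_stream()]s, one per bird, sorted by onset.
#'   Answer events carry no marker: downstream metrics must recover the
#'   interaction structure from timing alone, as with real data.
#' @export
simulate_vocal_session <- function(params) {
  stopifnot(inherits(params, "vocal_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  T <- params$session_length_s
  base <- list()
  for (b in params$bird_ids) {
    r <- params$rates[[b]]
    rows <- list()
    for (ct in names(r)) {
      if (r[[ct]] <= 0) next
      n <- stats::rpois(1L, r[[ct]] * T)
      if (n == 0L) next
      rows[[ct]] <- data.frame(
        emitter_id = b, call_type = ct,
        onset_s = sort(stats::runif(n, 0, T)),
        duration_s = unname(params$durations[ct]),
        day_index = params$day_index, treatment = params$treatment,
        stringsAsFactors = FALSE)
    }
    base[[b]] <- rbind_df(c(rows))
  }
  answers <- list()
  if (!is.null(params$reply)) {
    for (ri in seq_len(nrow(params$reply))) {
      rule <- params$reply[ri, ]
      refs <- rbind_df(c(unname(lapply(
        setdiff(params$bird_ids, rule$responder),
        function(b) base[[b]]))))
      if (is.null(refs) || nrow(refs) == 0L) next
      refs <- refs[refs$call_type == rule$ref_type, , drop = FALSE]
      if (nrow(refs) == 0L) next
      hit <- stats::runif(nrow(refs)) < rule$prob
      if (!any(hit)) next
      on <- refs$onset_s[hit] + draw_latency(sum(hit), params$latency)
      keep <- on < params$session_length_s
      if (!any(keep)) next
      answers[[length(answers) + 1L]] <- data.frame(
        emitter_id = rule$responder, call_type = rule$answer_type,
        onset_s = on[keep],
        duration_s = unname(params$durations[rule$answer_type]),
        day_index = params$day_index, treatment = params$treatment,
        stringsAsFactors = FALSE)
    }
  }
  ans <- rbind_df(c(answers))
  lapply(stats::setNames(params$bird_ids, params$bird_ids), function(b) {
    ev <- rbind(base[[b]],
                if (!is.null(ans)) ans[ans$emitter_id == b, , drop = FALSE])
    if (is.null(ev)) {
      ev <- call_events(character(), character(), numeric(), numeric(),
                        integer(), character())
    } else {
      ev <- ev[order(ev$onset_s), , drop = FALSE]
      rownames(ev) <- NULL
    }
    event_stream(b, ev, day_index = params$day_index,
                 treatment = params$treatment,
                 session_length_s = params$session_length_s)
  })
}

#' Parameters of the LFP simulator
#'
#' The trace is `noise + sum of bursts`: each heard call contributes an
#' amplitude-enveloped narrow-band oscillation at `f_c` spanning exactly
#' `[onset, onset + duration)`, with raised-cosine on/off ramps to avoid
#' spectral splatter, random phase, and amplitude
#' `base_amplitude * gain(treatment, call_type, emitter)`.
#'
#' @param fs_hz sampling rate, >= 400 (default 1000; the analysis bank
#'   tops at 200 Hz, so the full 44.1 kHz acquisition rate is unnecessary
#'   for simulation).
#' @param duration_s trace duration in seconds.
#' @param noise `list(model = "white" | "one_over_f", sd > 0)`.
#' @param f_c burst centre frequency in Hz (default 40, low gamma).
#' @param bandwidth burst bandwidth in Hz: each burst's carrier frequency
#'   is drawn uniformly from `f_c +/- bandwidth/2`, so that over many
#'   calls the evoked energy occupies the whole band (e.g. `f_c = 45`,
#'   `bandwidth = 30` emulates a 30-60 Hz low-gamma response). Default 0:
#'   a pure tone at `f_c`.
#' @param base_amplitude burst amplitude before gain.
#' @param ramp_s raised-cosine ramp length (default 10 ms).
#' @param gain burst gain: a single number, a function(event-row) -> gain,
#'   or a data.frame with any of `treatment`, `call_type`, `emitter_id`
#'   plus `gain` (first matching row wins; NA fields match anything;
#'   unmatched events get gain 1). Gains must be >= 0.
#' @param onset_jitter_s sd of Gaussian jitter added to burst onsets.
#' @param seed optional integer seed.
#' @return Object of class `lfp_sim_params`.
#' @export
lfp_sim_params <- function(fs_hz = 1000, duration_s = 600,
                           noise = list(model = "white", sd = 1),
                           f_c = 40, bandwidth = 0, base_amplitude = 1,
                           ramp_s = 0.01, gain = 1, onset_jitter_s = 0,
                           seed = NULL) {
  if (bandwidth < 0 || f_c - bandwidth / 2 <= 0) {
    stop("bandwidth must be >= 0 and leave f_c - bandwidth/2 positive",
         call. = FALSE)
  }
  if (fs_hz < 400) stop("fs_hz must be >= 400 (band plan tops at 200 Hz)",
                        call. = FALSE)
  if (!noise$model %in% c("white", "one_over_f")) {
    stop("noise model must be 'white' or 'one_over_f'", call. = FALSE)
  }
  if (noise$sd <= 0) stop("noise sd must be > 0", call. = FALSE)
  if (is.numeric(gain) && any(gain < 0)) stop("gains must be >= 0",
                                              call. = FALSE)
  if (is.data.frame(gain) && any(gain$gain < 0)) stop("gains must be >= 0",
                                                      call. = FALSE)
  structure(list(fs_hz = fs_hz, duration_s = duration_s, noise = noise,
                 f_c = f_c, bandwidth = bandwidth,
                 base_amplitude = base_amplitude, ramp_s = ramp_s,
                 gain = gain, onset_jitter_s = onset_jitter_s, seed = seed),
            class = "lfp_sim_params")
}

burst_gain <- function(event, gain) {
  if (is.function(gain)) return(gain(event))
  if (is.data.frame(gain)) {
    for (i in seq_len(nrow(gain))) {
      ok <- TRUE
      for (f in intersect(c("treatment", "call_type", "emitter_id"),
                          names(gain))) {
        if (!is.na(gain[[f]][i]) && gain[[f]][i] != event[[f]]) {
          ok <- FALSE; break
        }
      }
      if (ok) return(gain$gain[i])
    }
    return(1)
  }
  gain
}

raised_cosine_env <- function(n, ramp_n) {
  env <- rep(1, n)
  ramp_n <- min(ramp_n, floor(n / 2))
  if (ramp_n > 0L) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / (ramp_n + 1L)))
    env[seq_len(ramp_n)] <- up
    env[(n - ramp_n + 1L):n] <- rev(up)
  }
  env
}

one_over_f_noise <- function(n, sd) {
  # spectral amplitude shaping ~ 1/sqrt(f), rescaled to the requested sd
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y * sd / stats::sd(y)
}

#' Simulate an LFP trace evoked by heard calls
#'
#' @param events_heard call-event data.frame (the calls audible to the
#'   implanted bird); events outside the trace extent are ignored with a
#'   notice. Overlapping calls are allowed; their bursts sum.
#' @param params an [lfp_sim_params()].
#' @param bird_id identity of the implanted bird owning the trace.
#' @return An [lfp_trace()].
#' @export
simulate_lfp <- function(events_heard, params, bird_id = "focal") {
  stopifnot(inherits(params, "lfp_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$fs_hz
  n <- round(params$duration_s * fs)
  trace <- switch(params$noise$model,
                  white = stats::rnorm(n, 0, params$noise$sd),
                  one_over_f = one_over_f_noise(n, params$noise$sd))
  events_heard <- as.data.frame(events_heard)
  n_outside <- 0L
  for (i in seq_len(nrow(events_heard))) {
    ev <- events_heard[i, , drop = FALSE]
    on <- ev$onset_s + if (params$onset_jitter_s > 0)
      stats::rnorm(1L, 0, params$onset_jitter_s) else 0
    i0 <- round(on * fs)
    nd <- max(1L, round(ev$duration_s * fs))
    if (i0 < 0L || i0 + nd > n) { n_outside <- n_outside + 1L; next }
    g <- burst_gain(ev, params$gain)
    if (g <= 0) next
    t <- (seq_len(nd) - 1L) / fs
    phase <- stats::runif(1L, 0, 2 * pi)
    f_burst <- params$f_c + if (params$bandwidth > 0) {
      stats::runif(1L, -params$bandwidth / 2, params$bandwidth / 2)
    } else 0
    burst <- params$base_amplitude * g *
      raised_cosine_env(nd, round(params$ramp_s * fs)) *
      sin(2 * pi * f_burst * (on + t) + phase)
    idx <- (i0 + 1L):(i0 + nd)
    trace[idx] <- trace[idx] + burst
  }
  if (n_outside > 0L) {
    message(n_outside, " event(s) outside the trace extent were ignored")
  }
  lfp_trace(trace, fs, bird_id = bird_id)
}

#' Simulate a full breeding-onset experiment
#'
#' Generates a breeding-onset study design at configurable scale:
#' `n_days_nb` non-breeding and `n_days_b` breeding daytime sessions
#' (streams of every bird plus one LFP trace per focal bird per day,
#' driven by the calls of the other birds), and optionally night-playback
#' sessions with pseudorandomized schedules. One seed governs the whole
#' experiment; per-session sub-seeds are derived deterministically.
#'
#' @param config list, see Details; [default_experiment_config()] supplies
#'   a complete example.
#' @param out_dir optional directory; when given, events, traces (WAV),
#'   schedules and the manifest (JSON, including all true parameters) are
#'   written there in the package's interchange formats.
#' @details Config fields: `bird_ids`, `focal_birds`, `n_days_nb`,
#'   `n_days_b`, `session_length_s`, `rates`, `reply_nb`, `reply_b`
#'   (reply-rule data.frames), `latency`, `fs_hz`, `noise`, `f_c`,
#'   `base_amplitude`, `gain_nb`, `gain_b` (gain specs, see
#'   [lfp_sim_params()]), `playback` (NULL or list with `stimuli`
#'   data.frame (`stimulus_label`, `emitter`, `duration_s`),
#'   `repetitions`, `gap_range_s`, `nights_per_treatment`), `seed`.
#' @return List with `streams` (per day), `traces` (per focal bird, day),
#'   `playback` (schedules and night traces, if configured) and
#'   `manifest` (true parameters).
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  cf <- utils::modifyList(default_experiment_config(), config)
  seed <- if (is.null(cf$seed)) 1L else as.integer(cf$seed)
  days <- c(rep("NB", cf$n_days_nb), rep("B", cf$n_days_b))
  streams <- list(); traces <- list()
  for (d in seq_along(days)) {
    trt <- days[d]
    vp <- vocal_sim_params(
      bird_ids = cf$bird_ids, session_length_s = cf$session_length_s,
      rates = cf$rates,
      reply = if (trt == "NB") cf$reply_nb else cf$reply_b,
      latency = cf$latency, day_index = d, treatment = trt,
      seed = seed + 101L * d)
    ss <- simulate_vocal_session(vp)
    streams[[d]] <- ss
    for (fb in cf$focal_birds) {
      heard <- rbind_df(unname(lapply(
        ss[setdiff(cf$bird_ids, fb)], function(s) s$events)))
      lp <- lfp_sim_params(
        fs_hz = cf$fs_hz, duration_s = cf$session_length_s,
        noise = cf$noise, f_c = cf$f_c, bandwidth = cf$bandwidth,
        base_amplitude = cf$base_amplitude,
        gain = if (trt == "NB") cf$gain_nb else cf$gain_b,
        seed = seed + 101L * d + 13L * match(fb, cf$focal_birds))
      traces[[paste(fb, d, sep = ".")]] <- list(
        bird_id = fb, day_index = d, treatment = trt,
        trace = simulate_lfp(heard, lp, bird_id = fb),
        heard = heard)
    }
  }
  playback <- NULL
  if (!is.null(cf$playback)) {
    pb <- cf$playback
    playback <- list()
    nights <- c(rep("NB", pb$nights_per_treatment),
                rep("B", pb$nights_per_treatment))
    for (ni in seq_along(nights)) {
      trt <- nights[ni]
      sched <- build_schedule(pb$stimuli, repetitions = pb$repetitions,
                              gap_range_s = pb$gap_range_s,
                              seed = seed + 977L * ni)
      sched$presentations$treatment <- trt
      sched$presentations$day_index <- ni
      night_len <- max(sched$presentations$onset_s +
                         sched$presentations$duration_s) + 5
      for (fb in cf$focal_birds) {
        ev <- sched$presentations
        ev$call_type <- ifelse(ev$stimulus_label %in% CALL_TYPES,
                               ev$stimulus_label, "noise")
        ev$emitter_id <- ev$emitter
        lp <- lfp_sim_params(
          fs_hz = cf$fs_hz, duration_s = night_len, noise = cf$noise,
          f_c = cf$f_c, bandwidth = cf$bandwidth,
          base_amplitude = cf$base_amplitude,
          gain = if (trt == "NB") cf$gain_nb else cf$gain_b,
          seed = seed + 977L * ni + 13L * match(fb, cf$focal_birds))
        playback[[paste(fb, ni, sep = ".")]] <- list(
          bird_id = fb, night_index = ni, treatment = trt,
          schedule = sched, trace = simulate_lfp(ev, lp, bird_id = fb))
      }
    }
  }
  manifest <- list(
    bird_ids = cf$bird_ids, focal_birds = cf$focal_birds,
    n_days_nb = cf$n_days_nb, n_days_b = cf$n_days_b,
    session_length_s = cf$session_length_s, rates = cf$rates,
    reply_nb = cf$reply_nb, reply_b = cf$reply_b, latency = cf$latency,
    fs_hz = cf$fs_hz, noise = cf$noise, f_c = cf$f_c,
    bandwidth = cf$bandwidth, base_amplitude = cf$base_amplitude,
    gain_nb = cf$gain_nb, gain_b = cf$gain_b, seed = seed,
    null_effect = identical(cf$gain_nb, cf$gain_b))
  res <- list(streams = streams, traces = traces, playback = playback,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    all_streams <- unlist(streams, recursive = FALSE)
    write_events(all_streams, file.path(out_dir, "events.csv"))
    for (nm in names(traces)) {
      write_trace(traces[[nm]]$trace,
                  file.path(out_dir, paste0("trace_", nm, ".wav")))
    }
    if (!is.null(playback)) {
      for (nm in names(playback)) {
        utils::write.csv(playback[[nm]]$schedule$presentations,
                         file.path(out_dir, paste0("schedule_", nm, ".csv")),
                         row.names = FALSE, quote = FALSE)
        write_trace(playback[[nm]]$trace,
                    file.path(out_dir, paste0("night_", nm, ".wav")))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' Default experiment configuration
#'
#' A breeding-onset design at desk scale: a trio (female, male,
#' single male) with the mated pair implanted; 3 non-breeding + 4 breeding
#' days; contact-call Poisson rates with treatment-dependent reply
#' probabilities; white-noise LFP background with 40 Hz (low-gamma)
#' stimulus-locked bursts; optional two-nights-per-context playback of the
#' repertoire plus a 100 ms white-noise control, 30 repetitions each.
#'
#' @return Named list of configuration fields (see
#'   [simulate_experiment()]).
#' @export
default_experiment_config <- function() {
  list(
    bird_ids = c("female", "male", "single"),
    focal_birds = c("female", "male"),
    n_days_nb = 3L, n_days_b = 4L,
    session_length_s = 300,
    rates = c(stack = 0.05, tet = 0.05),
    reply_nb = data.frame(responder = c("female", "male"),
                          ref_type = c("stack", "stack"),
                          prob = c(0.2, 0.2),
                          answer_type = c("stack", "stack"),
                          stringsAsFactors = FALSE),
    reply_b = data.frame(responder = c("female", "male"),
                         ref_type = c("stack", "stack"),
                         prob = c(0.5, 0.5),
                         answer_type = c("stack", "stack"),
                         stringsAsFactors = FALSE),
    latency = list(family = "uniform", min = 0.05, max = 0.45),
    fs_hz = 500, noise = list(model = "white", sd = 1),
    f_c = 45, bandwidth = 30, base_amplitude = 0.5,
    gain_nb = 1, gain_b = 1,
    playback = NULL,
    seed = 1L
  )
}
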