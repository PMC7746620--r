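# Night-playback experiment support: stimulus peak normalization,
# pseudorandom schedule construction (no immediate stimulus repeats),
# and per-stimulus ARS aggregation across repetitions.

#' Peak-normalize a stimulus waveform
#'
#' Scales the waveform so its maximum absolute sample equals
#' `10^(target_db / 20)` (default -5 dB re full scale, i.e. 0.56234...);
#' the shape is otherwise unchanged.
#'
#' @param waveform numeric vector, not all zero.
#' @param target_db target peak level in dB re full scale (default -5).
#' @return Scaled waveform.
#' @export
normalize_peak <- function(waveform, target_db = -5) {
  peak <- max(abs(waveform))
  if (peak == 0) stop("cannot peak-normalize an all-zero waveform",
                      call. = FALSE)
  waveform * (10^(target_db / 20) / peak)
}

#' Build a pseudorandomized playback schedule
#'
#' Every stimulus appears exactly `repetitions` times; the order is
#' shuffled under the pseudorandomization constraint that no two
#' consecutive presentations share a stimulus, with inter-trial gaps drawn
#' uniformly from `gap_range_s`. Reproducible under a fixed seed.
#'
#' @param stimuli data.frame with columns `stimulus_label`, `emitter`,
#'   `duration_s` (one row per distinct stimulus; >= 2 rows).
#' @param repetitions presentations per stimulus (default 30).
#' @param gap_range_s length-2 numeric, uniform inter-trial gap bounds in
#'   seconds (default 8-12 s).
#' @param seed optional integer seed.
#' @param start_s onset of the first presentation (default 10 s).
#' @return Object of class `playback_schedule`: list with `presentations`
#'   (data.frame `stimulus_label`, `emitter`, `onset_s`, `duration_s`),
#'   `repetitions`, `gap_range_s`, `seed`.
#' @export
build_schedule <- function(stimuli, repetitions = 30,
                           gap_range_s = c(8, 12), seed = NULL,
                           start_s = 10) {
  stimuli <- as.data.frame(stimuli)
  stopifnot(all(c("stimulus_label", "emitter", "duration_s") %in%
                  names(stimuli)))
  n_stim <- nrow(stimuli)
  if (n_stim < 2L) {
    stop("need >= 2 distinct stimuli to satisfy the no-immediate-repeat ",
         "constraint", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  remaining <- rep(as.integer(repetitions), n_stim)
  total <- sum(remaining)
  order_idx <- integer(total)
  prev <- 0L
  for (slot in seq_len(total)) {
    slots_left <- total - slot + 1L
    cand <- which(remaining > 0L & seq_len(n_stim) != prev)
    if (length(cand) == 0L) {
      stop("pseudorandomization infeasible: one stimulus dominates the ",
           "remaining slots", call. = FALSE)
    }
    forced <- cand[2L * remaining[cand] - 1L >= slots_left]
    pick <- if (length(forced) > 0L) {
      forced[sample.int(length(forced), 1L)]
    } else {
      cand[sample.int(length(cand), 1L,
                      prob = remaining[cand])]
    }
    order_idx[slot] <- pick
    remaining[pick] <- remaining[pick] - 1L
    prev <- pick
  }
  dur <- stimuli$duration_s[order_idx]
  gaps <- stats::runif(total, gap_range_s[1L], gap_range_s[2L])
  onsets <- start_s + cumsum(c(0, (dur + gaps)[-total]))
  structure(list(
    presentations = data.frame(
      stimulus_label = stimuli$stimulus_label[order_idx],
      emitter = stimuli$emitter[order_idx],
      onset_s = onsets, duration_s = dur, stringsAsFactors = FALSE),
    repetitions = as.integer(repetitions),
    gap_range_s = gap_range_s, seed = seed), class = "playback_schedule")
}

#' @export
print.playback_schedule <- function(x, ...) {
  cat(sprintf(
    "<playback_schedule> %d presentations (%d stimuli x %d repetitions)\n",
    nrow(x$presentations),
    length(unique(x$presentations$stimulus_label)), x$repetitions))
  invisible(x)
}

#' Score a playback session
#'
#' Treats every presentation as a heard call, computes ARS records via
#' [compute_ars()] in the requested bands, and aggregates the mean ARS
#' across repetitions per (stimulus, emitter, band). Presentations too
#' close to the trace edges are skipped and reported.
#'
#' @param trace night [lfp_trace()].
#' @param schedule a [build_schedule()] result (or its `presentations`
#'   data.frame, possibly with `treatment`/`day_index` columns attached).
#' @param bank a [design_filter_bank()].
#' @param bands_of_interest band labels to retain (default c(30, 40, 50),
#'   the low-gamma bands; `NULL` keeps all bands).
#' @return List with `per_presentation` (one ARS record per presentation
#'   and band), `per_presentation_mean` (one row per presentation: the
#'   mean ARS over the retained bands, the night-analysis outcome scale),
#'   and `summary` (mean ARS per stimulus, emitter and band, with
#'   `n_presentations`).
#' @export
score_playback <- function(trace, schedule, bank,
                           bands_of_interest = c(30, 40, 50)) {
  pres <- if (inherits(schedule, "playback_schedule"))
    schedule$presentations else as.data.frame(schedule)
  recs <- compute_ars(trace, pres, bank)
  if (!is.null(bands_of_interest)) {
    recs <- recs[recs$band_hz %in% bands_of_interest, , drop = FALSE]
  }
  # per-presentation mean over the retained bands: one observation per
  # presentation avoids pseudo-replicating the same analysis window
  pkey <- interaction(recs$stimulus_label, recs$emitter, recs$onset_s,
                      drop = TRUE)
  ppm <- lapply(split(recs, pkey), function(g) {
    row <- g[1L, setdiff(names(g), c("band_hz", "rms_baseline",
                                     "rms_stimulus", "ars")), drop = FALSE]
    row$ars <- mean(g$ars)
    row
  })
  ppm <- rbind_df(ppm)
  if (!is.null(ppm)) {
    ppm <- ppm[order(ppm$onset_s), , drop = FALSE]
    rownames(ppm) <- NULL
  }
  key <- interaction(recs$stimulus_label, recs$emitter, recs$band_hz,
                     drop = TRUE)
  agg <- lapply(split(recs, key), function(g) data.frame(
    stimulus_label = g$stimulus_label[1L], emitter = g$emitter[1L],
    band_hz = g$band_hz[1L], mean_ars = mean(g$ars),
    n_presentations = nrow(g), stringsAsFactors = FALSE))
  summary <- rbind_df(c(agg))
  summary <- summary[order(summary$stimulus_label, summary$emitter,
                           summary$band_hz), , drop = FALSE]
  rownames(summary) <- NULL
  list(per_presentation = recs, per_presentation_mean = ppm,
       summary = summary)
}
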