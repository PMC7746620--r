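#' duetgamma: turn-taking metrics and low-gamma LFP response scoring
#'
#' Tools for analysing synchronized vocal and neural telemetry from
#' group-living songbirds: call-event tables, turn-taking statistics
#' (reply strength, reply latency), a 10-200 Hz Butterworth filter bank
#' for local field potentials, the baseline-corrected Auditory Response
#' Strength (ARS), playback-experiment scoring, and posterior-draw
#' summaries of linear mixed models.
#'
#' @keywords internal
"_PACKAGE"

#' Call repertoire
#'
#' The vocalization types recognised in event tables: the contact calls
#' (stack, tet, distance), the breeding calls (kackle, whine), hat calls,
#' song (males only) and a generic "noise" label used for non-vocal sounds
#' and playback controls.
#'
#' @format Character vector of the eight admissible `call_type` values.
#' @export
CALL_TYPES <- c("stack", "tet", "distance", "kackle", "whine",
                "hat", "song", "noise")

#' Breeding-call types pooled in breeding-call tallies
#' @format Character vector (kackle, whine).
#' @export
BREEDING_CALL_TYPES <- c("kackle", "whine")

#' Treatment levels: non-breeding and breeding context
#' @format Character vector c("NB", "B").
#' @export
TREATMENTS <- c("NB", "B")

#' Build and validate a call-event table
#'
#' One row per vocalization. All times are session-relative seconds on a
#' single clock shared with the LFP traces (synchrony of the transmitters
#' is an input assumption). Intervals are half-open: an event occupies
#' `[onset_s, onset_s + duration_s)`.
#'
#' @param emitter_id character, bird identity of the emitter.
#' @param call_type character, one of [CALL_TYPES].
#' @param onset_s numeric, onset in seconds (finite, >= 0).
#' @param duration_s numeric, strictly positive duration in seconds.
#' @param day_index integer recording day.
#' @param treatment "NB" (non-breeding) or "B" (breeding).
#' @return A `data.frame` with the six columns above, validated.
#' @export
call_events <- function(emitter_id, call_type, onset_s, duration_s,
                        day_index = 1L, treatment = "NB") {
  if (length(onset_s) == 0L) {
    return(data.frame(emitter_id = character(), call_type = character(),
                      onset_s = numeric(), duration_s = numeric(),
                      day_index = integer(), treatment = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    emitter_id = as.character(emitter_id),
    call_type = as.character(call_type),
    onset_s = as.numeric(onset_s),
    duration_s = as.numeric(duration_s),
    day_index = as.integer(day_index),
    treatment = as.character(treatment),
    stringsAsFactors = FALSE
  )
  validate_call_events(df)
}

#' Validate a call-event data frame
#'
#' @param df data.frame with columns emitter_id, call_type, onset_s,
#'   duration_s, day_index, treatment.
#' @return `df`, invisibly unchanged, or an error describing the violation.
#' @export
validate_call_events <- function(df) {
  required <- c("emitter_id", "call_type", "onset_s", "duration_s",
                "day_index", "treatment")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("event table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(df)
  bad_type <- setdiff(unique(df$call_type), CALL_TYPES)
  if (length(bad_type) > 0L) {
    stop("unknown call_type value(s): ", paste(bad_type, collapse = ", "),
         "; repertoire is: ", paste(CALL_TYPES, collapse = ", "),
         call. = FALSE)
  }
  bad_trt <- setdiff(unique(df$treatment), TREATMENTS)
  if (length(bad_trt) > 0L) {
    stop("unknown treatment value(s): ", paste(bad_trt, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$onset_s)) || any(df$onset_s < 0)) {
    stop("onset_s must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(df$duration_s)) || any(df$duration_s <= 0)) {
    stop("duration_s must be finite and strictly positive", call. = FALSE)
  }
  df
}

#' Construct an event stream (one bird, one session)
#'
#' An event stream holds the validated, onset-sorted calls of a single
#' bird during one recording session (one day under one treatment).
#'
#' @param bird_id character scalar.
#' @param events call-event data.frame (see [call_events()]); all rows
#'   must share `bird_id`, `day_index` and `treatment`.
#' @param day_index,treatment session metadata; defaulted from `events`
#'   when the table is non-empty.
#' @param session_length_s session duration in seconds (defaults to the
#'   last event offset).
#' @return An object of class `event_stream`: a list with fields
#'   `bird_id`, `events`, `day_index`, `treatment`, `session_length_s`.
#' @export
event_stream <- function(bird_id, events, day_index = NULL,
                         treatment = NULL, session_length_s = NULL) {
  events <- validate_call_events(events)
  if (nrow(events) > 0L) {
    if (!all(events$emitter_id == bird_id)) {
      stop("all events in a stream must be emitted by '", bird_id, "'",
           call. = FALSE)
    }
    if (is.null(day_index)) day_index <- events$day_index[1L]
    if (is.null(treatment)) treatment <- events$treatment[1L]
    if (length(unique(events$day_index)) > 1L ||
        length(unique(events$treatment)) > 1L) {
      stop("all events in a stream must share day_index and treatment",
           call. = FALSE)
    }
    if (is.unsorted(events$onset_s)) {
      message("event stream for '", bird_id, "' was unsorted; sorting by onset")
      events <- events[order(events$onset_s), , drop = FALSE]
      rownames(events) <- NULL
    }
  } else {
    if (is.null(day_index)) day_index <- 1L
    if (is.null(treatment)) treatment <- "NB"
  }
  if (is.null(session_length_s)) {
    session_length_s <- if (nrow(events) > 0L)
      max(events$onset_s + events$duration_s) else 0
  }
  structure(
    list(bird_id = as.character(bird_id), events = events,
         day_index = as.integer(day_index),
         treatment = as.character(treatment),
         session_length_s = as.numeric(session_length_s)),
    class = "event_stream"
  )
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> bird %s, day %d, %s: %d events over %.1f s\n",
              x$bird_id, x$day_index, x$treatment, nrow(x$events),
              x$session_length_s))
  invisible(x)
}

#' Interaction analysis configuration
#'
#' Windows used throughout the turn-taking and call-context analysis:
#' a call of another bird counts as an answer when its onset falls within
#' `answer_window_s` (default 0.5 s) after the reference onset; the
#' optional peri-event histogram spans `peri_window_s` (default 4 s) either
#' side of the onset in `bin_width_s` (default 50 ms) bins; a call is
#' "isolated" when no other sound occurs within `isolation_gap_s`
#' (default 5 s) before or after it.
#'
#' @param answer_window_s,peri_window_s,bin_width_s,isolation_gap_s
#'   strictly positive seconds; `answer_window_s` must not exceed
#'   `peri_window_s`.
#' @return Object of class `interaction_config`.
#' @export
interaction_config <- function(answer_window_s = 0.5, peri_window_s = 4,
                               bin_width_s = 0.05, isolation_gap_s = 5) {
  vals <- c(answer_window_s = answer_window_s, peri_window_s = peri_window_s,
            bin_width_s = bin_width_s, isolation_gap_s = isolation_gap_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all interaction_config values must be finite and > 0; got: ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (answer_window_s > peri_window_s) {
    stop("answer_window_s must be <= peri_window_s", call. = FALSE)
  }
  structure(as.list(vals), class = "interaction_config")
}

#' Construct an LFP trace
#'
#' A uniformly sampled single-channel neural signal sharing the session
#' clock of the event streams.
#'
#' @param samples numeric vector, finite.
#' @param fs_hz sampling rate (samples/second).
#' @param bird_id identity of the implanted bird.
#' @param t0_s session time of the first sample (default 0).
#' @return Object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs_hz, bird_id = "bird", t0_s = 0) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("trace samples must be finite", call. = FALSE)
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  structure(
    list(bird_id = as.character(bird_id), samples = samples,
         fs_hz = as.numeric(fs_hz), t0_s = as.numeric(t0_s)),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> bird %s: %d samples @ %g Hz (%.1f s from t0=%g s)\n",
              x$bird_id, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz, x$t0_s))
  invisible(x)
}
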