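# Turn-taking metrics on event streams. Conventions (documented, fixed):
# answers are defined on onsets only; the answer window is onset-exclusive
# and end-inclusive, (ref_onset, ref_onset + answer_window_s]; the
# baseline window for reply strength is [ref_onset - answer_window_s,
# ref_onset); self-replies are excluded by construction.

# counts of sorted vector v with value <= x (cnt_le) or < x (cnt_lt)
cnt_le <- function(x, v) findInterval(x, v)
cnt_lt <- function(x, v) findInterval(x, v, left.open = TRUE)

#' Find answer links between two birds
#'
#' For every call in `reference`, links every call of `responder` whose
#' onset lies in `(ref.onset, ref.onset + answer_window_s]`. Latency is
#' the onset difference. A call exactly at the reference onset is not an
#' answer (onset-exclusive window).
#'
#' @param reference,responder [event_stream()]s of two distinct birds.
#' @param cfg an [interaction_config()].
#' @return Data frame of answer links: `ref_index`, `ref_onset`,
#'   `ref_type`, `ans_index`, `ans_onset`, `ans_type`, `latency_s`
#'   (in `(0, answer_window_s]`), plus `ref_bird`/`ans_bird`.
#' @export
find_answers <- function(reference, responder, cfg = interaction_config()) {
  stopifnot(inherits(reference, "event_stream"),
            inherits(responder, "event_stream"))
  if (identical(reference$bird_id, responder$bird_id)) {
    stop("reference and responder must be distinct birds (self-replies ",
         "are excluded)", call. = FALSE)
  }
  w <- cfg$answer_window_s
  ro <- reference$events$onset_s
  ao <- responder$events$onset_s
  links <- vector("list", length(ro))
  for (i in seq_along(ro)) {
    from <- cnt_le(ro[i], ao) + 1L     # first onset strictly after ref
    to <- cnt_le(ro[i] + w, ao)        # last onset <= ref + w
    if (to >= from) {
      j <- from:to
      links[[i]] <- data.frame(
        ref_index = i, ref_onset = ro[i],
        ref_type = reference$events$call_type[i],
        ans_index = j, ans_onset = ao[j],
        ans_type = responder$events$call_type[j],
        latency_s = ao[j] - ro[i],
        ref_bird = reference$bird_id, ans_bird = responder$bird_id,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind_df(c(links))
  if (is.null(out)) {
    out <- data.frame(ref_index = integer(), ref_onset = numeric(),
                      ref_type = character(), ans_index = integer(),
                      ans_onset = numeric(), ans_type = character(),
                      latency_s = numeric(), ref_bird = character(),
                      ans_bird = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Reply strength of a focal bird toward a partner's calls
#'
#' Over all partner calls of the reference type, counts the focal bird's
#' calls of the focal type with onsets in the 500 ms (by default) window
#' after each reference onset (`n_response`) and in the 500 ms window
#' before it (`n_baseline`), then
#' `rs = (n_response - n_baseline) / (n_response + n_baseline)`.
#' `rs` is `NA` (missing, not NaN arithmetic) when both counts are zero.
#'
#' @param focal [event_stream()] of the replying bird.
#' @param partner [event_stream()] of the bird whose calls are references.
#' @param call_pair length-2 character: `c(focal_type, partner_type)`;
#'   symmetric interactions use the same type twice, the asymmetric
#'   tet-stack/stack-tet interactions differ.
#' @param cfg an [interaction_config()].
#' @return List of class `reply_strength_result`: `rs`, `n_response`,
#'   `n_baseline`, `n_reference_calls`, plus the call pair.
#' @export
reply_strength <- function(focal, partner, call_pair,
                           cfg = interaction_config()) {
  stopifnot(inherits(focal, "event_stream"), inherits(partner, "event_stream"),
            length(call_pair) == 2L)
  if (identical(focal$bird_id, partner$bird_id)) {
    stop("focal and partner must be distinct birds", call. = FALSE)
  }
  if (!all(call_pair %in% CALL_TYPES)) {
    stop("call_pair must be drawn from the repertoire", call. = FALSE)
  }
  w <- cfg$answer_window_s
  refs <- partner$events$onset_s[partner$events$call_type == call_pair[2L]]
  fo <- focal$events$onset_s[focal$events$call_type == call_pair[1L]]
  n_resp <- sum(cnt_le(refs + w, fo) - cnt_le(refs, fo))
  n_base <- sum(cnt_lt(refs, fo) - cnt_lt(refs - w, fo))
  rs <- if (n_resp + n_base > 0L) (n_resp - n_base) / (n_resp + n_base)
        else NA_real_
  structure(list(rs = rs, n_response = n_resp, n_baseline = n_base,
                 n_reference_calls = length(refs),
                 focal_type = call_pair[1L], partner_type = call_pair[2L]),
            class = "reply_strength_result")
}

#' @export
print.reply_strength_result <- function(x, ...) {
  cat(sprintf(
    "<reply_strength> %s answering %s: RS = %s (Nresp %d, Nbase %d, %d refs)\n",
    x$focal_type, x$partner_type,
    ifelse(is.na(x$rs), "NA", sprintf("%.3f", x$rs)),
    x$n_response, x$n_baseline, x$n_reference_calls))
  invisible(x)
}

#' Mean reply latency per group
#'
#' When a reference call received several answers, only the first answer
#' defines that reference's latency (all answers still count toward reply
#' strength). Latencies are then averaged within groups; empty groups are
#' missing, with a notice.
#'
#' @param links answer-link data.frame from [find_answers()] (optionally
#'   row-bound across dyads/sessions, with extra grouping columns added).
#' @param group_cols character vector of column names in `links` to group
#'   by, e.g. `c("ref_type", "ans_type")` for the call-interaction groups;
#'   `NULL` pools everything.
#' @return Data frame with the grouping columns, `n_links` (references
#'   with at least one answer) and `mean_latency_s`.
#' @export
reply_latency <- function(links, group_cols = NULL) {
  if (nrow(links) == 0L) {
    message("no answer links: reply latency is missing")
    out <- data.frame(n_links = 0L, mean_latency_s = NA_real_)
    return(out)
  }
  # first answer per reference call (per dyad)
  key <- interaction(links$ref_bird, links$ans_bird, links$ref_index,
                     drop = TRUE)
  first <- rbind_df(lapply(split(links, key), function(g)
    g[which.min(g$latency_s), , drop = FALSE]))
  if (is.null(group_cols)) {
    return(data.frame(n_links = nrow(first),
                      mean_latency_s = mean(first$latency_s)))
  }
  stopifnot(all(group_cols %in% names(first)))
  gk <- interaction(first[group_cols], drop = TRUE)
  agg <- lapply(split(first, gk), function(g) {
    cbind(g[1L, group_cols, drop = FALSE],
          data.frame(n_links = nrow(g), mean_latency_s = mean(g$latency_s)))
  })
  out <- do.call(rbind, c(agg))
  out[order(gk[!duplicated(gk)]), , drop = FALSE]
}

#' Classify the acoustic context of one call
#'
#' Relative to a focal (implanted) bird, a call is:
#' \describe{
#'   \item{isolated}{no other event of any bird overlaps the open window
#'     `(onset - isolation_gap_s, onset + duration + isolation_gap_s)`;}
#'   \item{answer_by_focal}{the call was emitted by another bird and the
#'     focal bird calls within `(onset, onset + answer_window_s]`;}
#'   \item{answered_by_partner}{the call's onset falls within
#'     `(f.onset, f.onset + answer_window_s]` of some focal call `f`
#'     (i.e. the call is itself an answer to the focal bird);}
#'   \item{other}{none of the above.}
#' }
#' When both answer rules hold, `answer_by_focal` wins. Calls emitted by
#' the focal bird itself can only be `isolated` or `other`.
#'
#' @param call single-row call-event data.frame (or list with
#'   `emitter_id`, `onset_s`, `duration_s`).
#' @param streams list of [event_stream()]s covering all birds in the
#'   session (the call's own stream included).
#' @param cfg an [interaction_config()].
#' @param focal_id bird identity of the focal (implanted) bird.
#' @return Character scalar label.
#' @export
classify_call_context <- function(call, streams, cfg = interaction_config(),
                                  focal_id) {
  gap <- cfg$isolation_gap_s
  w <- cfg$answer_window_s
  on <- call$onset_s; du <- call$duration_s; em <- call$emitter_id
  win_lo <- on - gap
  win_hi <- on + du + gap
  focal_onsets <- numeric(0)
  overlap <- FALSE
  for (s in streams) {
    ev <- s$events
    if (s$bird_id == focal_id) focal_onsets <- ev$onset_s
    if (nrow(ev) == 0L) next
    self <- s$bird_id == em & abs(ev$onset_s - on) < 1e-12 &
      abs(ev$duration_s - du) < 1e-12
    hit <- ev$onset_s < win_hi & (ev$onset_s + ev$duration_s) > win_lo & !self
    if (any(hit)) overlap <- TRUE
  }
  if (!overlap) return("isolated")
  if (em != focal_id) {
    if (cnt_le(on + w, focal_onsets) - cnt_le(on, focal_onsets) > 0L) {
      return("answer_by_focal")
    }
    if (cnt_lt(on, focal_onsets) - cnt_lt(on - w, focal_onsets) > 0L) {
      return("answered_by_partner")
    }
  }
  "other"
}

#' Classify the contexts of every call in a stream
#'
#' @param stream [event_stream()] whose calls are to be labelled (usually
#'   a partner stream heard by the focal bird).
#' @inheritParams classify_call_context
#' @return Character vector of labels, one per event of `stream`.
#' @export
classify_contexts <- function(stream, streams, cfg = interaction_config(),
                              focal_id) {
  ev <- stream$events
  vapply(seq_len(nrow(ev)), function(i)
    classify_call_context(ev[i, , drop = FALSE], streams, cfg, focal_id),
    character(1))
}

#' Daily call counts per type
#'
#' Counts events per (day, treatment, call type), with zero rows for
#' repertoire types absent from the stream so the counts always partition
#' the events. With `pool_breeding = TRUE` an extra `"breeding"` row per
#' day pools kackle and whine, the breeding-call tally.
#'
#' @param stream an [event_stream()].
#' @param pool_breeding add pooled breeding-call rows (default FALSE).
#' @return Data frame `bird_id`, `day_index`, `treatment`, `call_type`,
#'   `n`.
#' @export
daily_call_counts <- function(stream, pool_breeding = FALSE) {
  ev <- stream$events
  tab <- table(factor(ev$call_type, levels = CALL_TYPES))
  out <- data.frame(bird_id = stream$bird_id, day_index = stream$day_index,
                    treatment = stream$treatment,
                    call_type = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (pool_breeding) {
    out <- rbind(out, data.frame(
      bird_id = stream$bird_id, day_index = stream$day_index,
      treatment = stream$treatment, call_type = "breeding",
      n = sum(out$n[out$call_type %in% BREEDING_CALL_TYPES]),
      stringsAsFactors = FALSE))
  }
  out
}

#' Peri-event call histogram
#'
#' Optional export of the peri-event structure underlying the reply
#' metrics: counts of the focal bird's call onsets around each partner
#' reference onset, over `[-peri_window_s, +peri_window_s)` in
#' `bin_width_s` bins (defaults: 4 s either side, 50 ms bins). Reply
#' strength itself uses only the two `answer_window_s` counts.
#'
#' @inheritParams reply_strength
#' @return Data frame `bin_start_s`, `bin_end_s`, `n`.
#' @export
peri_event_histogram <- function(focal, partner, call_pair,
                                 cfg = interaction_config()) {
  refs <- partner$events$onset_s[partner$events$call_type == call_pair[2L]]
  fo <- focal$events$onset_s[focal$events$call_type == call_pair[1L]]
  edges <- seq(-cfg$peri_window_s, cfg$peri_window_s, by = cfg$bin_width_s)
  rel <- as.vector(outer(fo, refs, "-"))
  rel <- rel[rel >= -cfg$peri_window_s & rel < cfg$peri_window_s]
  counts <- if (length(rel) > 0L) {
    tabulate(findInterval(rel, edges), nbins = length(edges) - 1L)
  } else rep(0L, length(edges) - 1L)
  data.frame(bin_start_s = edges[-length(edges)], bin_end_s = edges[-1L],
             n = counts)
}
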