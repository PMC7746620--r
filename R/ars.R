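# LFP Auditory Response Strength (ARS): for each heard call and each
# filter-bank band, the RMS of the band-filtered trace during the call
# minus the RMS over an equal-length window immediately before the onset.

#' Root mean square of a segment
#'
#' @param x nonempty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("rms of an empty segment is undefined",
                            call. = FALSE)
  sqrt(mean(x^2))
}

# Sample-index bounds of the stimulus and baseline fragments of one call,
# or NULL when the baseline would run off the start (or the stimulus off
# the end) of the trace. 1-based, inclusive.
fragment_indices <- function(trace, onset_s, duration_s) {
  fs <- trace$fs_hz
  i0 <- round((onset_s - trace$t0_s) * fs)      # samples before onset
  nd <- max(1L, round(duration_s * fs))         # fragment length
  if (i0 - nd < 0L || i0 + nd > length(trace$samples)) return(NULL)
  list(stim = c(i0 + 1L, i0 + nd), base = c(i0 - nd + 1L, i0), n = nd)
}

#' Extract the baseline and stimulus fragments for one call
#'
#' The stimulus fragment covers `[onset, onset + duration)`; the baseline
#' fragment is the equal-length window immediately before the onset,
#' `[onset - duration, onset)`. Both are cut on the same clock as the
#' events.
#'
#' @param trace an [lfp_trace()].
#' @param onset_s,duration_s call timing in seconds.
#' @return List with numeric vectors `baseline` and `stimulus` (equal
#'   length), or `NULL` (with a message) when the call is too close to the
#'   trace edges for a full baseline.
#' @export
extract_fragments <- function(trace, onset_s, duration_s) {
  idx <- fragment_indices(trace, onset_s, duration_s)
  if (is.null(idx)) {
    message(sprintf(
      "call at %.3f s (duration %.3f s) skipped: insufficient trace for baseline/stimulus",
      onset_s, duration_s))
    return(NULL)
  }
  list(baseline = trace$samples[idx$base[1L]:idx$base[2L]],
       stimulus = trace$samples[idx$stim[1L]:idx$stim[2L]])
}

#' Compute Auditory Response Strength records
#'
#' For every (call, band) pair: band-filter the whole trace once
#' (zero-phase), then take `ars = rms(stimulus) - rms(baseline)` on the
#' filtered signal. Calls whose baseline or stimulus window falls outside
#' the trace are skipped and reported in the `"skipped"` attribute.
#'
#' @param trace an [lfp_trace()].
#' @param calls call-event data.frame (columns `onset_s`, `duration_s`;
#'   any additional metadata columns are carried through). Works equally
#'   for playback schedules with `stimulus_label` columns.
#' @param bank a [design_filter_bank()] whose `fs_hz` matches the trace.
#' @param zero_phase passed to [bandpass()].
#' @return Data frame with one row per (call, band): the call's metadata
#'   columns plus `bird_id`, `band_hz`, `rms_baseline`, `rms_stimulus`,
#'   `ars`. Attribute `"skipped"` holds the row indices of skipped calls.
#' @export
compute_ars <- function(trace, calls, bank, zero_phase = TRUE) {
  stopifnot(inherits(trace, "lfp_trace"), inherits(bank, "filter_bank"))
  if (abs(trace$fs_hz - bank$fs_hz) > 1e-9) {
    stop("trace sampling rate (", trace$fs_hz, " Hz) does not match the ",
         "filter bank (", bank$fs_hz, " Hz)", call. = FALSE)
  }
  calls <- as.data.frame(calls)
  idx <- lapply(seq_len(nrow(calls)), function(i)
    fragment_indices(trace, calls$onset_s[i], calls$duration_s[i]))
  keep <- !vapply(idx, is.null, logical(1))
  skipped <- which(!keep)
  if (length(skipped) > 0L) {
    message(length(skipped), " call(s) skipped (too close to trace edges)")
  }
  calls_kept <- calls[keep, , drop = FALSE]
  idx <- idx[keep]
  out <- vector("list", length(bank$bands))
  for (bi in seq_along(bank$bands)) {
    band <- bank$bands[[bi]]
    y <- bandpass(trace, band, zero_phase = zero_phase)$samples
    cs <- cumsum(y^2)
    seg_rms <- function(lo, hi) {
      s <- cs[hi] - if (lo > 1L) cs[lo - 1L] else 0
      sqrt(s / (hi - lo + 1L))
    }
    rms_stim <- vapply(idx, function(ix) seg_rms(ix$stim[1L], ix$stim[2L]),
                       numeric(1))
    rms_base <- vapply(idx, function(ix) seg_rms(ix$base[1L], ix$base[2L]),
                       numeric(1))
    rec <- calls_kept
    rec$bird_id <- trace$bird_id
    rec$band_hz <- band$label_hz
    rec$rms_baseline <- rms_base
    rec$rms_stimulus <- rms_stim
    rec$ars <- rms_stim - rms_base
    out[[bi]] <- rec
  }
  res <- rbind_df(out)
  if (is.null(res)) res <- data.frame()
  attr(res, "skipped") <- skipped
  res
}

#' Normalize ARS within each bird to \[-1, 1\]
#'
#' Divides every `ars` value by the maximum absolute `ars` of that bird
#' (all days, bands and contexts pooled), so that within each bird the
#' largest-magnitude response is +/-1. An all-zero bird passes through as
#' zeros.
#'
#' @param records data.frame with columns `bird_id` and `ars`.
#' @return `records` with an added/overwritten `ars_norm` column.
#' @export
normalize_within_bird <- function(records) {
  stopifnot(all(c("bird_id", "ars") %in% names(records)))
  records$ars_norm <- records$ars
  for (b in unique(records$bird_id)) {
    sel <- records$bird_id == b
    m <- max(abs(records$ars[sel]))
    records$ars_norm[sel] <- if (m > 0) records$ars[sel] / m else 0
  }
  records
}

#' Log-squared response transform
#'
#' The per-bird band-ranking response scale `log(x^2)` applied to ARS
#' values, with an epsilon floor: values with `|x| < eps` return `NA`
#' (they would be -Inf) and are counted in the `"n_floored"` attribute.
#' Monotone increasing in `|x|` above the floor.
#'
#' @param x numeric ARS values.
#' @param eps floor on `|x|` (default 1e-12).
#' @return `log(x^2)` with `NA` at floored positions.
#' @export
log_sq <- function(x, eps = 1e-12) {
  out <- ifelse(abs(x) < eps, NA_real_, log(x^2))
  attr(out, "n_floored") <- sum(abs(x) < eps)
  out
}

#' Select the band(s) of interest
#'
#' Per bird, bands are ranked by the mean of `log(ars^2)` over that bird's
#' records (the response scale of the per-bird band models) and the top-k
#' labels are retained; the experiment-level band set is the modal top-k
#' set across birds. With flat input (no dominant band) the selection is
#' flagged.
#'
#' @param records ARS data.frame with columns `bird_id`, `band_hz`, `ars`.
#' @param k number of bands to keep per bird (default 3, the low-gamma
#'   bands 30/40/50).
#' @param margin_tol minimum gap (log units) between the k-th and
#'   (k+1)-th band statistic below which a bird is flagged
#'   `no_dominant_band`.
#' @return Object of class `band_selection`: list with `bands` (sorted
#'   labels of the modal top-k set), `per_bird` (named list of each
#'   bird's ranked top-k labels), `stats` (per bird, per band mean
#'   log(ars^2)), and `no_dominant_band` (named logical).
#' @export
select_band_of_interest <- function(records, k = 3, margin_tol = 0.1) {
  stopifnot(all(c("bird_id", "band_hz", "ars") %in% names(records)))
  birds <- unique(records$bird_id)
  per_bird <- list(); flags <- logical(0); stats <- list()
  for (b in birds) {
    rec <- records[records$bird_id == b, , drop = FALSE]
    bands <- sort(unique(rec$band_hz))
    if (length(bands) < k) {
      stop("bird '", b, "' has ", length(bands), " band(s); need >= k = ", k,
           call. = FALSE)
    }
    stat <- vapply(bands, function(bd) {
      v <- log_sq(rec$ars[rec$band_hz == bd])
      mean(v, na.rm = TRUE)
    }, numeric(1))
    ord <- order(stat, decreasing = TRUE)
    top <- bands[ord[seq_len(k)]]
    margin <- if (length(bands) > k) stat[ord[k]] - stat[ord[k + 1L]] else Inf
    per_bird[[b]] <- top
    stats[[b]] <- stats::setNames(stat, bands)
    flags[b] <- !is.finite(margin) && length(bands) > k || margin < margin_tol
  }
  sets <- vapply(per_bird, function(s) paste(sort(s), collapse = ","),
                 character(1))
  modal <- names(sort(table(sets), decreasing = TRUE))[1L]
  structure(list(
    bands = as.numeric(strsplit(modal, ",")[[1L]]),
    per_bird = per_bird, stats = stats, no_dominant_band = flags
  ), class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat("<band_selection> bands of interest:",
      paste(x$bands, collapse = ", "), "Hz\n")
  for (b in names(x$per_bird)) {
    cat(sprintf("  %s: top bands %s%s\n", b,
                paste(x$per_bird[[b]], collapse = ", "),
                if (x$no_dominant_band[[b]]) " [no dominant band]" else ""))
  }
  invisible(x)
}
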