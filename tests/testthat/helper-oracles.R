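# Shared fixtures and independent O(n^2) oracle reimplementations used by
# the unit and acceptance tests. Oracles are deliberately written as
# plain all-pairs loops, independent of the package's sorted/findInterval
# code paths.

rand_stream <- function(bird, n, T = 100, types = c("stack", "tet"),
                        day = 1L, trt = "NB") {
  ev <- if (n == 0L) {
    call_events(character(), character(), numeric(), numeric(),
                integer(), character())
  } else {
    call_events(rep(bird, n), sample(types, n, replace = TRUE),
                sort(stats::runif(n, 0, T)), stats::runif(n, 0.05, 0.3),
                day, trt)
  }
  event_stream(bird, ev, day_index = day, treatment = trt,
               session_length_s = T)
}

# all-pairs answer finder: onset-exclusive, end-inclusive window
find_answers_bf <- function(reference, responder, cfg) {
  w <- cfg$answer_window_s
  out <- list()
  for (i in seq_len(nrow(reference$events))) {
    r <- reference$events$onset_s[i]
    for (j in seq_len(nrow(responder$events))) {
      a <- responder$events$onset_s[j]
      if (a > r && a <= r + w) {
        out[[length(out) + 1L]] <- data.frame(
          ref_index = i, ans_index = j, latency_s = a - r)
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(ref_index = integer(), ans_index = integer(),
                     latency_s = numeric())
  }
  df[order(df$ref_index, df$ans_index), , drop = FALSE]
}

# windowed brute-force tally of Eq.-style reply counts
reply_strength_bf <- function(focal, partner, call_pair, cfg) {
  w <- cfg$answer_window_s
  refs <- partner$events$onset_s[partner$events$call_type == call_pair[2]]
  fo <- focal$events$onset_s[focal$events$call_type == call_pair[1]]
  n_resp <- 0L; n_base <- 0L
  for (t in refs) {
    for (o in fo) {
      if (o > t && o <= t + w) n_resp <- n_resp + 1L
      if (o >= t - w && o < t) n_base <- n_base + 1L
    }
  }
  rs <- if (n_resp + n_base > 0) (n_resp - n_base) / (n_resp + n_base)
        else NA_real_
  list(rs = rs, n_response = n_resp, n_baseline = n_base)
}

# exhaustive re-derivation of the context interval rules
classify_bf <- function(call, streams, cfg, focal_id) {
  gap <- cfg$isolation_gap_s; w <- cfg$answer_window_s
  lo <- call$onset_s - gap
  hi <- call$onset_s + call$duration_s + gap
  any_overlap <- FALSE
  focal <- numeric(0)
  for (s in streams) {
    if (s$bird_id == focal_id) focal <- s$events$onset_s
    for (j in seq_len(nrow(s$events))) {
      e_on <- s$events$onset_s[j]
      e_off <- e_on + s$events$duration_s[j]
      is_self <- s$bird_id == call$emitter_id &&
        abs(e_on - call$onset_s) < 1e-12 &&
        abs(s$events$duration_s[j] - call$duration_s) < 1e-12
      if (!is_self && e_on < hi && e_off > lo) any_overlap <- TRUE
    }
  }
  if (!any_overlap) return("isolated")
  if (call$emitter_id != focal_id) {
    if (any(focal > call$onset_s & focal <= call$onset_s + w)) {
      return("answer_by_focal")
    }
    if (any(call$onset_s > focal & call$onset_s <= focal + w)) {
      return("answered_by_partner")
    }
  }
  "other"
}

# run a python snippet (scipy is part of the analysis image); returns
# stdout lines
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", f, stdout = TRUE)
}
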