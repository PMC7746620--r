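# Readers and writers: event tables (CSV), LFP traces (mono WAV),
# configuration (YAML). CSV dialect: comma-separated, header required,
# UTF-8, '.' decimal.

#' Read call-event streams from CSV
#'
#' Expects columns `emitter_id, call_type, onset_s, duration_s, day_index,
#' treatment`. Rows are split into one [event_stream()] per (bird, day);
#' unsorted input is sorted with a notice, unknown call types and negative
#' durations are rejected.
#'
#' @param path CSV file path.
#' @return List of `event_stream` objects, ordered by (bird, day).
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, fileEncoding = "UTF-8")
  required <- c("emitter_id", "call_type", "onset_s", "duration_s",
                "day_index", "treatment")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("'", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, required, drop = FALSE]
  df$emitter_id <- as.character(df$emitter_id)
  df$call_type <- as.character(df$call_type)
  df$treatment <- as.character(df$treatment)
  df$day_index <- as.integer(df$day_index)
  validate_call_events(df)
  if (nrow(df) == 0L) return(list())
  keys <- split(seq_len(nrow(df)),
                list(bird = df$emitter_id, day = df$day_index), drop = TRUE)
  ord <- order(vapply(keys, function(i) df$emitter_id[i[1L]], character(1)),
               vapply(keys, function(i) df$day_index[i[1L]], integer(1)))
  lapply(keys[ord], function(idx) {
    ev <- df[idx, , drop = FALSE]
    rownames(ev) <- NULL
    event_stream(ev$emitter_id[1L], ev)
  })
}

#' Write call-event streams to CSV
#'
#' Rows are written in canonical order (bird, day, onset) so that a
#' write/read round trip is the identity on sorted tables.
#'
#' @param streams a single `event_stream` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(streams, path) {
  if (inherits(streams, "event_stream")) streams <- list(streams)
  tabs <- lapply(streams, function(s) s$events)
  df <- rbind_df(c(tabs))
  if (is.null(df)) {
    df <- call_events(character(), character(), numeric(), numeric(),
                      integer(), character())
  }
  df <- df[order(df$emitter_id, df$day_index, df$onset_s), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- WAV container (mono RIFF, PCM 16/32-bit integer or IEEE float32) ----
# Minimal by design: the telemetry pipeline stores single-channel traces.

#' Read a mono WAV file as an LFP trace
#'
#' Supports 16/32-bit integer PCM and 32-bit IEEE float. Integer samples
#' are scaled to `[-1, 1]` by the full-scale value (2^(bits-1)); the
#' sampling rate is taken from the container.
#'
#' @param path WAV file path.
#' @param bird_id identity attached to the returned trace.
#' @param t0_s session time of the first sample.
#' @return An [lfp_trace()].
#' @export
read_trace <- function(path, bird_id = "bird", t0_s = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("'", path, "' is not a RIFF file",
                                     call. = FALSE)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("'", path, "' is not a WAVE file",
                                     call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1L, 2L,
                             signed = FALSE, endian = "little"),
        fs_hz = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("'", path, "': missing fmt/data chunk", call. = FALSE)
  }
  if (fmt$n_channels != 1L) {
    stop("'", path, "' has ", fmt$n_channels,
         " channels; only single-channel traces are supported", call. = FALSE)
  }
  samples <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) %/% 4L, 4L,
            endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) %/% 4L, 4L,
            endian = "little") / 2147483648
  } else {
    stop("'", path, "': unsupported WAV encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bit)", call. = FALSE)
  }
  lfp_trace(samples, fmt$fs_hz, bird_id = bird_id, t0_s = t0_s)
}

#' Write an LFP trace to a mono WAV file
#'
#' @param trace an [lfp_trace()].
#' @param path output path.
#' @param encoding `"float32"` (lossless for analysis traces) or
#'   `"pcm16"` (samples must lie in `[-1, 1]`; quantized to 1/32767).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, encoding = c("float32", "pcm16")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(trace, "lfp_trace"))
  x <- trace$samples
  fs <- as.integer(round(trace$fs_hz))
  if (encoding == "pcm16") {
    if (max(abs(x)) > 1 + 1e-12) {
      stop("pcm16 encoding requires samples in [-1, 1]", call. = FALSE)
    }
    bits <- 16L; fmt_code <- 1L
    payload_n <- 2L * length(x)
  } else {
    bits <- 32L; fmt_code <- 3L
    payload_n <- 4L * length(x)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_n), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")            # mono
  writeBin(fs, con, 4L, endian = "little")
  writeBin(as.integer(fs * bits %/% 8L), con, 4L, endian = "little")
  writeBin(as.integer(bits %/% 8L), con, 2L, endian = "little")
  writeBin(bits, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_n), con, 4L, endian = "little")
  if (encoding == "pcm16") {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32767)))),
             con, 2L, endian = "little")
  } else {
    writeBin(x, con, 4L, endian = "little")
  }
  invisible(path)
}

# ---- Configuration (YAML) ----

#' Read an interaction configuration from YAML
#'
#' Recognised keys: `answer_window_s`, `peri_window_s`, `bin_width_s`,
#' `isolation_gap_s`; missing keys take the [interaction_config()]
#' defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return An [interaction_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(interaction_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s) in '", path, "': ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  do.call(interaction_config, raw)
}

#' Write an interaction configuration to YAML
#' @param cfg an [interaction_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "interaction_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
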