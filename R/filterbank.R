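# First-order Butterworth band-pass filter bank for LFP analysis.
#
# The digital coefficients come from the analog prototype H(s) = 1/(s+1),
# the standard low-pass -> band-pass transform s -> (s^2 + w0^2)/(B s),
# and the bilinear transform with edge prewarping. For order 1 this yields
# a single biquad per band:
#   H(z) = (BK - BK z^-2) / ((K^2 + BK + w0^2)
#          + (2 w0^2 - 2 K^2) z^-1 + (K^2 - BK + w0^2) z^-2)
# with K = 2 fs and prewarped edges W = 2 fs tan(pi f / fs),
# B = Wh - Wl, w0^2 = Wl Wh.

#' First-order Butterworth band-pass coefficients
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < fs_hz/2`.
#' @param fs_hz sampling rate.
#' @return List with numerator `b` and denominator `a` (both length 3,
#'   `a[1] == 1`).
#' @export
butter_bandpass <- function(low_hz, high_hz, fs_hz) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs_hz / 2)) {
    stop("require 0 < low_hz < high_hz < Nyquist (", fs_hz / 2, " Hz); got [",
         low_hz, ", ", high_hz, "]", call. = FALSE)
  }
  wl <- 2 * fs_hz * tan(pi * low_hz / fs_hz)
  wh <- 2 * fs_hz * tan(pi * high_hz / fs_hz)
  bw <- wh - wl
  w0sq <- wl * wh
  k <- 2 * fs_hz
  a0 <- k^2 + bw * k + w0sq
  list(b = c(bw * k, 0, -bw * k) / a0,
       a = c(1, (2 * w0sq - 2 * k^2) / a0, (k^2 - bw * k + w0sq) / a0))
}

#' Design the LFP band-pass filter bank
#'
#' Contiguous first-order Butterworth band-pass filters covering
#' 10-200 Hz in 10 Hz-wide bands by default (19 bands). Bands are
#' labelled by their lower edge, so "band 30" spans 30-40 Hz and the
#' low-gamma bands of interest 30/40/50 together span 30-60 Hz.
#'
#' @param fs_hz sampling rate; must exceed `2 * high`.
#' @param low,high,width band-plan edges and width in Hz.
#' @param order filter order; only 1 (the analysis default) is supported.
#' @return Object of class `filter_bank`: list with `fs_hz` and `bands`,
#'   each band holding `label_hz`, `low_hz`, `high_hz`, `b`, `a`.
#' @export
design_filter_bank <- function(fs_hz, low = 10, high = 200, width = 10,
                               order = 1) {
  if (order != 1) {
    stop("only first-order band-pass filters are implemented", call. = FALSE)
  }
  if (fs_hz <= 2 * high) {
    stop("sampling rate ", fs_hz, " Hz violates the Nyquist requirement: ",
         "highest band edge ", high, " Hz needs fs > ", 2 * high, " Hz",
         call. = FALSE)
  }
  edges <- seq(low, high - width, by = width)
  bands <- lapply(edges, function(lo) {
    coef <- butter_bandpass(lo, lo + width, fs_hz)
    list(label_hz = lo, low_hz = lo, high_hz = lo + width,
         b = coef$b, a = coef$a)
  })
  structure(list(fs_hz = fs_hz, bands = bands, order = order),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  lo <- x$bands[[1L]]$low_hz
  hi <- x$bands[[length(x$bands)]]$high_hz
  cat(sprintf("<filter_bank> %d order-%d Butterworth bands, %g-%g Hz @ %g Hz\n",
              length(x$bands), x$order, lo, hi, x$fs_hz))
  invisible(x)
}

# Causal IIR filtering y = filter(b, a, x) via stats::filter (C speed):
# convolve with b, then apply the recursive part.
iir_filter <- function(x, b, a) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution",
                     sides = 1L)
  v <- as.numeric(v)[nb:(nb + n - 1L)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L] / a[1L], method = "recursive"))
  }
  v / a[1L]
}

#' Band-pass filter a trace
#'
#' Applies one band of a [design_filter_bank()] to a trace. The default is
#' zero-phase forward-backward application (so that RMS windows align with
#' call boundaries without group delay), using odd-reflection padding at
#' both ends to suppress edge transients; `zero_phase = FALSE` gives the
#' plain causal filter.
#'
#' @param trace an [lfp_trace()] or bare numeric vector.
#' @param band one element of `bank$bands` (or any list with `b`, `a`,
#'   and band edges `low_hz`/`high_hz` used to size the padding).
#' @param zero_phase logical, default TRUE.
#' @return Filtered object of the same kind (trace in, trace out); output
#'   length equals input length.
#' @export
bandpass <- function(trace, band, zero_phase = TRUE) {
  is_trace <- inherits(trace, "lfp_trace")
  x <- if (is_trace) trace$samples else as.numeric(trace)
  n <- length(x)
  if (n == 0L) return(trace)
  y <- if (!zero_phase) {
    iir_filter(x, band$b, band$a)
  } else {
    bw <- if (!is.null(band$high_hz)) band$high_hz - band$low_hz else NULL
    fs <- if (is_trace) trace$fs_hz else NULL
    padlen <- if (!is.null(bw) && !is.null(fs)) ceiling(6 * fs / bw) else 250L
    padlen <- min(n - 1L, max(padlen, 3L))
    xp <- if (padlen > 0L) {
      c(2 * x[1L] - x[(padlen + 1L):2L], x,
        2 * x[n] - x[(n - 1L):(n - padlen)])
    } else x
    yp <- iir_filter(xp, band$b, band$a)
    yp <- rev(iir_filter(rev(yp), band$b, band$a))
    yp[(padlen + 1L):(padlen + n)]
  }
  if (is_trace) {
    out <- trace
    out$samples <- y
    out
  } else y
}

#' Analytic magnitude response of a designed band
#'
#' Evaluates |H(e^{i 2 pi f / fs})| of the digital biquad; used as the
#' frequency-response reference for energy-ordering checks.
#'
#' @param band a bank band (list with `b`, `a`).
#' @param f_hz frequencies at which to evaluate.
#' @param fs_hz sampling rate.
#' @return Numeric vector of magnitudes.
#' @export
band_magnitude <- function(band, f_hz, fs_hz) {
  z <- exp(-1i * 2 * pi * f_hz / fs_hz)
  num <- band$b[1] + band$b[2] * z + band$b[3] * z^2
  den <- band$a[1] + band$a[2] * z + band$a[3] * z^2
  Mod(num / den)
}
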