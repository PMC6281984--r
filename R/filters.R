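#' Band filter specification
#'
#' Fourth-order Butterworth low- and high-pass filters applied in cascade
#' (high-pass at `low_cut`, low-pass at `high_cut`), the standard fNIRS
#' physiological-noise filter: respiration, cardiac pulsation and
#' low-frequency drift all fall outside the 0.01-0.15 Hz hemodynamic band.
#'
#' @param order filter order of each stage (default 4).
#' @param low_cut high-pass cutoff in Hz (default 0.01).
#' @param high_cut low-pass cutoff in Hz (default 0.15).
#' @param mode `"causal"` (forward-only, suitable online) or `"zero-phase"`
#'   (forward-backward, no group delay, offline).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, low_cut = 0.01, high_cut = 0.15,
                        mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  if (order < 1) stop("order must be >= 1")
  if (low_cut <= 0 || high_cut <= low_cut)
    stop("need 0 < low_cut < high_cut")
  structure(list(order = order, low_cut = low_cut, high_cut = high_cut,
                 mode = mode), class = "filter_spec")
}

## cascade of one high-pass and one low-pass Butterworth stage; either cutoff
## may be NA to skip that stage
.butter_apply <- function(x, rate, low_cut, high_cut, order, mode) {
  ny <- rate / 2
  if (!is.na(high_cut) && high_cut >= ny)
    stop("high_cut (", high_cut, " Hz) must be below the Nyquist frequency (",
         ny, " Hz)")
  if (!is.na(low_cut) && low_cut >= ny)
    stop("low_cut above Nyquist")
  y <- as.numeric(x)
  run <- function(y, flt) {
    if (mode == "zero-phase") as.numeric(signal::filtfilt(flt, y))
    else as.numeric(signal::filter(flt, y))
  }
  if (!is.na(low_cut))
    y <- run(y, signal::butter(order, low_cut / ny, type = "high"))
  if (!is.na(high_cut))
    y <- run(y, signal::butter(order, high_cut / ny, type = "low"))
  y
}

#' Band-pass filter a hemodynamic series
#'
#' @param h a [hemo_series()].
#' @param spec a [filter_spec()]; the default is the 4th-order 0.01-0.15 Hz
#'   causal cascade.
#' @return a filtered [hemo_series()] of identical length.
#' @export
bandpass_hemo <- function(h, spec = filter_spec()) {
  stopifnot(inherits(h, "hemo_series"), inherits(spec, "filter_spec"))
  hemo_series(
    hbo = .butter_apply(h$hbo, h$rate, spec$low_cut, spec$high_cut,
                        spec$order, spec$mode),
    hbr = .butter_apply(h$hbr, h$rate, spec$low_cut, spec$high_cut,
                        spec$order, spec$mode),
    rate = h$rate, channel_id = h$channel_id)
}

#' Magnitude response of the band filter cascade
#'
#' Closed-form gain of the [filter_spec()] cascade at frequencies `f`,
#' computed from the Butterworth coefficients (used as the oracle for the
#' pass-band / stop-band contract: 20 dB or more attenuation of a 1 Hz
#' cardiac tone, 5 percent or less loss at 0.05 Hz).
#'
#' @param spec a [filter_spec()].
#' @param f frequencies in Hz.
#' @param rate sampling rate in Hz.
#' @return numeric vector of gains (zero-phase mode squares the magnitude).
#' @export
filter_gain <- function(spec, f, rate) {
  ny <- rate / 2
  gain_of <- function(flt) {
    z <- exp(-1i * 2 * pi * f / rate)
    b <- vapply(seq_along(f), function(i)
      sum(flt$b * z[i]^(seq_along(flt$b) - 1)), complex(1))
    a <- vapply(seq_along(f), function(i)
      sum(flt$a * z[i]^(seq_along(flt$a) - 1)), complex(1))
    abs(b / a)
  }
  g <- gain_of(signal::butter(spec$order, spec$low_cut / ny, type = "high")) *
    gain_of(signal::butter(spec$order, spec$high_cut / ny, type = "low"))
  if (spec$mode == "zero-phase") g^2 else g
}

#' Canonical EEG band edges (Hz)
#'
#' alpha 8-12, beta 12-28, delta 0.5-4, theta 4-8.  Beta is the band tied to
#' motor activity and is the one the gate watches.
#'
#' @return named list of `c(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(alpha = c(8, 12), beta = c(12, 28), delta = c(0.5, 4),
       theta = c(4, 8))
}

#' Split an EEG series into the four canonical bands
#'
#' Applies the 4th-order Butterworth high-pass + low-pass cascade per band
#' (the delta band's 0.5 Hz edge is a high-pass stage like every other band).
#'
#' @param x numeric EEG series.
#' @param rate sampling rate in Hz; must exceed twice the highest band edge
#'   (56 Hz).
#' @param order per-stage filter order (default 4).
#' @param mode `"causal"` or `"zero-phase"`.
#' @return object of class `eeg_band_set`: a list of four numeric series
#'   (`alpha`, `beta`, `delta`, `theta`), each the length of `x`, plus `rate`.
#' @export
eeg_band_decompose <- function(x, rate, order = 4,
                               mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  bands <- eeg_bands()
  top <- max(vapply(bands, `[`, numeric(1), 2))
  if (rate <= 2 * top)
    stop("sampling rate ", rate, " Hz too low for the ", top,
         " Hz band edge (need > ", 2 * top, " Hz)")
  out <- lapply(bands, function(b)
    .butter_apply(x, rate, b[1], b[2], order, mode))
  out$rate <- rate
  structure(out, class = "eeg_band_set")
}
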