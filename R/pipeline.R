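#' Detection pipeline configuration
#'
#' Collects every tunable of the hybrid detector in one place.
#'
#' @param threshold_frac EEG gate margin over the baseline maximum window
#'   power (default 0.15).
#' @param band EEG band the gate watches (default `"beta"`).
#' @param window_s EEG/fNIRS synchronization window (default 1 s).
#' @param hop_s gate re-evaluation hop; default one fNIRS sample period so
#'   gates and trajectory samples share a clock.
#' @param timeout_s trajectory monitoring horizon per gate (default 3 s).
#' @param decision_horizon_s command window after onset for scoring
#'   (default 1.5 s).
#' @param rest_offset_s negative-window offset after onset (default 15 s).
#' @param filter_mode fNIRS band filter direction for the detector path:
#'   `"zero-phase"` (default; offline-aligned timing, see vignette) or
#'   `"causal"` for true online operation.
#' @param dpf differential pathlength factor for the Beer-Lambert inversion.
#' @param r1_skip_s leading seconds of the pre-rest excluded from the
#'   resting-radius estimate (filter startup transient; default 10 s).
#' @param r1_tail_skip_s trailing seconds of the pre-rest excluded from the
#'   resting-radius estimate (default 5 s): zero-phase filtering mixes
#'   post-onset samples backward into the last few baseline seconds, which
#'   an online causal system would never see.
#' @param reference trajectory referencing for [detect_crossings()]:
#'   `"window"` (default; excursion relative to the gate window's mean, with
#'   the resting radius likewise referenced to the baseline's own mean) or
#'   `"none"`.
#' @param lda_window_s LDA feature window after onset (default 1.5 s).
#' @return list of class `detect_config`.
#' @export
detect_config <- function(threshold_frac = 0.15, band = "beta",
                          window_s = 1, hop_s = NULL, timeout_s = 3,
                          decision_horizon_s = 1.5, rest_offset_s = 15,
                          filter_mode = c("zero-phase", "causal"),
                          dpf = 6, r1_skip_s = 10, r1_tail_skip_s = 5,
                          reference = c("window", "none"),
                          lda_window_s = 1.5) {
  structure(list(threshold_frac = threshold_frac, band = band,
                 window_s = window_s, hop_s = hop_s, timeout_s = timeout_s,
                 decision_horizon_s = decision_horizon_s,
                 rest_offset_s = rest_offset_s,
                 filter_mode = match.arg(filter_mode), dpf = dpf,
                 r1_skip_s = r1_skip_s, r1_tail_skip_s = r1_tail_skip_s,
                 reference = match.arg(reference),
                 lda_window_s = lda_window_s),
            class = "detect_config")
}

## resting radius on the detector's own footing: the largest baseline
## excursion of the (dHbO, dHbR) vector relative to a trailing 1-s window
## mean, over lags up to the monitoring horizon.  Identical to the plain
## maximum resting magnitude when the baseline is stationary around zero,
## but immune to the slow offset any high-pass filter leaves under a
## repeated-trial response train (methods vignette).
.excursion_radius <- function(hbo, hbr, rate, window_s = 1, timeout_s = 3) {
  n <- length(hbo)
  L <- max(1L, floor(window_s * rate + 1e-9))
  K <- max(1L, floor(timeout_s * rate + 1e-9))
  if (n <= L + 1) stop("baseline too short for the excursion radius")
  cs_o <- cumsum(c(0, hbo)); cs_r <- cumsum(c(0, hbr))
  i <- L:n                                  # trailing-window means m[i]
  m_o <- (cs_o[i + 1] - cs_o[i - L + 1]) / L
  m_r <- (cs_r[i + 1] - cs_r[i - L + 1]) / L
  r1 <- 0
  for (k in seq_len(K)) {                   # lag k samples after the window
    j <- (L + k):n
    e_o <- hbo[j] - m_o[seq_along(j)]
    e_r <- hbr[j] - m_r[seq_along(j)]
    r1 <- max(r1, sqrt(e_o^2 + e_r^2))
  }
  r1
}

## accept either a generated or a loaded session
.session_parts <- function(session) {
  if (inherits(session, "synth_session") ||
      inherits(session, "loaded_session")) {
    list(fnirs = session$fnirs, eeg = session$eeg,
         times_eeg = session$times_eeg, sched = session$schedule,
         spec = session$spec,
         geometry = session$geometry %||% probe_geometry())
  } else stop("session must come from generate_session() or load_session()")
}

#' Convert and filter every fNIRS channel of a session
#'
#' Intensity to optical density (baseline = mean intensity over the pre-rest
#' block), Beer-Lambert inversion with per-channel source-detector distance,
#' and optionally the 0.01-0.15 Hz band filter.
#'
#' @param session a [generate_session()] or [load_session()] result.
#' @param config a [detect_config()].
#' @param filtered apply the band filter (`TRUE` for the detector path;
#'   `FALSE` gives the raw concentration scale used by the t-map).
#' @return list of [hemo_series()], one per channel.
#' @export
preprocess_session <- function(session, config = detect_config(),
                               filtered = TRUE) {
  p <- .session_parts(session)
  rate <- p$spec$fnirs_rate
  base_idx <- which(p$sched$times < p$spec$pre_rest_s)
  dists <- p$geometry$channels$distance_cm
  fspec <- filter_spec(mode = config$filter_mode)
  lapply(seq_len(ncol(p$fnirs$wl690)), function(ch) {
    od690 <- intensity_to_od(p$fnirs$wl690[, ch], base_idx)
    od830 <- intensity_to_od(p$fnirs$wl830[, ch], base_idx)
    h <- od_to_hemo(od690, od830, pathlength_cm = dists[ch],
                    dpf = config$dpf, rate = rate, channel_id = ch)
    if (filtered) bandpass_hemo(h, fspec) else h
  })
}

## per-electrode beta-band power streams on the shared gate clock
.beta_power_streams <- function(session, config) {
  p <- .session_parts(session)
  hop <- config$hop_s %||% (1 / p$spec$fnirs_rate)
  streams <- list()
  for (el in seq_len(ncol(p$eeg))) {
    bands <- eeg_band_decompose(p$eeg[, el], p$spec$eeg_rate)
    streams[[as.character(el)]] <-
      power_stream(bands[[config$band]], p$spec$eeg_rate,
                   window_s = config$window_s, hop_s = hop)
  }
  streams
}

#' Run the hybrid EEG-fNIRS detector on a session
#'
#' End-to-end pipeline: Beer-Lambert conversion and band filtering of every
#' fNIRS channel; beta-band power streams per electrode on a 1-s moving
#' window; electrode selection on the first task epoch (strongest horizontal
#' and vertical electrode, then fixed); gate events where both selected
#' electrodes exceed the 15 percent-over-baseline-maximum threshold;
#' per-channel resting circle radii from the pre-rest baseline; gate-by-gate
#' trajectory monitoring ([detect_crossings()]) on the 12 candidate channels
#' of the cross-check map; and per-trial scoring ([classify_trials()], OR
#' fusion across the candidate set).
#'
#' @param session a [generate_session()] or [load_session()] result.
#' @param config a [detect_config()].
#' @return object of class `hybrid_detection`: the per-gate `records`, the
#'   per-trial `outcomes`, `accuracy` (percent), the selected `electrodes`
#'   and candidate `channels`, per-channel `r1`, the gate table, the
#'   filtered hemodynamics, and the configuration.
#' @export
hybrid_detect <- function(session, config = detect_config()) {
  p <- .session_parts(session)
  sched <- p$sched
  hemo <- preprocess_session(session, config, filtered = TRUE)
  streams <- .beta_power_streams(session, config)

  ## electrode calibration on the first task epoch
  o1 <- sched$onsets[1]
  epoch_power <- vapply(streams, function(s)
    mean(s$power[s$t_start >= o1 & s$t_end <= o1 + sched$task_s]),
    numeric(1))
  names(epoch_power) <- names(streams)
  pair <- select_electrodes(epoch_power)
  channels <- candidate_channels(pair)
  channels <- channels[channels <= length(hemo)]

  gates <- gate_events(streams, c(pair$horizontal, pair$vertical),
                       baseline_end_s = p$spec$pre_rest_s,
                       threshold_frac = config$threshold_frac)

  base_keep <- sched$times >= config$r1_skip_s &
    sched$times < p$spec$pre_rest_s - config$r1_tail_skip_s
  records <- list()
  r1 <- numeric(0)
  for (ch in channels) {
    h <- hemo[[ch]]
    bo <- h$hbo[base_keep]; br <- h$hbr[base_keep]
    r1[as.character(ch)] <- if (config$reference == "window") {
      .excursion_radius(bo, br, p$spec$fnirs_rate,
                        window_s = config$window_s,
                        timeout_s = config$timeout_s)
    } else {
      resting_radius(bo, br)
    }
    records[[as.character(ch)]] <-
      detect_crossings(h, gates, r1[as.character(ch)],
                       timeout_s = config$timeout_s, sched = sched,
                       reference = config$reference)
  }
  records <- do.call(rbind, records)
  outcomes <- classify_trials(records, sched,
                              decision_horizon_s = config$decision_horizon_s,
                              rest_offset_s = config$rest_offset_s)
  structure(list(records = records, outcomes = outcomes,
                 accuracy = attr(outcomes, "accuracy"),
                 electrodes = pair, channels = channels, r1 = r1,
                 gates = gates, hemo = hemo, schedule = sched,
                 config = config),
            class = "hybrid_detection")
}

#' @export
print.hybrid_detection <- function(x, ...) {
  cat("Hybrid EEG-fNIRS detection\n")
  cat("  electrodes:", x$electrodes$horizontal, "(horizontal),",
      x$electrodes$vertical, "(vertical)\n")
  cat("  candidate channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  gate events:", nrow(x$gates), "; detections:",
      sum(x$records$decision == "detected"), "\n")
  cat("  accuracy:", x$accuracy, "%\n")
  invisible(x)
}

#' @export
summary.hybrid_detection <- function(object, ...) {
  det <- object$records[object$records$decision == "detected", ]
  out <- list(
    accuracy = object$accuracy,
    n_gates = nrow(object$gates),
    n_detections = nrow(det),
    mean_latency_s = if (nrow(det)) mean(det$latency) else NA_real_,
    electrodes = object$electrodes,
    channels = object$channels,
    outcomes = object$outcomes)
  class(out) <- "summary.hybrid_detection"
  out
}

#' @export
print.summary.hybrid_detection <- function(x, ...) {
  cat("Hybrid detection summary\n")
  cat("  accuracy:       ", x$accuracy, "%\n")
  cat("  gate events:    ", x$n_gates, "\n")
  cat("  detections:     ", x$n_detections, "\n")
  cat("  mean r2->r1 latency:", round(x$mean_latency_s, 3), "s\n")
  invisible(x)
}

#' Vector-phase diagram of one channel around one trial
#'
#' Plots the dHbO-dHbR trajectory from 2 s before to 3 s after the trial
#' onset, with the resting circle (r1) and the first gate's inner circle
#' (r2), octant boundaries, and the fourth quadrant where detection happens.
#'
#' @param x a `hybrid_detection`.
#' @param channel channel id to plot (default: first candidate).
#' @param trial trial number (default 1).
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.hybrid_detection <- function(x, channel = x$channels[1], trial = 1,
                                  ...) {
  h <- x$hemo[[channel]]
  o <- x$schedule$onsets[trial]
  times <- (seq_along(h$hbo) - 1) / h$rate
  idx <- times >= o - 2 & times <= o + 3
  r1 <- x$r1[as.character(channel)]
  g <- x$records[x$records$channel_id == channel &
                   !is.na(x$records$trial_id) &
                   x$records$trial_id == trial, ]
  r2 <- if (nrow(g)) g$r2[1] else NA
  lim <- max(abs(c(h$hbo[idx], h$hbr[idx], r1)), na.rm = TRUE) * 1.1
  graphics::plot(h$hbo[idx], h$hbr[idx], type = "l", asp = 1,
                 xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = expression(Delta * "HbO"),
                 ylab = expression(Delta * "HbR"),
                 main = sprintf("channel %d, trial %d", channel, trial),
                 ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(r1 * cos(th), r1 * sin(th), col = "red")
  if (!is.na(r2)) graphics::lines(r2 * cos(th), r2 * sin(th), col = "black")
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = 1, col = "grey85", lty = 3)
  graphics::abline(a = 0, b = -1, col = "grey85", lty = 3)
  invisible(x)
}

#' LDA baseline accuracy for a session
#'
#' Builds the comparison classifier's features — per candidate channel the
#' dHbO mean and slope over the 0-1.5 s post-onset window, plus the beta
#' power of each selected electrode over the same window — for the 12 task
#' onsets and 12 matched mid-rest windows, and scores leave-one-window-out
#' LDA ([lda_baseline()]).
#'
#' @param session a [generate_session()] or [load_session()] result.
#' @param config a [detect_config()].
#' @return the accuracy (percent) with the feature matrix attached as
#'   attribute `features`.
#' @export
hybrid_lda <- function(session, config = detect_config()) {
  p <- .session_parts(session)
  sched <- p$sched
  hemo <- preprocess_session(session, config, filtered = TRUE)
  streams <- .beta_power_streams(session, config)
  o1 <- sched$onsets[1]
  epoch_power <- vapply(streams, function(s)
    mean(s$power[s$t_start >= o1 & s$t_end <= o1 + sched$task_s]),
    numeric(1))
  names(epoch_power) <- names(streams)
  pair <- select_electrodes(epoch_power)
  channels <- candidate_channels(pair)
  channels <- channels[channels <= length(hemo)]
  electrodes <- c(pair$horizontal, pair$vertical)

  beta <- lapply(electrodes, function(el)
    eeg_band_decompose(p$eeg[, el], p$spec$eeg_rate)$beta)
  names(beta) <- as.character(electrodes)

  wlen <- config$lda_window_s
  starts <- c(sched$onsets, sched$onsets + config$rest_offset_s)
  labels <- rep(c("task", "rest"), each = sched$n_trials)

  feat <- t(vapply(starts, function(t0) {
    f <- numeric(0)
    for (ch in channels) {
      h <- hemo[[ch]]
      idx <- which(sched$times >= t0 & sched$times < t0 + wlen)
      y <- h$hbo[idx]; tt <- sched$times[idx]
      sl <- stats::cov(tt, y) / stats::var(tt)
      f <- c(f, mean(y), sl)
    }
    for (el in as.character(electrodes))
      f <- c(f, window_power(beta[[el]], p$spec$eeg_rate, t0, wlen))
    f
  }, numeric(2 * length(channels) + length(electrodes))))

  lda_baseline(feat, labels, folds = rep(seq_len(sched$n_trials), 2))
}
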