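#' Noise model for synthetic dual-modality sessions
#'
#' fNIRS side: additive sinusoidal cardiac (~1 Hz), respiratory (~0.3 Hz) and
#' low-frequency drift (< 0.01 Hz) components with channel-wise random
#' phases, plus white sensor noise, all in concentration space (mM).
#' EEG side: each canonical band is filtered white noise with a band
#' amplitude; only the beta band is task-modulated (amplitude gain
#' `eeg_beta_gain_task` during task blocks, jittered per trial), with
#' spontaneous short beta bursts outside task blocks — the physiological
#' source of EEG false positives that the hybrid method is built to veto.
#'
#' @param cardiac_hz,resp_hz,drift_hz component frequencies in Hz.
#' @param cardiac_amp,resp_amp,drift_amp component amplitudes in mM.
#' @param white_sd fNIRS white-noise standard deviation in mM.
#' @param eeg_band_amps named amplitudes (a.u.) for alpha/beta/delta/theta.
#' @param eeg_white_sd broadband EEG noise standard deviation (a.u.).
#' @param eeg_beta_gain_task beta amplitude gain during task (> 1 for an
#'   active session; power scales with its square).
#' @param eeg_trial_gain_sdlog lognormal sd of the per-trial gain jitter.
#' @param eeg_task_ramp_s seconds over which the task beta synchronization
#'   develops after onset (default 0.5; 0 gives an instantaneous step).
#' @param eeg_bg_sdlog lognormal sd of the slow (~tens of seconds)
#'   nonstationarity of the background beta amplitude (default 0.15;
#'   0 gives a stationary background).
#' @param eeg_burst_rate_hz Poisson rate of spontaneous resting beta bursts.
#' @param eeg_burst_gain,eeg_burst_s burst amplitude gain and duration (s).
#' @param electrode_weights length-5 spatial weights applied to the
#'   task/burst beta gain per electrode (electrodes 1 and 4 strongest by
#'   default, matching the cross-check layout).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(cardiac_hz = 1.0, resp_hz = 0.3, drift_hz = 0.005,
                       cardiac_amp = 2e-4, resp_amp = 1e-4,
                       drift_amp = 2e-4, white_sd = 2e-5,
                       eeg_band_amps = c(alpha = 1, beta = 1,
                                         delta = 1.5, theta = 0.8),
                       eeg_white_sd = 0.2,
                       eeg_beta_gain_task = 2.5,
                       eeg_trial_gain_sdlog = 0.15,
                       eeg_task_ramp_s = 0.5, eeg_bg_sdlog = 0.15,
                       eeg_burst_rate_hz = 0.08,
                       eeg_burst_gain = 1.5, eeg_burst_s = 0.4,
                       electrode_weights = c(1, 0.7, 0.7, 1, 0.7)) {
  amps <- c(cardiac_amp, resp_amp, drift_amp, white_sd, eeg_band_amps,
            eeg_white_sd)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  if (eeg_beta_gain_task < 1) stop("eeg_beta_gain_task must be >= 1")
  structure(list(cardiac_hz = cardiac_hz, resp_hz = resp_hz,
                 drift_hz = drift_hz, cardiac_amp = cardiac_amp,
                 resp_amp = resp_amp, drift_amp = drift_amp,
                 white_sd = white_sd, eeg_band_amps = eeg_band_amps,
                 eeg_white_sd = eeg_white_sd,
                 eeg_beta_gain_task = eeg_beta_gain_task,
                 eeg_trial_gain_sdlog = eeg_trial_gain_sdlog,
                 eeg_task_ramp_s = eeg_task_ramp_s,
                 eeg_bg_sdlog = eeg_bg_sdlog,
                 eeg_burst_rate_hz = eeg_burst_rate_hz,
                 eeg_burst_gain = eeg_burst_gain,
                 eeg_burst_s = eeg_burst_s,
                 electrode_weights = electrode_weights),
            class = "noise_spec")
}

#' Synthetic session specification
#'
#' Defines one dual-modality recording session: the block paradigm (12 trials
#' of 10 s task / 20 s rest between a 60 s pre-rest and 10 s post-rest), the
#' two sampling clocks (fNIRS 9.19 Hz, EEG 256 Hz), the probe size (36 fNIRS
#' channels, 5 EEG electrodes), which channels carry a task-evoked response,
#' the hemodynamic ground-truth model and the noise structure.
#'
#' Ground truth is injected in concentration space — active channels get an
#' HRF-shaped dHbO rise with `hbr = -hbr_ratio * hbo` — and folded through
#' the forward Beer-Lambert model into two-wavelength intensities, so the
#' preprocessing chain can be validated by round-trip recovery.
#'
#' @param n_trials,task_s,rest_s,pre_rest_s,post_rest_s paradigm, see
#'   [paradigm_schedule()].
#' @param fnirs_rate,eeg_rate sampling rates in Hz.
#' @param n_fnirs_channels,n_eeg_electrodes probe size.
#' @param active_channels integer ids of channels carrying the response
#'   (must be a subset of `1:n_fnirs_channels`).
#' @param amp_hbo single-trial peak dHbO amplitude in mM (default 3e-3 mM,
#'   a strong but reported motor-cortex response).
#' @param hbr_ratio dHbR = `-hbr_ratio * dHbO`, in (0, 1) (default 1/3).
#' @param trial_amp_sdlog lognormal sd of per-trial amplitude jitter.
#' @param hrf [gamma_params()] used for the synthetic response.  The default
#'   is a fast-onset two-gamma (`phi1 = 4`, `tau1 = 1` s, time-to-peak 3 s)
#'   emulating the rapid early concentration rise the 1.5-s command window
#'   of the detection method presupposes (the reported trajectories reach
#'   the resting circle about 1.5 s after onset, which pins down the
#'   kernel's early-rise fraction); the analysis-side dHRF keeps the slower
#'   canonical defaults.
#' @param noise a [noise_spec()].
#' @param dpf differential pathlength factor used by the forward model.
#' @param seed integer RNG seed; identical seeds give bit-identical sessions.
#' @return object of class `session_spec`.
#' @export
session_spec <- function(n_trials = 12, task_s = 10, rest_s = 20,
                         pre_rest_s = 60, post_rest_s = 10,
                         fnirs_rate = 9.19, eeg_rate = 256,
                         n_fnirs_channels = 36, n_eeg_electrodes = 5,
                         active_channels = c(17, 18, 29, 33),
                         amp_hbo = 3e-3, hbr_ratio = 1 / 3,
                         trial_amp_sdlog = 0.25,
                         hrf = gamma_params(phi1 = 4, tau1 = 1),
                         noise = noise_spec(), dpf = 6, seed = 1L) {
  if (fnirs_rate <= 0 || eeg_rate <= 0) stop("rates must be positive")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (length(active_channels) &&
      !all(active_channels %in% seq_len(n_fnirs_channels)))
    stop("active_channels must be a subset of 1:", n_fnirs_channels)
  if (hbr_ratio <= 0 || hbr_ratio >= 1) stop("hbr_ratio must lie in (0, 1)")
  stopifnot(inherits(hrf, "gamma_params"), inherits(noise, "noise_spec"))
  structure(list(n_trials = n_trials, task_s = task_s, rest_s = rest_s,
                 pre_rest_s = pre_rest_s, post_rest_s = post_rest_s,
                 fnirs_rate = fnirs_rate, eeg_rate = eeg_rate,
                 n_fnirs_channels = n_fnirs_channels,
                 n_eeg_electrodes = n_eeg_electrodes,
                 active_channels = as.integer(active_channels),
                 amp_hbo = amp_hbo, hbr_ratio = hbr_ratio,
                 trial_amp_sdlog = trial_amp_sdlog,
                 hrf = hrf, noise = noise, dpf = dpf,
                 seed = as.integer(seed)),
            class = "session_spec")
}

## run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic EEG-fNIRS session
#'
#' Builds the paradigm, injects HRF-shaped concentration ground truth on the
#' active channels, adds physiological and sensor noise, folds concentrations
#' through the forward Beer-Lambert model into dual-wavelength raw
#' intensities, and synthesizes band-structured EEG with task-modulated beta.
#' Fully seeded: the same `spec` yields bit-identical output.
#'
#' @param spec a [session_spec()].
#' @param geometry a [probe_geometry()] supplying per-channel source-detector
#'   distances for the forward model.
#' @return object of class `synth_session`: the paradigm `schedule`, raw
#'   `fnirs` intensities (`wl690`, `wl830`: samples x channels), `eeg`
#'   (samples x electrodes) with `times_eeg`, the concentration-space ground
#'   `truth` (`hbo`, `hbr` matrices, per-trial amplitudes and EEG gains,
#'   burst onsets), plus `spec` and `geometry`.
#' @export
generate_session <- function(spec = session_spec(),
                             geometry = probe_geometry()) {
  stopifnot(inherits(spec, "session_spec"))
  .with_seed(spec$seed, {
    sched <- paradigm_schedule(spec$n_trials, spec$task_s, spec$rest_s,
                               spec$pre_rest_s, spec$post_rest_s,
                               spec$fnirs_rate)
    n_f <- length(sched$times)
    n_ch <- spec$n_fnirs_channels
    ns <- spec$noise

    ## --- hemodynamic ground truth (concentration space, mM) --------------
    trial_amp <- exp(stats::rnorm(spec$n_trials, 0, spec$trial_amp_sdlog))
    s_jit <- as.numeric(sched$s)
    for (i in seq_len(spec$n_trials)) {
      o <- sched$onsets[i]
      idx <- sched$times >= o - 1e-12 & sched$times < o + spec$task_s - 1e-12
      s_jit[idx] <- trial_amp[i]
    }
    h_k <- canonical_hrf(sched$times, spec$hrf)
    u_jit <- .dhrf_conv(h_k, s_jit, spec$hrf$k1)
    sched1 <- paradigm_schedule(1, spec$task_s, spec$rest_s, 0,
                                spec$task_s + spec$rest_s, spec$fnirs_rate)
    u1 <- designed_hrf(spec$hrf, sched1)
    scale <- spec$amp_hbo / max(u1)

    truth_hbo <- matrix(0, n_f, n_ch)
    for (ch in spec$active_channels) truth_hbo[, ch] <- scale * u_jit
    truth_hbr <- -spec$hbr_ratio * truth_hbo

    ## --- physiological + sensor noise, then forward MBLL ------------------
    dists <- geometry$channels$distance_cm[seq_len(min(n_ch,
                                                       nrow(geometry$channels)))]
    if (length(dists) < n_ch)                     # off-grid extra channels
      dists <- rep(dists, length.out = n_ch)
    wl690 <- matrix(NA_real_, n_f, n_ch)
    wl830 <- matrix(NA_real_, n_f, n_ch)
    tt <- sched$times
    osc <- function(amp, f) {
      if (amp == 0) return(numeric(n_f))
      amp * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    }
    for (ch in seq_len(n_ch)) {
      nz_o <- osc(ns$cardiac_amp, ns$cardiac_hz) +
        osc(ns$resp_amp, ns$resp_hz) + osc(ns$drift_amp, ns$drift_hz)
      nz_r <- osc(ns$cardiac_amp, ns$cardiac_hz) +
        osc(ns$resp_amp, ns$resp_hz) + osc(ns$drift_amp, ns$drift_hz)
      w_o <- if (ns$white_sd > 0) stats::rnorm(n_f, 0, ns$white_sd) else 0
      w_r <- if (ns$white_sd > 0) stats::rnorm(n_f, 0, ns$white_sd) else 0
      inten <- forward_mbll(truth_hbo[, ch] + nz_o + w_o,
                            truth_hbr[, ch] + nz_r + w_r,
                            pathlength_cm = dists[ch], dpf = spec$dpf)
      wl690[, ch] <- inten$wl690
      wl830[, ch] <- inten$wl830
    }

    ## --- EEG: band-structured noise, task-modulated beta ------------------
    n_e <- floor(sched$total_s * spec$eeg_rate + 1e-9)
    t_e <- (seq_len(n_e) - 1) / spec$eeg_rate
    task_e <- in_task(sched, t_e)

    trial_gain <- spec$noise$eeg_beta_gain_task *
      exp(stats::rnorm(spec$n_trials, 0, ns$eeg_trial_gain_sdlog))

    ## spontaneous beta bursts outside task blocks (shared timing across
    ## electrodes, electrode-weighted amplitude)
    n_burst <- stats::rpois(1, ns$eeg_burst_rate_hz * sched$total_s)
    burst_on <- sort(stats::runif(n_burst, 0, sched$total_s - ns$eeg_burst_s))
    keep <- !in_task(sched, burst_on) &
      !in_task(sched, burst_on + ns$eeg_burst_s)
    burst_on <- burst_on[keep]
    burst_e <- rep(FALSE, n_e)
    for (b in burst_on)
      burst_e[t_e >= b & t_e < b + ns$eeg_burst_s] <- TRUE

    ## task envelope: synchronization develops over eeg_task_ramp_s
    gain_e <- rep(1, n_e)
    for (i in seq_len(spec$n_trials)) {
      o <- sched$onsets[i]
      sel <- t_e >= o - 1e-12 & t_e < o + spec$task_s - 1e-12
      ramp <- if (ns$eeg_task_ramp_s > 0)
        pmin(1, (t_e[sel] - o) / ns$eeg_task_ramp_s) else 1
      gain_e[sel] <- 1 + (trial_gain[i] - 1) * ramp
    }

    ## slow background beta nonstationarity (lognormal, ~0.02 Hz), built on
    ## a 1 Hz grid and interpolated onto the EEG clock
    if (ns$eeg_bg_sdlog > 0) {
      n_c <- ceiling(sched$total_s) + 2
      bg_c <- .butter_apply(stats::rnorm(n_c), 1, NA, 0.02, 2, "causal")
      bg_c <- bg_c / stats::sd(bg_c) * ns$eeg_bg_sdlog
      bg_e <- exp(stats::approx(seq_len(n_c) - 1, bg_c, xout = t_e,
                                rule = 2)$y)
    } else bg_e <- rep(1, n_e)

    bands <- eeg_bands()
    w_el <- rep(ns$electrode_weights, length.out = spec$n_eeg_electrodes)
    eeg <- matrix(0, n_e, spec$n_eeg_electrodes)
    for (el in seq_len(spec$n_eeg_electrodes)) {
      x <- numeric(n_e)
      for (bn in names(bands)) {
        amp <- ns$eeg_band_amps[[bn]]
        if (amp == 0) next
        b <- bands[[bn]]
        xb <- .butter_apply(stats::rnorm(n_e), spec$eeg_rate,
                            b[1], b[2], 4, "causal")
        xb <- xb / stats::sd(xb) * amp
        if (bn == "beta") {
          env <- 1 + (gain_e * w_el[el] - 1) * as.numeric(task_e) +
            (ns$eeg_burst_gain * w_el[el] - 1) * as.numeric(burst_e)
          xb <- xb * env * bg_e
        }
        x <- x + xb
      }
      if (ns$eeg_white_sd > 0)
        x <- x + stats::rnorm(n_e, 0, ns$eeg_white_sd)
      eeg[, el] <- x
    }

    structure(list(spec = spec, geometry = geometry, schedule = sched,
                   fnirs = list(wl690 = wl690, wl830 = wl830),
                   eeg = eeg, times_eeg = t_e,
                   truth = list(hbo = truth_hbo, hbr = truth_hbr,
                                active_channels = spec$active_channels,
                                trial_amp = trial_amp,
                                eeg_trial_gain = trial_gain,
                                burst_onsets = burst_on),
                   seed = spec$seed),
              class = "synth_session")
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat("Synthetic EEG-fNIRS session (seed", x$seed, ")\n")
  print(x$schedule)
  cat("   fNIRS:", ncol(x$fnirs$wl690), "channels x 2 wavelengths;",
      "active:", paste(x$truth$active_channels, collapse = ", "), "\n")
  cat("   EEG:  ", ncol(x$eeg), "electrodes at", x$spec$eeg_rate, "Hz\n")
  invisible(x)
}

#' Generate a multi-subject synthetic study
#'
#' One session per subject, seeds derived from the study seed by fixed
#' offsets.  The default 3-subject study at the default paradigm yields
#' 36 channels x 12 trials x 3 subjects = 1296 channel-trial series.
#'
#' @param n_subjects number of subjects (default 3).
#' @param spec template [session_spec()] (per-subject seed is overridden).
#' @param seed study seed.
#' @return list of class `synth_study` with `sessions` and the realized
#'   `channel_trial_count`.
#' @export
generate_study <- function(n_subjects = 3, spec = session_spec(),
                           seed = 1L) {
  sessions <- lapply(seq_len(n_subjects), function(i) {
    sp <- spec
    sp$seed <- as.integer(seed + 1000L * (i - 1L))
    generate_session(sp)
  })
  cnt <- sum(vapply(sessions, function(s)
    ncol(s$fnirs$wl690) * s$spec$n_trials, numeric(1)))
  structure(list(sessions = sessions, channel_trial_count = cnt,
                 seed = seed), class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("Synthetic study:", length(x$sessions), "subjects,",
      x$channel_trial_count, "channel-trial series\n")
  invisible(x)
}
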