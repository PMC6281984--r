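# compact sessions for fast tests: 4 trials, full 36-channel probe
mini_spec <- function(seed = 1, ...) {
  session_spec(n_trials = 4, pre_rest_s = 40, post_rest_s = 5,
               seed = seed, ...)
}

# a noise-free spec: flat intensities except ground truth, silent EEG
silent_noise <- function(...) {
  noise_spec(cardiac_amp = 0, resp_amp = 0, drift_amp = 0, white_sd = 0,
             eeg_band_amps = c(alpha = 0, beta = 0, delta = 0, theta = 0),
             eeg_white_sd = 0, eeg_beta_gain_task = 1,
             eeg_trial_gain_sdlog = 0, eeg_task_ramp_s = 0,
             eeg_bg_sdlog = 0, eeg_burst_rate_hz = 0, ...)
}

# brute-force octant oracle: exhaustive interval table in degrees
oracle_phase <- function(hbo, hbr) {
  ang <- atan2(hbr, hbo) * 180 / pi
  lo <- c(0, 45, 90, 135, -180, -135, -90, -45)
  hi <- c(45, 90, 135, 180, -135, -90, -45, 0)
  out <- integer(length(ang))
  for (k in 1:8)
    out[ang > lo[k] & ang <= hi[k]] <- k
  out
}
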