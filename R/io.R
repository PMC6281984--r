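## On-disk conventions (documented once, used by every reader/writer):
## - delimited tables are UTF-8, tab-separated, with a header row; the time
##   column is seconds, 0 at paradigm start; sample indices are 0-based
## - channel/electrode ids are 1-based, matching the probe figures
## - the paradigm file is a 3-column onset/duration/condition table
##   (seconds, 0-based onsets)
## - the manifest is JSON and records the seed and the full session spec,
##   sufficient to regenerate the session bit-identically

.spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$hrf <- unclass(out$hrf)
  out$hrf$alpha1 <- out$hrf$alpha1 %||% NA
  out$noise <- unclass(out$noise)
  # keep band names through JSON (atomic vectors serialize as bare arrays)
  out$noise$eeg_band_amps <- as.list(out$noise$eeg_band_amps)
  out
}

.spec_from_list <- function(l) {
  hr <- l$hrf
  a1 <- hr$alpha1
  if (is.null(a1) || length(a1) == 0 || is.na(a1)) a1 <- NULL
  hrf <- gamma_params(alpha1 = a1, alpha2 = hr$alpha2, tau1 = hr$tau1,
                      tau2 = hr$tau2, phi1 = hr$phi1, phi2 = hr$phi2,
                      k1 = hr$k1, use_gamma_fn = isTRUE(hr$use_gamma_fn))
  nz <- l$noise
  noise <- noise_spec(cardiac_hz = nz$cardiac_hz, resp_hz = nz$resp_hz,
                      drift_hz = nz$drift_hz, cardiac_amp = nz$cardiac_amp,
                      resp_amp = nz$resp_amp, drift_amp = nz$drift_amp,
                      white_sd = nz$white_sd,
                      eeg_band_amps = unlist(nz$eeg_band_amps),
                      eeg_white_sd = nz$eeg_white_sd,
                      eeg_beta_gain_task = nz$eeg_beta_gain_task,
                      eeg_trial_gain_sdlog = nz$eeg_trial_gain_sdlog,
                      eeg_task_ramp_s = nz$eeg_task_ramp_s,
                      eeg_bg_sdlog = nz$eeg_bg_sdlog,
                      eeg_burst_rate_hz = nz$eeg_burst_rate_hz,
                      eeg_burst_gain = nz$eeg_burst_gain,
                      eeg_burst_s = nz$eeg_burst_s,
                      electrode_weights = unlist(nz$electrode_weights))
  session_spec(n_trials = l$n_trials, task_s = l$task_s, rest_s = l$rest_s,
               pre_rest_s = l$pre_rest_s, post_rest_s = l$post_rest_s,
               fnirs_rate = l$fnirs_rate, eeg_rate = l$eeg_rate,
               n_fnirs_channels = l$n_fnirs_channels,
               n_eeg_electrodes = l$n_eeg_electrodes,
               active_channels = unlist(l$active_channels),
               amp_hbo = l$amp_hbo, hbr_ratio = l$hbr_ratio,
               trial_amp_sdlog = l$trial_amp_sdlog,
               hrf = hrf, noise = noise, dpf = l$dpf, seed = l$seed)
}

## full-precision numeric table writer (round-trips doubles)
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
}

#' Write a synthetic session to delimited fixtures
#'
#' One wide tab-separated table per modality and wavelength
#' (`fnirs_wl690.tsv`, `fnirs_wl830.tsv`: `time` + `ch<i>`;
#' `eeg.tsv`: `time` + `e<i>`), a BED-like paradigm table
#' (`paradigm.tsv`: onset / duration / condition, seconds) and a JSON
#' manifest recording the seed and full spec.  Numeric values are written at
#' full precision so the round trip through [load_session()] is lossless.
#'
#' @param session a [generate_session()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_fixtures <- function(session, dir) {
  stopifnot(inherits(session, "synth_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ft <- session$schedule$times
  for (wl in c("wl690", "wl830")) {
    m <- session$fnirs[[wl]]
    df <- data.frame(time = ft, m)
    names(df) <- c("time", paste0("ch", seq_len(ncol(m))))
    .write_tsv(df, file.path(dir, paste0("fnirs_", wl, ".tsv")))
  }
  eeg <- data.frame(time = session$times_eeg, session$eeg)
  names(eeg) <- c("time", paste0("e", seq_len(ncol(session$eeg))))
  .write_tsv(eeg, file.path(dir, "eeg.tsv"))

  sch <- session$schedule
  par <- data.frame(onset = sch$onsets, duration = sch$task_s,
                    condition = "task")
  .write_tsv(par, file.path(dir, "paradigm.tsv"))

  jsonlite::write_json(
    list(seed = session$seed, spec = .spec_to_list(session$spec),
         format = "hybridphase-fixtures-v1"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Load a fixture directory as an aligned multimodal session
#'
#' Reads the delimited tables written by [write_fixtures()] (or arranged in
#' the same layout), reconstructs the paradigm on the fNIRS clock, and
#' builds the nearest-sample mapping between the two clocks
#' (`fnirs sample i -> eeg sample round(i * eeg_rate / fnirs_rate)`,
#' 0-based).
#'
#' @param dir fixture directory.
#' @return list of class `loaded_session`: `fnirs` (wavelength matrices),
#'   `times_fnirs`, `eeg` matrix, `times_eeg`, `paradigm` data frame,
#'   `schedule`, `spec` (rebuilt from the manifest), `clock_map` (integer
#'   vector, 0-based EEG sample per fNIRS sample).
#' @export
load_session <- function(dir) {
  need <- c("fnirs_wl690.tsv", "fnirs_wl830.tsv", "eeg.tsv",
            "paradigm.tsv", "manifest.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing session file(s): ", paste(missing, collapse = ", "))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  spec <- .spec_from_list(man$spec)

  rd <- function(f) as.data.frame(data.table::fread(file.path(dir, f)))
  w690 <- rd("fnirs_wl690.tsv"); w830 <- rd("fnirs_wl830.tsv")
  eeg <- rd("eeg.tsv"); par <- rd("paradigm.tsv")
  if (nrow(w690) != nrow(w830))
    stop("wavelength files disagree in length: fnirs_wl690.tsv vs ",
         "fnirs_wl830.tsv")
  sched <- paradigm_schedule(spec$n_trials, spec$task_s, spec$rest_s,
                             spec$pre_rest_s, spec$post_rest_s,
                             spec$fnirs_rate)
  if (nrow(w690) != length(sched$times))
    stop("fNIRS length does not match the paradigm/manifest ",
         "(fnirs_wl690.tsv)")
  n_f <- nrow(w690)
  clock_map <- as.integer(round((seq_len(n_f) - 1) *
                                  spec$eeg_rate / spec$fnirs_rate))
  clock_map <- pmin(clock_map, nrow(eeg) - 1L)
  structure(list(
    fnirs = list(wl690 = as.matrix(w690[, -1, drop = FALSE]),
                 wl830 = as.matrix(w830[, -1, drop = FALSE])),
    times_fnirs = w690$time,
    eeg = as.matrix(eeg[, -1, drop = FALSE]),
    times_eeg = eeg$time,
    paradigm = par, schedule = sched, spec = spec,
    clock_map = clock_map, seed = man$seed),
    class = "loaded_session")
}
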