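#' Mean-square power of one signal window
#'
#' Power is the mean of the squared band-filtered samples over the window
#' `[t_start, t_start + duration)`; a unit-amplitude in-band sinusoid has
#' power 1/2.
#'
#' @param x numeric band-filtered series.
#' @param rate sampling rate in Hz.
#' @param t_start window start in seconds (0 = series start).
#' @param duration window length in seconds (default 1).
#' @return scalar power (signal units squared).
#' @export
window_power <- function(x, rate, t_start, duration = 1) {
  i0 <- floor(t_start * rate + 1e-9) + 1
  i1 <- floor((t_start + duration) * rate + 1e-9)
  if (i0 < 1 || i1 > length(x) || i1 < i0)
    stop("window [", t_start, ", ", t_start + duration,
         ") s not fully inside the series")
  mean(x[i0:i1]^2)
}

#' Sliding-window power stream
#'
#' Power of every 1-s (by default) window sliding at `hop_s` over the series,
#' computed in O(n) with a cumulative sum.  The hop defaults to the fNIRS
#' sample period so that gate events and trajectory samples share a clock.
#'
#' @param x numeric band-filtered series (one electrode).
#' @param rate sampling rate in Hz.
#' @param window_s window length in seconds (default 1).
#' @param hop_s hop between successive window starts in seconds
#'   (default `1 / 9.19`).
#' @return data frame `window_id, t_start, t_end, power`, windows fully
#'   inside the series.
#' @export
power_stream <- function(x, rate, window_s = 1, hop_s = 1 / 9.19) {
  n <- length(x)
  L <- floor(window_s * rate + 1e-9)
  if (L < 1 || L > n) stop("window longer than series")
  cs <- cumsum(c(0, x^2))
  t_total <- n / rate
  starts <- seq(0, t_total - window_s, by = hop_s)
  i0 <- floor(starts * rate + 1e-9) + 1
  keep <- i0 + L - 1 <= n
  i0 <- i0[keep]; starts <- starts[keep]
  p <- (cs[i0 + L] - cs[i0]) / L
  data.frame(window_id = seq_along(i0), t_start = starts,
             t_end = starts + window_s, power = p)
}

#' EEG gate events: strict power exceedance over the resting baseline
#'
#' A gate event fires for a window when the band power of every selected
#' electrode strictly exceeds `(1 + threshold_frac)` times that electrode's
#' maximum baseline window power (15 percent over the baseline maximum by
#' default, the safety margin against false detections).
#'
#' @param powers named list of power-stream data frames
#'   (from [power_stream()]), one per electrode, on a common window grid.
#' @param electrodes integer ids (names into `powers`) that must all exceed
#'   threshold.
#' @param baseline_end_s end of the resting baseline in seconds; windows with
#'   `t_end <= baseline_end_s` form the baseline.
#' @param threshold_frac fractional margin over the baseline maximum
#'   (default 0.15, must be > -1; 0 degenerates to exceeding the baseline
#'   maximum itself).
#' @return data frame of events: `window_id, t_start, t_end`, per-electrode
#'   `power_<id>`, and `threshold_<id>`.  Zero rows when nothing exceeds.
#' @export
gate_events <- function(powers, electrodes, baseline_end_s,
                        threshold_frac = 0.15) {
  if (threshold_frac <= -1) stop("threshold_frac must exceed -1")
  stopifnot(length(electrodes) >= 1)
  grid <- powers[[as.character(electrodes[1])]]
  base <- grid$t_end <= baseline_end_s + 1e-9
  if (!any(base)) stop("no complete baseline windows before ",
                       baseline_end_s, " s")
  eval_w <- grid$t_start >= baseline_end_s - 1e-9
  ok <- rep(TRUE, nrow(grid))
  ev <- grid[, c("window_id", "t_start", "t_end")]
  for (e in electrodes) {
    p <- powers[[as.character(e)]]$power
    thr <- (1 + threshold_frac) * max(p[base])
    ok <- ok & (p > thr)
    ev[[paste0("power_", e)]] <- p
    ev[[paste0("threshold_", e)]] <- thr
  }
  ev[ok & eval_w, , drop = FALSE]
}

#' Pick the strongest electrode in each group
#'
#' Argmax of task-epoch band power within the horizontally and the vertically
#' arranged electrode groups; ties break deterministically to the lowest id.
#'
#' @param epoch_powers named numeric vector of per-electrode power over a
#'   calibration task epoch (names are electrode ids).
#' @param horizontal,vertical integer ids of the two groups (defaults 1:2 and
#'   3:5, the patch layout: two electrodes above the optode grid, three along
#'   its side).
#' @return list with `horizontal` and `vertical` winning ids.
#' @export
select_electrodes <- function(epoch_powers, horizontal = 1:2,
                              vertical = 3:5) {
  pick <- function(ids) {
    if (length(ids) == 0) stop("empty electrode group")
    p <- epoch_powers[as.character(ids)]
    if (any(is.na(p))) stop("missing power for electrode(s) ",
                            paste(ids[is.na(p)], collapse = ", "))
    ids[which.max(p)]   # which.max returns the first (lowest-id) maximum
  }
  list(horizontal = pick(horizontal), vertical = pick(vertical))
}

#' Electrode-pair to candidate fNIRS channel cross-check map
#'
#' The optode patch has 12 emitters in a 4-row x 3-column grid; pairing with
#' detector d shifts the emitter index by `12 * (d - 1)`, giving channels
#' 1-36.  The two horizontal electrodes sit above column pairs (electrode 1
#' over columns 2-3, electrode 2 over columns 1-2) and the three vertical
#' electrodes beside row pairs (electrode 3 by rows 3-4, 4 by rows 2-3, 5 by
#' rows 1-2).  The four emitters at the intersection of the winning column
#' pair and row pair are the base channels, replicated across the three
#' detector rows (+0, +12, +24) to give the 12 candidate channels.
#'
#' @param col_pairs,row_pairs named lists overriding the default geometry
#'   (names are electrode ids, values column/row index pairs).
#' @return named list keyed `"<horizontal>-<vertical>"`, each a sorted
#'   integer vector of 12 channel ids.
#' @export
#' @examples
#' cross_check_map()[["1-4"]]  # 5 6 8 9 17 18 20 21 29 30 32 33
cross_check_map <- function(col_pairs = list(`1` = c(2, 3), `2` = c(1, 2)),
                            row_pairs = list(`3` = c(3, 4), `4` = c(2, 3),
                                             `5` = c(1, 2))) {
  out <- list()
  for (h in names(col_pairs)) for (v in names(row_pairs)) {
    base <- as.vector(outer(col_pairs[[h]], (row_pairs[[v]] - 1) * 3, `+`))
    out[[paste0(h, "-", v)]] <- sort(as.vector(outer(base, c(0, 12, 24), `+`)))
  }
  out
}

#' Candidate fNIRS channels for a selected electrode pair
#'
#' @param pair list with `horizontal` and `vertical` electrode ids (as from
#'   [select_electrodes()]).
#' @param map a [cross_check_map()].
#' @return integer vector of 12 channel ids.
#' @export
candidate_channels <- function(pair, map = cross_check_map()) {
  key <- paste0(pair$horizontal, "-", pair$vertical)
  if (is.null(map[[key]]))
    stop("electrode pair (", key, ") not present in the cross-check map; ",
         "supply it via the map argument")
  map[[key]]
}
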