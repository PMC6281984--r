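## linear interpolation of the first upward crossing of radius r at or after
## sample i0 (1-based), scanning no further than sample i1; requires the
## exceeding sample to lie in the fourth quadrant. Returns NA when none.
.first_crossing <- function(mag, q4, times, r, i0, i1, upward_only = FALSE) {
  if (i0 > i1) return(NA_real_)
  for (i in i0:i1) {
    if (mag[i] > r && q4[i]) {
      if (i > 1 && mag[i - 1] <= r) {
        dt <- times[i] - times[i - 1]
        return(times[i - 1] + dt * (r - mag[i - 1]) / (mag[i] - mag[i - 1]))
      }
      if (upward_only) next       # already above: not an outward crossing
      return(times[i])
    }
  }
  NA_real_
}

#' Gate-triggered trajectory crossing detection
#'
#' The headline detection rule.  For every EEG gate event: the inner circle
#' radius `r2` is computed (per [eeg_window_radius()]) from the hemodynamic
#' samples of the 1-s window that fired the gate; the trajectory is then
#' monitored from the window end, and the gate resolves to *detected* iff,
#' while in the fourth quadrant (dHbO > 0, dHbR < 0), the vector magnitude
#' exceeds `r2` and subsequently crosses the resting circle `r1` outward,
#' within `timeout_s` of the gate.  Crossing times are linearly interpolated
#' between samples.  A trajectory already outside `r1` when the gate fires
#' (e.g. the decaying tail of an earlier response) is not an outward crossing
#' and does not detect.  When a window's `r2 >= r1`, `r2` eligibility implies
#' immediate eligibility and the decision rests on the `r1` crossing alone.
#'
#' With `reference = "window"` the trajectory and the inner-circle formula
#' are referenced to the gate window's mean (dHbO, dHbR): the diagram then
#' measures the excursion that follows the EEG event rather than the
#' excursion from the session-wide filter baseline.  This makes the detector
#' robust to the slow offset that any high-pass filter leaves under a
#' repeated-trial response train (see the methods vignette); `"none"` is the
#' literal unreferenced rule.
#'
#' @param h band-passed [hemo_series()] for one channel.
#' @param gates gate-event data frame from [gate_events()].
#' @param r1 resting-state circle radius (> 0) from the pre-rest baseline
#'   (referenced consistently with `reference`).
#' @param timeout_s monitoring horizon after each gate (default 3 s).
#' @param sched optional [paradigm_schedule()] used to attach trial ids.
#' @param reference `"none"` (default) or `"window"`.
#' @return data frame, one row per gate event: `channel_id, window_id,
#'   gate_time, r2, r2_cross_time, r1_cross_time, latency, command_time,
#'   decision, trial_id`.  `latency = r1_cross_time - r2_cross_time`;
#'   `command_time` equals the `r1` crossing.
#' @export
detect_crossings <- function(h, gates, r1, timeout_s = 3, sched = NULL,
                             reference = c("none", "window")) {
  reference <- match.arg(reference)
  stopifnot(inherits(h, "hemo_series"))
  if (!is.finite(r1) || r1 <= 0)
    stop("r1 must be positive: the resting baseline is empty, constant, ",
         "or was not supplied")
  n <- length(h$hbo)
  times <- (seq_len(n) - 1) / h$rate

  out <- vector("list", nrow(gates))
  for (g in seq_len(nrow(gates))) {
    t0 <- gates$t_start[g]; t1 <- gates$t_end[g]
    win <- which(times >= t0 - 1e-9 & times <= t1 + 1e-9)
    if (!length(win)) next
    i1 <- min(n, floor((t1 + timeout_s) * h$rate + 1e-9) + 1L)
    sl <- win[1]:i1                       # window + monitoring slice
    hbo <- h$hbo[sl]; hbr <- h$hbr[sl]
    if (reference == "window") {
      w_loc <- seq_along(win)
      hbo <- hbo - mean(hbo[w_loc])
      hbr <- hbr - mean(hbr[w_loc])
    }
    mag <- sqrt(hbo^2 + hbr^2)
    q4 <- hbo > 0 & hbr < 0
    tsl <- times[sl]
    r2 <- eeg_window_radius(hbo[seq_along(win)], hbr[seq_along(win)])
    i0 <- length(win) + 1L
    iN <- length(sl)
    t_r2 <- .first_crossing(mag, q4, tsl, r2, i0, iN)
    if (!is.na(t_r2)) t_r2 <- max(t_r2, t1)   # a crossing cannot precede
    t_r1 <- NA_real_                          # the gate that armed it
    if (!is.na(t_r2)) {
      if (r2 >= r1) {
        ## inverted circles: passing the (outer) EEG-window circle already
        ## puts the trajectory beyond r1, so the r2 crossing is the command
        t_r1 <- t_r2
      } else {
        j0 <- max(i0, findInterval(t_r2, tsl))
        ## unreferenced trajectories may sit outside r1 for reasons
        ## unrelated to this gate (e.g. the decaying tail of an earlier
        ## response), so only an outward crossing counts; window-referenced
        ## excursions cannot (a decaying tail has negative dHbO excursion
        ## and fails the fourth-quadrant test), so immediate exceedance is
        ## a detection
        t_r1 <- .first_crossing(mag, q4, tsl, r1, j0, iN,
                                upward_only = (reference == "none"))
        if (!is.na(t_r1)) t_r1 <- max(t_r1, t_r2)
      }
    }
    detected <- !is.na(t_r1)
    trial <- NA_integer_
    if (!is.null(sched)) {
      k <- which(t1 >= sched$onsets & t1 < sched$onsets + sched$trial_s)
      if (length(k)) trial <- k[1]
    }
    out[[g]] <- data.frame(
      channel_id = h$channel_id, window_id = gates$window_id[g],
      gate_time = t1, r2 = r2, r2_cross_time = t_r2, r1_cross_time = t_r1,
      latency = if (detected) t_r1 - t_r2 else NA_real_,
      command_time = if (detected) t_r1 else NA_real_,
      decision = if (detected) "detected" else "not-detected",
      trial_id = trial)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(channel_id = integer(0), window_id = integer(0),
                      gate_time = numeric(0), r2 = numeric(0),
                      r2_cross_time = numeric(0), r1_cross_time = numeric(0),
                      latency = numeric(0), command_time = numeric(0),
                      decision = character(0), trial_id = integer(0))
  res
}

#' Round-to-one-decimal percentage accuracy
#'
#' `100 * n_correct / n_total` reported to one decimal: 10/12 gives 83.3,
#' 11/12 gives 91.7.
#'
#' @param n_correct,n_total counts.
#' @return scalar percentage.
#' @export
trial_accuracy <- function(n_correct, n_total) {
  if (n_total <= 0) stop("empty record set")
  round(100 * n_correct / n_total, 1)
}

#' Score detections into per-trial outcomes
#'
#' A trial is predicted *task* iff any monitored channel produced a detection
#' whose resting-circle crossing falls within `decision_horizon_s` of the
#' trial onset.  Each trial contributes one matched *rest* negative, a window
#' time-locked `rest_offset_s` after the onset (mid-rest), predicted task iff
#' a detection crossing falls inside it — giving 12 negatives to balance the
#' 12 positives at the defaults.
#'
#' @param records detection records (rows from [detect_crossings()], possibly
#'   several channels bound together).
#' @param sched a [paradigm_schedule()].
#' @param decision_horizon_s window after onset in which a crossing counts
#'   (default 1.5 s, the method's command-generation window).
#' @param rest_offset_s offset of the negative-class windows (default 15 s).
#' @return object of class `trial_outcomes`: data frame `trial_id, truth,
#'   predicted, correct` (2 rows per trial) with the percentage `accuracy`
#'   attached as an attribute.
#' @export
classify_trials <- function(records, sched, decision_horizon_s = 1.5,
                            rest_offset_s = 15) {
  stopifnot(inherits(sched, "paradigm_schedule"))
  hit <- function(t0) {
    any(records$decision == "detected" &
          !is.na(records$r1_cross_time) &
          records$r1_cross_time >= t0 &
          records$r1_cross_time <= t0 + decision_horizon_s)
  }
  rows <- lapply(seq_len(sched$n_trials), function(i) {
    o <- sched$onsets[i]
    data.frame(trial_id = c(i, i), truth = c("task", "rest"),
               predicted = ifelse(c(hit(o), hit(o + rest_offset_s)),
                                  "task", "rest"))
  })
  out <- do.call(rbind, rows)
  out$correct <- out$truth == out$predicted
  acc <- trial_accuracy(sum(out$correct), nrow(out))
  structure(out, accuracy = acc, class = c("trial_outcomes", "data.frame"))
}

#' @export
print.trial_outcomes <- function(x, ...) {
  cat("Trial outcomes:", sum(x$correct), "/", nrow(x),
      "correct =", attr(x, "accuracy"), "%\n")
  print.data.frame(x, ...)
  invisible(x)
}

## ridge-regularized two-class LDA with grouped leave-one-out CV; fallback
## when the within-class scatter is singular (e.g. more features than
## windows).  standardization is computed inside each training fold only.
.ridge_lda_cv <- function(x, y, folds, lambda = 1e-2) {
  n <- nrow(x)
  pred <- character(n)
  lev <- sort(unique(y))
  for (f in unique(folds)) {
    te <- which(folds == f); tr <- which(folds != f)
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    scl[scl < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    xt <- xs[tr, , drop = FALSE]; yt <- y[tr]
    mu <- lapply(lev, function(l) colMeans(xt[yt == l, , drop = FALSE]))
    cen <- xt
    for (l in seq_along(lev))
      cen[yt == lev[l], ] <- sweep(xt[yt == lev[l], , drop = FALSE], 2,
                                   mu[[l]])
    S <- crossprod(cen) / (nrow(xt) - 2)
    S <- S + lambda * mean(diag(S)) * diag(ncol(x))
    w <- solve(S, mu[[2]] - mu[[1]])
    thr <- as.numeric(crossprod(w, (mu[[1]] + mu[[2]]) / 2))
    sc <- xs[te, , drop = FALSE] %*% w
    pred[te] <- ifelse(as.numeric(sc) > thr, lev[2], lev[1])
  }
  pred
}

#' Linear discriminant baseline with leave-one-trial-out cross-validation
#'
#' Two-class LDA on per-window feature vectors, scored by cross-validated
#' accuracy with one fold per trial (both windows of a trial are held out
#' together).  When the within-class scatter is singular (collinear or
#' over-complete features), a ridge-regularized discriminant is used
#' instead and the fallback is recorded on the result.
#'
#' @param features numeric matrix, one row per window.
#' @param labels character/factor vector of two classes.
#' @param folds fold ids (e.g. trial numbers), one per window; default one
#'   fold per window (plain leave-one-out).
#' @return percentage accuracy (see [trial_accuracy()]) with attributes
#'   `predicted` and `fallback` (logical: ridge path taken).
#' @export
lda_baseline <- function(features, labels, folds = seq_len(nrow(features))) {
  x <- as.matrix(features)
  y <- as.character(labels)
  if (length(unique(y)) < 2) stop("need two classes")
  stopifnot(length(folds) == nrow(x))
  keep <- apply(x, 2, function(c) stats::sd(c) > 1e-12)
  x <- x[, keep, drop = FALSE]
  fallback <- FALSE
  pred <- rep(NA_character_, nrow(x))
  plain_loo <- length(unique(folds)) == nrow(x)
  if (plain_loo) {
    pred <- tryCatch(
      as.character(suppressWarnings(
        MASS::lda(x, grouping = factor(y), CV = TRUE)$class)),
      error = function(e) rep(NA_character_, nrow(x)))
  } else {
    pred <- tryCatch({
      p <- rep(NA_character_, nrow(x))
      for (f in unique(folds)) {
        te <- folds == f
        fit <- suppressWarnings(MASS::lda(x[!te, , drop = FALSE],
                                          grouping = factor(y[!te])))
        p[te] <- as.character(stats::predict(fit,
                                             x[te, , drop = FALSE])$class)
      }
      p
    }, error = function(e) rep(NA_character_, nrow(x)))
  }
  if (anyNA(pred)) {
    fallback <- TRUE
    pred <- .ridge_lda_cv(x, y, folds)
  }
  acc <- trial_accuracy(sum(pred == y), length(y))
  attr(acc, "predicted") <- pred
  attr(acc, "fallback") <- fallback
  acc
}
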