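#' Block-design task/rest paradigm on a sampling clock
#'
#' Builds the boxcar stimulus sequence `s(k)` and the trial bookkeeping for a
#' block paradigm: a pre-rest baseline, `n_trials` trials of task followed by
#' rest, and a post-rest tail.  Times are seconds, zero at paradigm start;
#' sample `k` (0-based) sits at `k / rate` seconds.
#'
#' @param n_trials number of trials (default 12).
#' @param task_s task duration per trial, seconds (default 10).
#' @param rest_s rest duration per trial, seconds (default 20).
#' @param pre_rest_s initial baseline rest, seconds (default 60).
#' @param post_rest_s final rest, seconds (default 10).
#' @param rate sampling rate in Hz the boxcar is laid out on (default 9.19,
#'   the fNIRS clock).
#'
#' @return An object of class `paradigm_schedule`: a list with the sample
#'   `times` (s), the binary boxcar `s`, trial `onsets` (s), the trial length
#'   `trial_s`, a `segments` data frame labelling every instant of the
#'   timeline (`pre_rest`, `task`, `rest`, `post_rest`) without gaps or
#'   overlaps, and the constructor arguments.
#' @export
#' @examples
#' sched <- paradigm_schedule(n_trials = 2, rate = 10)
#' table(sched$s)
paradigm_schedule <- function(n_trials = 12, task_s = 10, rest_s = 20,
                              pre_rest_s = 60, post_rest_s = 10, rate = 9.19) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (rate <= 0) stop("rate must be positive")
  if (task_s <= 0 || rest_s < 0 || pre_rest_s < 0 || post_rest_s < 0)
    stop("durations must be non-negative (task_s strictly positive)")

  trial_s <- task_s + rest_s
  total_s <- pre_rest_s + n_trials * trial_s + post_rest_s
  n <- floor(total_s * rate + 1e-9)
  times <- (seq_len(n) - 1) / rate
  onsets <- pre_rest_s + (seq_len(n_trials) - 1) * trial_s

  s <- integer(n)
  for (o in onsets) s[times >= o - 1e-12 & times < o + task_s - 1e-12] <- 1L

  segs <- data.frame(
    t0 = c(0, as.vector(rbind(onsets, onsets + task_s))),
    t1 = c(pre_rest_s, as.vector(rbind(onsets + task_s, onsets + trial_s))),
    label = c("pre_rest", rep(c("task", "rest"), n_trials)),
    trial = c(NA_integer_, rep(seq_len(n_trials), each = 2)),
    stringsAsFactors = FALSE
  )
  if (post_rest_s > 0) {
    segs <- rbind(segs, data.frame(t0 = total_s - post_rest_s, t1 = total_s,
                                   label = "post_rest", trial = NA_integer_))
  }

  structure(list(times = times, s = s, onsets = onsets,
                 n_trials = n_trials, task_s = task_s, rest_s = rest_s,
                 pre_rest_s = pre_rest_s, post_rest_s = post_rest_s,
                 trial_s = trial_s, total_s = total_s, rate = rate,
                 segments = segs),
            class = "paradigm_schedule")
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat("Block paradigm:", x$n_trials, "trials of", x$task_s, "s task /",
      x$rest_s, "s rest;", x$pre_rest_s, "s pre-rest,", x$post_rest_s,
      "s post-rest\n")
  cat("  ", length(x$times), "samples at", x$rate, "Hz (", x$total_s,
      "s total)\n")
  invisible(x)
}

#' Task membership of arbitrary time points
#'
#' @param sched a [paradigm_schedule()].
#' @param t numeric vector of times in seconds.
#' @return logical vector, `TRUE` where `t` falls inside a task block
#'   (onset inclusive, offset exclusive).
#' @export
in_task <- function(sched, t) {
  stopifnot(inherits(sched, "paradigm_schedule"))
  out <- rep(FALSE, length(t))
  for (o in sched$onsets) out <- out | (t >= o - 1e-12 & t < o + sched$task_s - 1e-12)
  out
}
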