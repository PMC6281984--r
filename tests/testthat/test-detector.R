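# analytic fourth-quadrant ray at 10 Hz: hbo = v t, hbr = -v t / 3, so the
# vector magnitude is exactly t and the line-circle crossing of radius r
# happens at t = 3 r / (v sqrt(10))
ray_series <- function(v = 3 / sqrt(10), rate = 10, dur = 6) {
  t <- seq(0, dur, by = 1 / rate)
  hemo_series(v * t, -v * t / 3, rate, channel_id = 1L)
}

one_gate <- function(t_start = 0, t_end = 1) {
  data.frame(window_id = 1L, t_start = t_start, t_end = t_end)
}

test_that("the analytic ray reproduces the 0.5 s crossing narrative", {
  h <- ray_series()
  rec <- detect_crossings(h, one_gate(), r1 = 1.5, timeout_s = 3)
  expect_equal(rec$decision, "detected")
  # Eq.-style inner radius over [0, 1]: component maxima at the window end
  expect_equal(rec$r2, 1, tolerance = 1e-9)
  expect_equal(rec$r2_cross_time, 1.0, tolerance = 1e-9)
  expect_equal(rec$r1_cross_time, 1.5, tolerance = 1e-9)
  expect_equal(rec$latency, 0.5, tolerance = 1e-9)
  expect_equal(rec$command_time, 1.5, tolerance = 1e-9)
  # line-circle closed form t = 3 r / (v sqrt(10)) for both circles
  v <- 3 / sqrt(10)
  expect_equal(rec$r2_cross_time, 3 * rec$r2 / (v * sqrt(10)),
               tolerance = 1e-9)
  expect_equal(rec$r1_cross_time, 3 * 1.5 / (v * sqrt(10)),
               tolerance = 1e-9)
})

test_that("gate precedence: no gates means no detections", {
  h <- ray_series()
  gates0 <- one_gate()[0, ]
  rec <- detect_crossings(h, gates0, r1 = 0.5)
  expect_equal(nrow(rec), 0)
})

test_that("trajectories outside the fourth quadrant never detect", {
  t <- seq(0, 6, by = 0.1)
  h2 <- hemo_series(-t, t / 3, 10)             # second quadrant ray
  rec <- detect_crossings(h2, one_gate(), r1 = 1.5)
  expect_equal(rec$decision, "not-detected")
  h3 <- hemo_series(t, t / 3, 10)              # first quadrant
  expect_equal(detect_crossings(h3, one_gate(), r1 = 1.5)$decision,
               "not-detected")
})

test_that("inverted circles (r2 >= r1) still detect at the r1 crossing", {
  h <- ray_series()
  rec <- detect_crossings(h, one_gate(), r1 = 0.5)   # r1 < r2 = 1
  expect_equal(rec$decision, "detected")
  # eligibility is immediate once past r2; the decision stamps the r1 pass
  expect_equal(rec$r1_cross_time, max(rec$r2_cross_time, 0.5),
               tolerance = 1e-9)
})

test_that("a timeout expires unresolved gates silently", {
  h <- ray_series(v = 0.05, dur = 40)          # too slow to reach r1 in 3 s
  rec <- detect_crossings(h, one_gate(), r1 = 1.5, timeout_s = 3)
  expect_equal(rec$decision, "not-detected")
  rec2 <- detect_crossings(h, one_gate(), r1 = 1.5, timeout_s = 35)
  expect_equal(rec2$decision, "detected")
})

test_that("degenerate resting radius is rejected", {
  expect_error(detect_crossings(ray_series(), one_gate(), r1 = 0),
               "baseline")
})

test_that("latency ordering holds on every detected record", {
  for (ref in c("none", "window")) {
    s <- generate_session(mini_spec(seed = 31))
    d <- hybrid_detect(s, detect_config(reference = ref))
    det <- d$records[d$records$decision == "detected", ]
    if (nrow(det)) {
      expect_true(all(det$gate_time <= det$r2_cross_time + 1e-9))
      expect_true(all(det$r2_cross_time <= det$r1_cross_time + 1e-9))
      expect_true(all(det$latency >= -1e-9))
    }
  }
})

test_that("trial scoring implements the command window and rest negatives", {
  sched <- paradigm_schedule(n_trials = 3, rate = 10)
  rec <- data.frame(channel_id = 1L, window_id = 1L,
                    gate_time = c(60.5, 121),
                    r2 = 0.1,
                    r2_cross_time = c(60.9, 121.2),
                    r1_cross_time = c(61.2, 122.0),   # trial 1 in window,
                    latency = 0.3,                    # trial 3 too late
                    command_time = c(61.2, 122.0),
                    decision = "detected", trial_id = c(1L, 3L))
  out <- classify_trials(rec, sched)
  expect_equal(nrow(out), 6)
  task <- out[out$truth == "task", ]
  expect_equal(task$predicted, c("task", "rest", "rest"))
  expect_true(all(out$predicted[out$truth == "rest"] == "rest"))
  expect_equal(attr(out, "accuracy"), trial_accuracy(4, 6))
  # a crossing inside a rest window flags its negative
  rec2 <- rec
  rec2$r1_cross_time[2] <- sched$onsets[2] + 15.4
  out2 <- classify_trials(rec2, sched)
  expect_equal(out2$predicted[out2$truth == "rest" & out2$trial_id == 2],
               "task")
})

test_that("accuracy is reported to one decimal like the trial tables", {
  expect_equal(trial_accuracy(10, 12), 83.3)
  expect_equal(trial_accuracy(11, 12), 91.7)
  expect_equal(trial_accuracy(12, 12), 100)
  expect_equal(trial_accuracy(0, 12), 0)
  expect_error(trial_accuracy(1, 0), "empty")
})

test_that("LDA baseline separates separable features and not null ones", {
  set.seed(12)
  n <- 24
  y <- rep(c("task", "rest"), each = n / 2)
  x_sep <- cbind(ifelse(y == "task", 5, -5) + rnorm(n, 0, 0.1), rnorm(n))
  expect_equal(as.numeric(lda_baseline(x_sep, y)), 100)
  # identical class distributions: accuracy hovers around chance
  accs <- replicate(20, {
    x0 <- matrix(rnorm(n * 4), n)
    as.numeric(lda_baseline(x0, sample(y)))
  })
  expect_gt(mean(accs), 30)
  expect_lt(mean(accs), 65)
  expect_error(lda_baseline(x_sep, rep("task", n)), "two classes")
})

test_that("grouped folds hold both windows of a trial out together", {
  set.seed(13)
  n <- 24
  y <- rep(c("task", "rest"), each = 12)
  x <- cbind(rnorm(n) + 3 * (y == "task"), matrix(rnorm(n * 30), n))  # p > n
  folds <- rep(1:12, 2)
  acc <- lda_baseline(x, y, folds = folds)
  expect_length(attr(acc, "predicted"), n)
  expect_true(as.numeric(acc) >= 0 && as.numeric(acc) <= 100)
  # the ridge fallback path itself classifies a separable problem
  x2 <- cbind(rnorm(n) + 3 * (y == "task"), matrix(rnorm(n * 10), n))
  pred <- hybridphase:::.ridge_lda_cv(x2, y, folds)
  expect_gt(mean(pred == y), 0.7)
})

test_that("detection rate never falls as task amplitude grows", {
  rates <- vapply(c(1e-3, 3e-3, 9e-3), function(a) {
    s <- generate_session(mini_spec(seed = 33, amp_hbo = a))
    d <- hybrid_detect(s)
    oc <- d$outcomes
    mean(oc$correct[oc$truth == "task"])
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
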