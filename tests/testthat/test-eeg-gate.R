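test_that("window power matches the analytic mean square", {
  rate <- 256
  t <- seq(0, 5, by = 1 / rate)
  expect_equal(window_power(rep(0, 1000), rate, 1), 0)
  tone <- sin(2 * pi * 16 * t)                 # integer cycles per second
  expect_equal(window_power(tone, rate, 2), 0.5, tolerance = 1e-3)
  expect_equal(window_power(2 * tone, rate, 2),
               4 * window_power(tone, rate, 2), tolerance = 1e-12)
  expect_error(window_power(tone, rate, 4.5), "inside")
})

test_that("power stream agrees with windowed recomputation", {
  set.seed(11)
  rate <- 64
  x <- rnorm(10 * rate)
  ps <- power_stream(x, rate, window_s = 1, hop_s = 0.5)
  for (i in c(1, 5, nrow(ps))) {
    expect_equal(ps$power[i], window_power(x, rate, ps$t_start[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(ps$t_end - ps$t_start - 1) < 1e-9))
})

test_that("gate fires only on strict exceedance of the 15% margin", {
  # constant power everywhere: nothing exceeds its own baseline maximum
  ps <- data.frame(window_id = 1:40, t_start = (0:39) / 2,
                   t_end = (0:39) / 2 + 1, power = 1)
  ev <- gate_events(list(`1` = ps), 1, baseline_end_s = 10)
  expect_equal(nrow(ev), 0)
  # a window 20% above baseline max fires; 10% above does not
  ps2 <- ps; ps2$power[30] <- 1.2; ps2$power[35] <- 1.1
  ev2 <- gate_events(list(`1` = ps2), 1, baseline_end_s = 10)
  expect_equal(ev2$window_id, 30)
  # threshold_frac = 0 degenerates to exceeding the baseline max
  ev3 <- gate_events(list(`1` = ps2), 1, baseline_end_s = 10,
                     threshold_frac = 0)
  expect_setequal(ev3$window_id, c(30, 35))
  # with two electrodes, both must exceed
  ps3 <- ps; ps3$power[30] <- 1.01
  ev4 <- gate_events(list(`1` = ps2, `2` = ps3), c(1, 2),
                     baseline_end_s = 10)
  expect_equal(nrow(ev4), 0)
  expect_error(gate_events(list(`1` = ps), 1, baseline_end_s = 0), "baseline")
})

test_that("gates on a beta-modulated session localize to task windows", {
  sp <- mini_spec(seed = 21,
                  noise = noise_spec(eeg_beta_gain_task = 2.5,
                                     eeg_trial_gain_sdlog = 0,
                                     eeg_task_ramp_s = 0, eeg_bg_sdlog = 0,
                                     eeg_burst_rate_hz = 0))
  s <- generate_session(sp)
  bands <- eeg_band_decompose(s$eeg[, 1], sp$eeg_rate)
  ps <- power_stream(bands$beta, sp$eeg_rate, hop_s = 1 / sp$fnirs_rate)
  ev <- gate_events(list(`1` = ps), 1, baseline_end_s = sp$pre_rest_s)
  expect_gt(nrow(ev), 10)
  # every event window overlaps a task block (1-window slack at the edges)
  near_task <- vapply(seq_len(nrow(ev)), function(i) {
    any(in_task(s$schedule, seq(ev$t_start[i] - 0.15, ev$t_end[i] + 0.15,
                                by = 0.05)))
  }, logical(1))
  expect_true(all(near_task))
  # and every trial is hit
  hit <- vapply(s$schedule$onsets, function(o)
    any(ev$t_end >= o & ev$t_end < o + sp$task_s), logical(1))
  expect_true(all(hit))
})

test_that("a null session produces (close to) no gate events", {
  sp <- mini_spec(seed = 22,
                  noise = noise_spec(eeg_beta_gain_task = 1,
                                     eeg_trial_gain_sdlog = 0,
                                     eeg_task_ramp_s = 0, eeg_bg_sdlog = 0,
                                     eeg_burst_rate_hz = 0))
  s <- generate_session(sp)
  bands <- eeg_band_decompose(s$eeg[, 1], sp$eeg_rate)
  ps <- power_stream(bands$beta, sp$eeg_rate, hop_s = 1 / sp$fnirs_rate)
  ev <- gate_events(list(`1` = ps), 1, baseline_end_s = sp$pre_rest_s)
  # strict exceedance of the baseline max by 15%: false-alarm windows are
  # a small fraction of the ~1200 evaluated windows
  expect_lt(nrow(ev) / nrow(ps), 0.02)
})

test_that("beta power is insensitive to out-of-band additions", {
  rate <- 256
  t <- seq(0, 20, by = 1 / rate)
  x <- sin(2 * pi * 16 * t)
  p1 <- window_power(eeg_band_decompose(x, rate)$beta, rate, 10)
  p2 <- window_power(eeg_band_decompose(x + sin(2 * pi * 2 * t), rate)$beta,
                     rate, 10)
  expect_lt(abs(p2 - p1) / p1, 0.05)
})

test_that("electrode selection takes the groupwise argmax with low-id ties", {
  p <- c(`1` = 5, `2` = 3, `3` = 1, `4` = 7, `5` = 2)
  sel <- select_electrodes(p)
  expect_equal(sel, list(horizontal = 1L, vertical = 4L))
  p2 <- c(`1` = 5, `2` = 3, `3` = 7, `4` = 1, `5` = 2)
  expect_equal(select_electrodes(p2)$vertical, 3L)
  ptie <- c(`1` = 5, `2` = 5, `3` = 2, `4` = 2, `5` = 2)
  expect_equal(select_electrodes(ptie),
               list(horizontal = 1L, vertical = 3L))
  expect_error(select_electrodes(p, horizontal = integer(0)), "empty")
})

test_that("cross-check map reproduces the catalogued electrode-pair rows", {
  m <- cross_check_map()
  expect_equal(candidate_channels(list(horizontal = 1, vertical = 4), m),
               c(5, 6, 8, 9, 17, 18, 20, 21, 29, 30, 32, 33))
  expect_equal(candidate_channels(list(horizontal = 1, vertical = 3), m),
               c(8, 9, 11, 12, 20, 21, 23, 24, 32, 33, 35, 36))
  for (k in names(m)) {
    ch <- m[[k]]
    expect_length(ch, 12)
    expect_true(all(ch %in% 1:36))
    base <- ch[ch <= 12]
    expect_length(base, 4)
    expect_setequal(ch, c(base, base + 12, base + 24))  # detector replicas
  }
  expect_error(candidate_channels(list(horizontal = 9, vertical = 9), m),
               "not present")
})
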