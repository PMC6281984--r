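test_that("canonical kernel has the expected analytic properties", {
  t <- seq(0, 40, by = 0.01)
  h <- canonical_hrf(t)
  expect_equal(h[1], 0)                       # h(0) = 0 for phi >= 2
  expect_equal(max(h), 1, tolerance = 1e-6)   # peak normalized
  pk <- t[which.max(h)]
  expect_gt(pk, 4); expect_lt(pk, 8)          # canonical peak envelope
  # exactly one sign change after the peak (positive lobe then undershoot)
  after <- h[t > pk & t < 35]
  flips <- sum(diff(sign(after[after != 0])) != 0)
  expect_equal(flips, 1)
  # zero amplitude collapses the kernel
  expect_equal(canonical_hrf(t, gamma_params(alpha1 = 0)), rep(0, length(t)))
  # negative times are zero
  expect_equal(canonical_hrf(c(-5, -0.1)), c(0, 0))
})

test_that("factorial form guards integer shapes, gamma form relaxes them", {
  expect_error(gamma_params(phi1 = 5.5), "gamma-function")
  p <- gamma_params(phi1 = 5.5, use_gamma_fn = TRUE)
  expect_s3_class(p, "gamma_params")
  expect_error(gamma_params(tau1 = 0), "tau")
  expect_error(gamma_params(alpha2 = 1), "alpha2")
})

test_that("designed HRF equals the double-loop convolution oracle", {
  sched <- paradigm_schedule(n_trials = 2, task_s = 3, rest_s = 4,
                             pre_rest_s = 5, post_rest_s = 2, rate = 5)
  p <- gamma_params()
  u <- designed_hrf(p, sched)
  h <- canonical_hrf(sched$times, p)
  s <- as.numeric(sched$s)
  oracle <- vapply(seq_along(s), function(i) {
    k <- i - 1
    if (k == 0) return(0)
    acc <- 0
    for (n in 0:(k - 1)) acc <- acc + h[n + 1] * s[k - n + 1]
    p$k1 * acc
  }, numeric(1))
  expect_equal(u, oracle, tolerance = 1e-10)
  expect_equal(u[sched$times < sched$onsets[1]],
               rep(0, sum(sched$times < sched$onsets[1])),
               tolerance = 1e-12)
})

test_that("dHRF is linear in the stimulus and the impulse response is k1*h", {
  sched <- paradigm_schedule(n_trials = 1, task_s = 2, rest_s = 3,
                             pre_rest_s = 4, post_rest_s = 1, rate = 8)
  p <- gamma_params()
  # zero stimulus
  s0 <- sched; s0$s <- rep(0L, length(sched$s))
  expect_equal(designed_hrf(p, s0), rep(0, length(sched$s)))
  # impulse at sample k0 reproduces the shifted kernel
  k0 <- 10L
  si <- sched; si$s <- rep(0L, length(sched$s)); si$s[k0 + 1] <- 1L
  u <- designed_hrf(p, si)
  h <- canonical_hrf(sched$times, p)
  expect_equal(u[(k0 + 2):length(u)],
               p$k1 * h[2:(length(u) - k0)], tolerance = 1e-10)
  # additivity over disjoint stimuli
  sa <- sched; sa$s <- rep(0L, length(sched$s)); sa$s[15] <- 1L
  sb <- sched; sb$s <- rep(0L, length(sched$s)); sb$s[25] <- 1L
  sab <- sched; sab$s <- sa$s + sb$s
  expect_equal(designed_hrf(p, sab),
               designed_hrf(p, sa) + designed_hrf(p, sb),
               tolerance = 1e-12)
})

test_that("dHRF for the default block design peaks well after the kernel", {
  sched <- paradigm_schedule(n_trials = 1, pre_rest_s = 20,
                             post_rest_s = 30, rate = 9.19)
  u <- designed_hrf(gamma_params(), sched)
  lag <- sched$times[which.max(u)] - sched$onsets[1]
  # the 10-s boxcar shifts the response peak to ~11-12 s after onset
  expect_gt(lag, 10); expect_lt(lag, 13)
})

test_that("ideal trajectory is exactly collinear and confined to phases 7/8", {
  sched <- paradigm_schedule(n_trials = 2, task_s = 4, rest_s = 6,
                             pre_rest_s = 10, post_rest_s = 5, rate = 9.19)
  r <- 1 / 3
  traj <- ideal_trajectory(gamma_params(), sched, r = r)
  expect_equal(max(abs(traj$hbr + r * traj$hbo)), 0)   # residual is zero
  pos <- traj$hbo > 0
  expect_true(all(traj$phase[pos] %in% c(7, 8)))
  expect_equal(traj$angle_deg[pos],
               rep(atan(-r) * 180 / pi, sum(pos)), tolerance = 1e-9)
  # r = 1 runs along the phase 7/8 boundary at -45 degrees
  t1 <- ideal_trajectory(gamma_params(), sched, r = 1)
  expect_equal(unique(round(t1$angle_deg[t1$hbo > 0], 9)), -45)
  # alpha1 = 0 collapses to the origin
  t0 <- ideal_trajectory(gamma_params(alpha1 = 0), sched)
  expect_equal(max(t0$magnitude), 0)
  expect_error(ideal_trajectory(gamma_params(), sched, r = 0), "r must")
})
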