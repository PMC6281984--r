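test_that("45-degree rotation maps the named directions correctly", {
  expect_equal(hbt_coe(1, 1), list(hbt = sqrt(2), coe = 0))
  expect_equal(hbt_coe(1, -1), list(hbt = 0, coe = -sqrt(2)))
  # the angle identity: atan2(hbr, hbo) = atan(coe/hbt) + 45 deg
  r <- hbt_coe(2, 1)
  expect_equal(atan2(1, 2) * 180 / pi,
               atan(r$coe / r$hbt) * 180 / pi + 45, tolerance = 1e-12)
  expect_equal(atan2(1, 2) * 180 / pi, 26.5650512, tolerance = 1e-6)
})

test_that("rotation preserves the vector norm on random points", {
  set.seed(7)
  n <- 1e5
  hbo <- rnorm(n); hbr <- rnorm(n)
  r <- hbt_coe(hbo, hbr)
  expect_equal(r$hbt^2 + r$coe^2, hbo^2 + hbr^2, tolerance = 1e-12)
})

test_that("phase classifier agrees with the angle-octant oracle everywhere", {
  # dense polar grid plus every boundary angle exactly
  ang <- c(seq(-179.5, 180, by = 0.25), seq(-135, 180, by = 45))
  rad <- c(0.5, 1, 7)
  grid <- expand.grid(a = ang, r = rad)
  hbo <- grid$r * cos(grid$a * pi / 180)
  hbr <- grid$r * sin(grid$a * pi / 180)
  expect_equal(classify_phase(hbo, hbr), oracle_phase(hbo, hbr))
})

test_that("named example points fall in their documented phases", {
  expect_equal(classify_phase(1, 0.5), 1L)
  expect_equal(classify_phase(-1, 0.5), 4L)    # angle ~153.4 deg
  expect_equal(classify_phase(1, -0.5), 8L)    # hemodynamic, ~-26.6 deg
  expect_error(classify_phase(0, 0), "zero vector")
  expect_equal(classify_phase(0, 0, origin = "na"), NA_integer_)
})

test_that("sign patterns and flags follow the octant geometry", {
  mid <- seq(22.5, 337.5, by = 45)             # octant midpoints, phase 1..8
  mid[mid > 180] <- mid[mid > 180] - 360
  hbo <- cos(mid * pi / 180); hbr <- sin(mid * pi / 180)
  ph <- classify_phase(hbo, hbr)
  expect_equal(ph, 1:8)
  rot <- hbt_coe(hbo, hbr)
  sign_tab <- data.frame(
    phase = 1:8,
    hbo = c(1, 1, -1, -1, -1, -1, 1, 1),
    hbr = c(1, 1, 1, 1, -1, -1, -1, -1),
    hbt = c(1, 1, 1, -1, -1, -1, -1, 1),
    coe = c(-1, 1, 1, 1, 1, -1, -1, -1))
  expect_equal(sign(hbo), sign_tab$hbo)
  expect_equal(sign(hbr), sign_tab$hbr)
  expect_equal(sign(rot$hbt), sign_tab$hbt)
  expect_equal(sign(rot$coe), sign_tab$coe)
  fl <- phase_flags(ph)
  expect_equal(which(fl$dip), 3:5)
  expect_equal(which(fl$hemo), 7:8)
  # phases 7/8 are exactly the fourth quadrant
  set.seed(8)
  ho <- rnorm(2000); hr <- rnorm(2000)
  p <- classify_phase(ho, hr)
  expect_equal(p %in% 7:8, ho > 0 & hr < 0)
})

test_that("resting radius is the max paired per-sample magnitude", {
  expect_equal(resting_radius(c(0.1, -0.2), c(0.05, 0.1)),
               sqrt(0.05), tolerance = 1e-12)
  expect_equal(resting_radius(3, 4), 5)
  expect_equal(resting_radius(c(0, 0), c(0, 0)), 0)
  expect_error(resting_radius(numeric(0), numeric(0)), "empty")
})

test_that("EEG-window radius takes separate absolute component maxima", {
  expect_equal(eeg_window_radius(c(0.1, 0.3), c(-0.2, -0.1)),
               sqrt(0.09 + 0.04), tolerance = 1e-12)
  expect_equal(eeg_window_radius(0, 0), 0)
  # component lower bounds
  set.seed(9)
  ho <- rnorm(50); hr <- rnorm(50)
  r2 <- eeg_window_radius(ho, hr)
  expect_gte(r2, max(abs(ho)))
  expect_gte(r2, max(abs(hr)))
  expect_error(eeg_window_radius(numeric(0), numeric(0)), "empty")
})

test_that("both radii are scale equivariant", {
  set.seed(10)
  ho <- rnorm(100); hr <- rnorm(100)
  for (c0 in c(0.2, 3, 117)) {
    expect_equal(resting_radius(c0 * ho, c0 * hr),
                 c0 * resting_radius(ho, hr), tolerance = 1e-12)
    expect_equal(eeg_window_radius(c0 * ho, c0 * hr),
                 c0 * eeg_window_radius(ho, hr), tolerance = 1e-12)
  }
})

test_that("trajectory records are ordered and circle-consistent", {
  h <- hemo_series(rep(0, 20), rep(0, 20), 10)
  tr <- track_trajectory(h, r1 = 1, r2 = 0.5)
  expect_true(all(tr$in_r1 & tr$in_r2))
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(is.na(tr$phase)))
  # analytic ray: in_r2/in_r1 flip exactly at the closed-form crossings
  v <- 3 / sqrt(10)
  t <- (0:49) / 10
  ray <- hemo_series(v * t, -v * t / 3, 10)
  tr2 <- track_trajectory(ray, r1 = 1.5, r2 = 1)
  expect_equal(tr2$magnitude, t, tolerance = 1e-12)
  expect_equal(min(tr2$time[!tr2$in_r2]), 1.1, tolerance = 1e-9)
  expect_equal(min(tr2$time[!tr2$in_r1]), 1.6, tolerance = 1e-9)
  expect_error(track_trajectory(h, 1, 1, start_index = 21), "beyond")
})
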