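test_that("burst detection handles flat, square and merged inputs", {
  expect_identical(nrow(detect_bursts(rep(-60, 5000), fs = 1000)), 0L)

  # square wave, period 1 s, duty 0.4, 10 kHz: durations 0.4 s +/- 1 sample
  fs <- 10000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  v <- ifelse(t %% 1 < 0.4, -30, -60)
  b <- detect_bursts(v, fs = fs, min_gap = 0.05)
  expect_gte(nrow(b), 9)
  expect_true(all(abs(b$duration - 0.4) <= 1 / fs + 1e-12))

  # two depolarisations 10 ms apart merge under a 50 ms minimum gap
  v2 <- rep(-60, 3000)
  v2[1001:1100] <- -30
  v2[1201:1300] <- -30
  b2 <- detect_bursts(v2, fs = fs, min_gap = 0.05)
  expect_identical(nrow(b2), 1L)
  b3 <- detect_bursts(v2, fs = fs, min_gap = 0.005)
  expect_identical(nrow(b3), 2L)
})

test_that("burst tables are ordered, non-overlapping and positive", {
  tr <- free_run("rulkov_bursting", 12, fs = 2000, target_burst = 1,
                 live_range = c(-60, -25))
  b <- detect_bursts(tr, min_gap = 0.3)
  expect_true(all(b$duration > 0))
  expect_true(all(diff(b$onset) > 0))
  expect_true(all(b$onset[-1] > b$offset[-nrow(b)]))
  expect_true(all(b$v_max > b$v_min))
})

test_that("amplitude maps are exact two-point affine bijections", {
  map <- fit_amplitude_map(c(-2, 2), c(-60, -20))
  expect_equal(map$gain, 10)
  expect_equal(map$offset, -40)
  expect_equal(map_to_mv(map, c(-2, 2)), c(-60, -20))

  ident <- fit_amplitude_map(c(-60, -20), c(-60, -20))
  expect_equal(ident$gain, 1)
  expect_equal(map_to_mv(ident, -33.3), -33.3)

  set.seed(3)
  x <- stats::runif(100, -2, 2)
  expect_equal(map_to_model(map, map_to_mv(map, x)), x, tolerance = 1e-12)

  expect_error(fit_amplitude_map(c(1, 1), c(-60, -20)), "degenerate")
})

test_that("time-scale factors follow the interval arithmetic", {
  # map burst of 200 points shown at 1 s and 10 kHz: 50 samples per point
  expect_equal(fit_time_scale(200, 1, 10000, kind = "map"), 50)
  # native resolution round trip: scale 1
  expect_equal(fit_time_scale(1000, 1, 1000, kind = "map"), 1)
  # doubling fs doubles the interpolation ratio
  expect_equal(fit_time_scale(200, 1, 20000, kind = "map"),
               2 * fit_time_scale(200, 1, 10000, kind = "map"))
  # ODE: model-time per interval
  expect_equal(fit_time_scale(150, 1, 10000, kind = "ode"), 0.015)
  expect_error(fit_time_scale(200, -1, 10000), "target_burst")
})

test_that("map interpolation emits exactly r samples per point in the long run", {
  # r = 1 reproduces the raw sequence
  out <- interpolate_map_output(0.3, 0.9, r = 1, phase = 0)
  expect_identical(out$samples, 0.3)

  # midpoint at r = 2
  out <- interpolate_map_output(0, 1, r = 2, phase = 0)
  expect_identical(out$samples, c(0, 0.5))

  # accumulator-count oracle: r = 2.5 over 10 points emits exactly 25
  phase <- 0; count <- 0L
  for (k in 1:10) {
    out <- interpolate_map_output(k - 1, k, r = 2.5, phase = phase)
    count <- count + length(out$samples)
    phase <- out$phase
  }
  expect_identical(count, 25L)

  # emission-rate exactness property for random non-integer ratios
  set.seed(5)
  for (trial in 1:20) {
    r <- stats::runif(1, 0.3, 40)
    n_pts <- sample(20:200, 1)
    phase <- 0; count <- 0L
    for (k in seq_len(n_pts)) {
      out <- interpolate_map_output(0, 1, r = r, phase = phase)
      count <- count + length(out$samples)
      phase <- out$phase
    }
    expect_true(count %in% c(floor(n_pts * r), ceiling(n_pts * r)))
  }
})

test_that("drift compensation tracks a slow linear baseline shift", {
  # disabled: correction is exactly zero
  st <- drift_state(enabled = FALSE)
  expect_identical(update_drift(st, c(1, 2, 3))$correction, 0)

  # drift-free periodic signal: correction stays within noise of zero
  set.seed(9)
  st <- drift_state(tau_s = 2, window_s = 1)
  fs <- 1000
  correction <- NA
  for (w in 1:30) {
    t <- ((w - 1) * fs + 1):(w * fs) / fs
    win <- -55 + 10 * sin(2 * pi * t) + stats::rnorm(fs, 0, 0.1)
    up <- update_drift(st, win)
    st <- up$state; correction <- up$correction
  }
  expect_lt(abs(correction), 0.3)

  # 1 mV over the run recovered within 10%
  st <- drift_state(tau_s = 2, window_s = 1)
  for (w in 1:60) {
    t <- ((w - 1) * fs + 1):(w * fs) / fs
    win <- -55 + 10 * sin(2 * pi * t) + (1 / 60) * t
    up <- update_drift(st, win)
    st <- up$state; correction <- up$correction
  }
  expect_equal(correction, 1, tolerance = 0.1)

  expect_error(update_drift(drift_state(), numeric(0)), "non-empty")
})

test_that("calibration reproduces range, scale and warm state", {
  m <- neuron_preset("rulkov_bursting")
  cal <- calibrate_model(m, fs = 2000, target_burst = 0.5,
                         live_range = c(-58, -22))
  expect_s3_class(cal, "calibration")
  expect_equal(map_to_mv(cal$amplitude, cal$native_range), c(-58, -22))
  expect_equal(cal$time_scale$r, 0.5 * 2000 / cal$native_burst)
  expect_true(all(is.finite(cal$state_ready)))

  # calibrated free runs stay inside the live range (up to 1e-9)
  tr <- free_run(m, 8, fs = 2000, calibration = cal)
  expect_true(all(tr$v >= -58 - 1e-9 & tr$v <= -22 + 1e-9))
})
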