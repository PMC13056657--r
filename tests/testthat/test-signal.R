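test_that("manual exclusions mask exactly the requested samples", {
  w <- waveform(rep(10, 100 * 60), fs = 100, channel = "ICP")
  expect_identical(apply_manual_exclusions(w, NULL)$valid, w$valid)

  w2 <- apply_manual_exclusions(w, data.frame(start = 10, end = 40))
  expect_equal(sum(!w2$valid), 30 * 100)
  expect_true(all(!w2$valid[wf_time(w) >= 10 & wf_time(w) < 40]))

  expect_error(apply_manual_exclusions(w, data.frame(start = 40, end = 10)),
               "start < end")
  expect_error(
    apply_manual_exclusions(w, data.frame(start = c(0, 5), end = c(10, 15))),
    "overlap")
  expect_error(apply_manual_exclusions(w, data.frame(start = 0, end = 1e5)),
               "span")
})

test_that("coarse graining averages 10-s windows and tracks coverage", {
  w <- waveform(rep(7.5, 1000), fs = 10, channel = "ICP")
  tr <- coarse_grain(w)
  expect_true(all(tr$value == 7.5))
  expect_true(all(tr$coverage == 1))
  expect_equal(diff(tr$time), rep(10, nrow(tr) - 1))

  # ramp at 100 Hz: first window averages samples 0..999
  r <- waveform(seq(0, by = 1, length.out = 3000), fs = 100,
                channel = "ICP")
  expect_equal(coarse_grain(r)$value[1], 499.5)

  # a fully masked window yields a missing value with coverage 0
  w$valid[1:100] <- FALSE
  tr2 <- coarse_grain(w)
  expect_true(is.na(tr2$value[1]))
  expect_equal(tr2$coverage[1], 0)

  # global mean preserved over fully valid spans
  set.seed(1)
  x <- rnorm(50 * 600)
  wf <- waveform(x, fs = 50, channel = "ABP")
  expect_equal(mean(coarse_grain(wf)$value), mean(x), tolerance = 1e-12)
})

test_that("threshold filter rejects out-of-range values, bounds inclusive", {
  tr <- make_trend(c(-11, -10, 0, 59, 60, 61), "ICP")
  f <- threshold_filter(tr)
  expect_equal(is.na(f$value), c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))

  cpp <- make_trend(c(-1, 0, 150, 151), "CPP")
  fc <- threshold_filter(cpp)
  expect_equal(is.na(fc$value), c(TRUE, FALSE, FALSE, TRUE))

  inr <- make_trend(c(0, 10, 20), "ICP")
  expect_equal(threshold_filter(inr)$value, inr$value)

  # idempotent
  expect_identical(threshold_filter(f), f)
})

test_that("CPP trend is the value-wise ABP - ICP difference", {
  abp <- make_trend(c(91, 90, NA), "ABP")
  icp <- make_trend(c(9, NA, 10), "ICP")
  cpp <- cpp_trend(abp, icp)
  expect_equal(cpp$value[1], 82)
  expect_true(all(is.na(cpp$value[2:3])))
  expect_error(cpp_trend(abp, make_trend(c(1, 2), "ICP")), "timestamps")
})

test_that("pulse amplitude recovers the cardiac fundamental", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  w <- waveform(3 * sin(2 * pi * 1.5 * t), fs = fs, channel = "ICP")
  amp <- pulse_amplitude(w, heart_rate_band = c(1, 2))
  expect_true(all(abs(amp$value - 3) / 3 < 0.02))

  const <- waveform(rep(5, fs * 30), fs = fs, channel = "ICP")
  expect_true(all(pulse_amplitude(const, c(1, 2))$value == 0))

  expect_error(pulse_amplitude(w, c(2, 1)), "increasing")
  expect_error(pulse_amplitude(w, c(1, 80)), "Nyquist|within")
})

test_that("AMP grows with mean ICP across PEEP steps via the pressure-volume surrogate", {
  cfg <- sim_config(seed = 13, peep_icp_slope = 0.6, pv_knee_icp = 9,
                    vasoreactivity_gain = 0, slow_wave_amplitude = 0,
                    noise_sd = list(abp = 0, icp = 0.05, paw = 0, pes = 0,
                                    flow = 0))
  prot <- protocol_design("A1", step_minutes = 2)
  abp <- simulate_abp(cfg, 16 * 120)
  icp <- simulate_icp(abp, cfg, prot)
  amp <- pulse_amplitude(icp, c(1, 2.5))
  per_mean <- sapply(1:4, function(i) {
    sel <- amp$time > prot$start[i] + 30 &
      amp$time <= prot$start[i] + prot$duration[i]
    mean(amp$value[sel], na.rm = TRUE)
  })
  expect_true(all(diff(per_mean) > 0))
})

test_that("Fisher transform and its inverse behave as artanh/tanh", {
  expect_equal(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.5), atanh(0.5))
  expect_equal(fisher_transform(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(abs(inverse_fisher(fisher_transform(r)) - r) < 1e-9))
  # clipping keeps +/-1 finite
  expect_true(is.finite(fisher_transform(1)))
  idx <- index_series(c(60, 120), c(0.5, -1), c(30L, 30L), "PRx")
  z <- fisher_transform(idx)
  expect_equal(z$value[1], atanh(0.5))
  rt <- inverse_fisher(z)
  expect_equal(rt$value[1], 0.5, tolerance = 1e-9)
})
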