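test_that("occlusion detection finds the embedded holds and matches truth timing", {
  cfg <- quiet_config(seed = 10)
  prot <- protocol_design("A1", "prone_first", step_minutes = 2)
  vent <- simulate_ventilator(cfg, prot)
  occ <- detect_occlusions(vent$flow, vent$paw)
  expect_equal(nrow(occ), nrow(vent$holds))
  truth <- vent$holds[order(vent$holds$start), ]
  occ <- occ[order(occ$start), ]
  expect_equal(occ$kind, truth$kind)
  expect_true(all(abs(occ$start - truth$start) <= 0.2))
  expect_true(all(abs(occ$end - truth$end) <= 0.2))
})

test_that("strict zero-flow threshold and minimum duration rules apply", {
  set.seed(12)
  fs <- 50
  noisy <- waveform(rnorm(fs * 120, 0, 0.01), fs = fs, channel = "FLOW")
  paw <- waveform(rep(10, fs * 120), fs = fs, channel = "PAW")
  expect_equal(nrow(detect_occlusions(noisy, paw,
                                      zero_flow_threshold = 0)), 0L)

  # a 4-s hold passes the >= 3 s rule; a 2-s lull does not
  f <- rep(0.5, fs * 60)
  f[(10 * fs):(14 * fs - 1)] <- 0
  f[(30 * fs):(32 * fs - 1)] <- 0
  flow <- waveform(f, fs = fs, channel = "FLOW")
  p <- waveform(rep(c(20, 10), c(20 * fs, 40 * fs)), fs = fs,
                channel = "PAW")
  occ <- detect_occlusions(flow, p, zero_flow_threshold = 0.02)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$start, 10, tolerance = 0.05)
})

test_that("plateau pressure averages the settled tail of the hold", {
  fs <- 100
  w <- waveform(rep(21, fs * 5), fs = fs, channel = "PAW")
  occ <- data.frame(start = 0, end = 5)
  expect_equal(plateau_pressure(w, occ), 21)

  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  settle <- waveform(21 + 8 * exp(-t / 0.3), fs = fs, channel = "PAW")
  expect_lt(abs(plateau_pressure(settle, occ) - 21), 0.05)

  expect_error(plateau_pressure(w, data.frame(start = 0, end = 1.5)),
               "2 s")
})

test_that("Baydur ratio validates balloon position with exclusive 0.8 bound", {
  fs <- 50
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  occ <- data.frame(start = 0, end = 5)
  paw <- waveform(10 + sin(2 * pi * t), fs = fs, channel = "PAW")
  pes_ok <- waveform(5 + 1.0 * sin(2 * pi * t), fs = fs, channel = "PES")
  pes_low <- waveform(5 + 0.79 * sin(2 * pi * t), fs = fs,
                      channel = "PES")
  b1 <- baydur_check(paw, pes_ok, occ)
  expect_equal(b1$ratio, 1, tolerance = 1e-6)
  expect_true(b1$valid)
  b2 <- baydur_check(paw, pes_low, occ)
  expect_equal(b2$ratio, 0.79, tolerance = 1e-6)
  expect_false(b2$valid)

  flat <- waveform(rep(10, fs * 5), fs = fs, channel = "PAW")
  expect_error(baydur_check(flat, pes_ok, occ), "undefined")

  # simulator reproduces the configured ratio during holds
  cfg <- quiet_config(seed = 14, pes_to_paw_ratio = 1.0)
  prot <- protocol_design("A1", step_minutes = 1)
  vent <- simulate_ventilator(cfg, prot)
  ee <- vent$holds[vent$holds$kind == "end_expiratory", ][1, ]
  b <- baydur_check(vent$paw, vent$pes, ee)
  expect_equal(b$ratio, 1, tolerance = 0.02)
})

test_that("derived mechanics reproduce the standard formulas", {
  # occlusion pressures consistent with Ecw 17, El 65 at VT 0.2 L
  m <- derive_mechanics(pawei = 21, pawee = 21 - 0.2 * 82,
                        pesei = 8, pesee = 8 - 0.2 * 17,
                        ppeak_paw = 31, ppeak_pes = 11,
                        vt = 0.2, rr = 35)
  expect_equal(m$Ers, 82)
  expect_equal(m$Ecw, 17)
  expect_equal(m$El, 65)
  expect_equal(m$Ers, m$Ecw + m$El)
  expect_equal(m$TPPei, 13)
  expect_equal(m$TPPelast, 21 * 65 / 82)
  expect_equal(m$Ppeakl, 20)
  expect_true(m$valid)

  # degenerate chest wall: Pesei = Pesee
  m0 <- derive_mechanics(21, 5, 8, 8, 31, 11, vt = 0.2, rr = 35)
  expect_equal(m0$Ecw, 0)
  expect_equal(m0$El, m0$Ers)

  # inverted pressures flag the record instead of erroring
  bad <- derive_mechanics(5, 21, 8, 5, 31, 11, vt = 0.2, rr = 35)
  expect_false(bad$valid)
  expect_error(derive_mechanics(21, 5, 8, 5, 31, 11, vt = 0, rr = 35),
               "positive")
})

test_that("mechanical power follows the simplified volume-control formula", {
  expect_equal(mechanical_power(0, 35, 31, 21, 5), 0)
  expect_equal(mechanical_power(0.19, 70, 31, 21, 5),
               2 * mechanical_power(0.19, 35, 31, 21, 5))
  expect_equal(mechanical_power(0.19, 35, 31, 21, 5),
               0.098 * 35 * 0.19 * 23)
  expect_equal(mechanical_power(0.19, 35, 31, 21, 5), 14.99, tolerance = 1e-3)
})

test_that("mechanics invariants hold on simulated records", {
  cfg <- quiet_config(seed = 16, chest_wall_elastance = 21,
                      lung_elastance = 48, tidal_volume = 0.22)
  prot <- protocol_design("A1", step_minutes = 1)
  vent <- simulate_ventilator(cfg, prot)
  mech <- period_mechanics(vent$paw, vent$pes, vent$flow, prot,
                           cfg$tidal_volume, cfg$respiratory_rate)
  expect_true(all(mech$valid))
  expect_equal(mech$Ers, mech$Ecw + mech$El, tolerance = 1e-12)
  expect_true(all(mech$TPPelast <= mech$Pawei + 1e-9))
  expect_true(all(abs(mech$Ecw - 21) / 21 < 0.01))
  expect_true(all(abs(mech$El - 48) / 48 < 0.01))

  # uniform time-shift leaves every derived quantity unchanged
  shift <- 137
  shifted <- lapply(vent[c("paw", "pes", "flow")], function(w) {
    w$start_time <- w$start_time + shift
    w
  })
  prot2 <- prot
  prot2$start <- prot2$start + shift
  mech2 <- period_mechanics(shifted$paw, shifted$pes, shifted$flow,
                            prot2, cfg$tidal_volume,
                            cfg$respiratory_rate)
  num <- vapply(mech, is.numeric, TRUE)
  expect_equal(mech[, num], mech2[, num], tolerance = 1e-9)
})
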