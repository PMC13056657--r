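test_that("ABP generator is deterministic and collapses to baseline with all components off", {
  cfg <- sim_config(seed = 4, slow_wave_amplitude = 0,
                    pulse_amplitude_abp = 0, resp_amplitude_abp = 0,
                    noise_sd = list(abp = 0, icp = 0, paw = 0, pes = 0,
                                    flow = 0))
  w <- simulate_abp(cfg, 60)
  expect_true(all(w$values == cfg$baseline_abp))

  cfg2 <- sim_config(seed = 9)
  a <- simulate_abp(cfg2, 120)
  b <- simulate_abp(cfg2, 120)
  expect_identical(a$values, b$values)
  expect_error(simulate_abp(cfg2, 0), "positive")
})

test_that("ABP spectral power concentrates in the slow-wave band", {
  cfg <- sim_config(seed = 11, pulse_amplitude_abp = 0,
                    resp_amplitude_abp = 0,
                    noise_sd = list(abp = 0.5, icp = 0, paw = 0, pes = 0,
                                    flow = 0))
  w <- simulate_abp(cfg, 3600)
  sp <- stats::spec.pgram(w$values - mean(w$values), plot = FALSE,
                          taper = 0)
  f <- sp$freq * cfg$sampling_rate
  p_slow <- sum(sp$spec[f >= 0.005 & f <= 0.05])
  p_mid <- sum(sp$spec[f >= 0.1 & f <= 0.2])
  expect_gt(p_slow / p_mid, 10)
})

test_that("ICP couples to PEEP with the programmed slope", {
  cfg <- quiet_config(seed = 2, peep_icp_slope = 0.35,
                      vasoreactivity_gain = 0)
  prot <- protocol_design("A1", "prone_first", step_minutes = 2)
  abp <- simulate_abp(cfg, 16 * 120)
  icp <- simulate_icp(abp, cfg, prot)
  t <- wf_time(icp)
  in_period <- function(i) t >= prot$start[i] + 30 &
    t < prot$start[i] + prot$duration[i]
  d <- mean(icp$values[in_period(4)]) - mean(icp$values[in_period(1)])
  expect_equal(d, 0.35 * 15, tolerance = 1e-9)

  # g = 0, beta = 0, noise off: constant at baseline
  cfg0 <- quiet_config(seed = 2, peep_icp_slope = 0,
                       vasoreactivity_gain = 0)
  icp0 <- simulate_icp(simulate_abp(cfg0, 16 * 120), cfg0, prot)
  expect_true(all(abs(icp0$values - cfg0$baseline_icp) < 1e-12))

  short <- simulate_abp(cfg, 60)
  expect_error(simulate_icp(short, cfg, prot), "span")
})

test_that("vasoreactivity gain drives the sign of downstream PRx", {
  run <- function(g) {
    cfg <- sim_config(seed = 21, vasoreactivity_gain = g)
    prot <- protocol_design("A1", step_minutes = 15)
    abp <- simulate_abp(cfg, 7200)
    icp <- simulate_icp(abp, cfg, prot)
    p <- prx(coarse_grain(abp, variable = "ABP"),
             threshold_filter(coarse_grain(icp, variable = "ICP")))
    mean(p$value, na.rm = TRUE)
  }
  expect_gt(run(0.5), 0.3)
  expect_lt(run(-0.5), -0.3)
})

test_that("ventilator waveforms satisfy the constructed mechanics identities", {
  cfg <- quiet_config(seed = 5, chest_wall_elastance = 17,
                      lung_elastance = 65, tidal_volume = 0.2)
  prot <- protocol_design("A1", "prone_first", step_minutes = 1)
  vent <- simulate_ventilator(cfg, prot)
  ei <- vent$holds[vent$holds$kind == "end_inspiratory" &
                     vent$holds$period == 1, ]
  pawei <- plateau_pressure(vent$paw, ei)
  expect_equal(pawei, 5 + 0.2 * 82, tolerance = 1e-3)

  # flow is exactly zero throughout every hold
  tt <- wf_time(vent$flow)
  for (i in seq_len(nrow(vent$holds))) {
    h <- vent$holds[i, ]
    expect_true(all(vent$flow$values[tt >= h$start & tt < h$end] == 0))
  }

  # VT = 0 collapses the airway plateau to PEEP
  cfg0 <- quiet_config(seed = 5, tidal_volume = 1e-9)
  vent0 <- simulate_ventilator(cfg0, prot)
  ei0 <- vent0$holds[vent0$holds$kind == "end_inspiratory" &
                       vent0$holds$period == 1, ]
  expect_equal(plateau_pressure(vent0$paw, ei0), 5, tolerance = 1e-6)
})

test_that("artifact injection is deterministic, bookkept, and off by default", {
  cfg <- sim_config(seed = 3)
  w <- simulate_abp(cfg, 1200)
  none <- inject_artifacts(w, artifact_spec(), seed = 1)
  expect_identical(none$waveform$values, w$values)
  expect_equal(nrow(none$windows), 0L)

  spec <- artifact_spec(spike_rate = 12, dropout_rate = 6)
  a <- inject_artifacts(w, spec, seed = 8)
  b <- inject_artifacts(w, spec, seed = 8)
  expect_identical(a$windows, b$windows)
  expect_identical(a$waveform$values, b$waveform$values)
  expect_gt(nrow(a$windows), 0L)
  # windows sit on the 10-s grid
  expect_true(all(a$windows$start %% 10 == 0))
  # dropouts masked, spikes at the recorded level
  for (i in seq_len(nrow(a$windows))) {
    win <- a$windows[i, ]
    idx <- wf_time(w) >= win$start & wf_time(w) < win$end
    if (win$kind == "dropout") {
      expect_true(all(!a$waveform$valid[idx]))
    } else {
      expect_true(all(a$waveform$values[idx] == win$level))
    }
  }
})

test_that("cohorts allocate sequences in balance and expose ground truth", {
  co <- generate_cohort(12, quiet_config(), seed = 2, step_minutes = 1,
                        channels = "abp")
  expect_equal(sum(co$truth$sequence == "prone_first"), 6)
  expect_equal(sum(co$truth$sequence == "supine_first"), 6)
  expect_true(all(c("g", "beta") %in% names(co$truth)))
  expect_equal(nrow(co$truth), 12)

  co2 <- generate_cohort(2, quiet_config(), seed = 2, step_minutes = 1,
                         channels = "abp")
  expect_setequal(co2$truth$sequence, c("prone_first", "supine_first"))
})

test_that("programmed PEEP slope is recoverable from noise-free period means", {
  cfg <- quiet_config(seed = 6, peep_icp_slope = 0.4)
  co <- generate_cohort(2, cfg, seed = 6, step_minutes = 2)
  s <- cohort_summaries(co, settle_minutes = 0.5)
  fit <- stats::lm(ICP ~ I(peep - 5), data = s)
  expect_lt(abs(unname(coef(fit)[2]) - 0.4), 0.01)
})
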