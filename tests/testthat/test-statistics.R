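test_that("normality routing matches the Shapiro-Wilk decision", {
  # near-nominal pass rate for truly normal samples
  set.seed(50)
  routes <- replicate(100, normality_route(rnorm(50))$route)
  expect_gte(mean(routes == "parametric"), 0.9)

  # a heavy log-normal sample goes to the rank route
  set.seed(51)
  rank_rate <- mean(replicate(50,
    normality_route(exp(rnorm(30, 0, 1.5)))$route == "rank"))
  expect_gte(rank_rate, 0.9)

  # degenerate samples take the conservative rank route
  expect_equal(normality_route(rep(3, 10))$route, "rank")
  expect_equal(normality_route(c(1, 2))$route, "rank")
})

test_that("baseline comparison routes between t and Mann-Whitney", {
  x <- c(1, 2, 3, 4, 5, 6)
  r <- baseline_compare(x, x)
  expect_equal(r$p, 1, tolerance = 1e-9)

  set.seed(52)
  a <- rnorm(6, 0, 1)
  b <- rnorm(6, 10, 1)        # 10 SD separation
  r2 <- baseline_compare(a, b)
  expect_lt(r2$p, 0.01)
  expect_equal(r2$method, "t")

  skewed <- exp(rnorm(30, 0, 2))
  r3 <- baseline_compare(skewed, skewed + 0.01)
  expect_equal(r3$method, "mann-whitney")
})

test_that("two-sample comparison holds its size at n = 6 per group", {
  set.seed(53)
  rate <- mean(replicate(400, baseline_compare(rnorm(6), rnorm(6))$p < 0.05))
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("crossover assumption tests detect injected sequence effects", {
  pow <- mean(sapply(1:30, function(r) {
    s <- simulate_summary_cohort(12, sequence_effect = 3, seed = 600 + r)
    a <- suppressWarnings(crossover_assumptions(s))
    a$p[a$effect == "sequence"] < 0.05
  }))
  expect_gte(pow, 0.8)

  # and stay quiet under the null (coarse check; calibration is studied
  # at scale in the acceptance suite)
  typ1 <- rowMeans(sapply(1:40, function(r) {
    s <- simulate_summary_cohort(12, seed = 700 + r)
    suppressWarnings(crossover_assumptions(s))$p < 0.05
  }), na.rm = TRUE)
  expect_true(all(typ1 <= 0.2))
})

test_that("degenerate responses are reported, not silently analyzed", {
  s <- simulate_summary_cohort(4, beta = 0, sd_animal = 0,
                               sd_position = 0, sd_resid = 0, seed = 2)
  a <- crossover_assumptions(s)
  expect_true(all(grepl("degenerate", a$method)))
  expect_true(all(is.na(a$p)))
})

test_that("PEEP-position ANOVA pools when no interaction and falls back on violations", {
  s <- simulate_summary_cohort(12, beta = 0.35, seed = 60)
  r <- peep_position_anova(s)
  expect_true("peep (pooled)" %in% r$effect)
  expect_lt(r$p[r$effect == "peep (pooled)"], 0.05)
  expect_gt(r$p[r$effect == "peep:position"], 0.05)

  # identical beta in both positions: interaction rarely flagged
  no_int <- mean(sapply(1:50, function(r) {
    s <- simulate_summary_cohort(12, seed = 800 + r)
    peep_position_anova(s)$p[1] >= 0.05
  }))
  expect_gte(no_int, 0.9)

  # strongly position-specific beta: interaction detected
  det <- mean(sapply(1:30, function(r) {
    s <- simulate_summary_cohort(12, beta = 0, position_beta_diff = 0.7,
                                 seed = 900 + r)
    peep_position_anova(s)$p[1] < 0.05
  }))
  expect_gte(det, 0.8)

  # all-zero deltas: no evidence of a PEEP effect
  s0 <- simulate_summary_cohort(6, beta = 0, sd_animal = 0,
                                sd_position = 0, sd_resid = 0, seed = 3)
  r0 <- peep_position_anova(s0)
  expect_true(all(r0$p == 1))

  # heavy-tailed deltas route to Kruskal-Wallis
  s_kw <- simulate_summary_cohort(12, seed = 61)
  s_kw$ICP <- s_kw$ICP + rt(nrow(s_kw), df = 1) * 5
  r_kw <- peep_position_anova(s_kw)
  pooled <- r_kw[r_kw$effect == "peep (pooled)", ]
  if (nrow(pooled) == 1L && !is.na(pooled$shapiro_p) &&
      pooled$shapiro_p < 0.05)
    expect_equal(pooled$method, "kruskal-wallis")
})

test_that("baseline covariate models recover modulation and admit defeat on constants", {
  hits <- sapply(1:30, function(r) {
    s <- simulate_summary_cohort(12, covariate_effect = 0.15,
                                 seed = 1100 + r)
    x <- suppressWarnings(baseline_predictor_model(s, "cov"))
    !is.na(x$estimate) && x$estimate > 0 && x$p < 0.05
  })
  expect_gte(mean(hits), 0.9)

  s <- simulate_summary_cohort(12, seed = 1)
  s$flat <- 5
  r <- baseline_predictor_model(s, "flat")
  expect_match(r$method, "non-identifiable")
  expect_true(is.na(r$p))
})

test_that("mixed-model PEEP slope is exact on noise-free cohorts", {
  cfg <- quiet_config(seed = 70, peep_icp_slope = 0.35)
  co <- generate_cohort(2, cfg, seed = 70, step_minutes = 2)
  s <- cohort_summaries(co, settle_minutes = 0.5)
  est <- estimate_peep_slope(s)
  expect_lt(abs(est$slope - 0.35), 1e-6)
})

test_that("analysis results are invariant to row order", {
  s <- simulate_summary_cohort(12, seed = 77)
  set.seed(78)
  shuf <- s[sample(nrow(s)), ]
  r1 <- peep_position_anova(s)
  r2 <- peep_position_anova(shuf)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  a1 <- suppressWarnings(crossover_assumptions(s))
  a2 <- suppressWarnings(crossover_assumptions(shuf))
  expect_equal(a1$p, a2$p, tolerance = 1e-8)
})
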