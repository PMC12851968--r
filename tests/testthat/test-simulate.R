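test_that("noiseless simulation reproduces the curve exactly", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 1)
  expect_identical(rec$rri, cas_curve(rec$time, reference_cas()))
  expect_false(any(rec$mask))
  # beat clock: cumulative intervals reproduce beat times to 1e-9 min
  expect_equal(rec$time,
               c(0, cumsum(rec$rri[-length(rec$rri)])) / 60000,
               tolerance = 1e-9)
})

test_that("noiseless series minimum matches a dense-grid minimization", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 1)
  grid <- seq(0, 14, by = 1 / 60000 * 60)  # 1-ms steps in time units of min
  expect_equal(min(rec$rri), min(cas_curve(grid, reference_cas())),
               tolerance = 0.1 / 500)
})

test_that("rest-plateau beat count matches constant-rate integration", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 1)
  # over [0, 5] min the curve is flat at alpha to ~1e-5 relative
  n_plateau <- sum(rec$time < 5)
  expect_lte(abs(n_plateau - 5 * 60000 / 884.77), 2)
})

test_that("simulation is reproducible and noise is calibrated", {
  r1 <- simulate_rri(reference_cas(sigma = 30), seed = 7)
  r2 <- simulate_rri(reference_cas(sigma = 30), seed = 7)
  expect_identical(r1, r2)
  resid <- unlist(lapply(1:5, function(s) {
    r <- simulate_rri(reference_cas(sigma = 30), seed = s)
    r$rri - cas_curve(r$time, reference_cas())
  }))
  expect_gte(length(resid), 5000)
  expect_lt(abs(stats::sd(resid) - 30) / 30, 0.03)
})

test_that("redraws keep intervals positive under extreme noise", {
  # a positive mean keeps each redraw's success probability above 1/2, so
  # the bounded retry loop repairs nonpositive draws rather than failing
  p <- cas_parameters(alpha = 400, beta = 50, c = 1, lam = 2, phi = 2,
                      tau = 1, delta = 0.5, sigma = 2000)
  rec <- simulate_rri(p, protocol_timing(rest = 1, exercise = 1,
                                         recovery = 1), seed = 2)
  expect_true(all(rec$rri > 0))
  expect_error(inject_ectopics(rec, 0.6, c(0.4, 0.6)), "rate")
  expect_error(inject_ectopics(rec, 0.1, c(0, 0.6)), "magnitude")
})

test_that("ectopic injection honours rate, magnitude and alternation", {
  rec <- make_flat_recording(1000)
  # rate 0: identity
  out0 <- inject_ectopics(rec, 0, c(0.4, 0.6), seed = 1)
  expect_identical(out0$recording$rri, rec$rri)
  expect_false(any(out0$truth))
  # magnitude arithmetic on an 800-ms beat with range (0.3, 0.6)
  out <- inject_ectopics(rec, 0.3, c(0.3, 0.6), seed = 2)
  corrupted <- out$recording$rri[out$truth]
  expect_true(all((corrupted >= 320 & corrupted <= 560) |
                    (corrupted >= 1040 & corrupted <= 1280)))
  # alternation: signs of corrupted deviations alternate
  signs <- sign(out$recording$rri[out$truth] - 800)
  expect_true(all(signs[-1] != signs[-length(signs)]))
  # beat times untouched
  expect_identical(out$recording$time, rec$time)
})

test_that("corrupted counts follow the binomial law across seeds", {
  rec <- make_flat_recording(1000)
  counts <- vapply(1:500, function(s)
    sum(inject_ectopics(rec, 0.05, c(0.4, 0.6), seed = s)$truth), numeric(1))
  # reproducible
  expect_equal(counts[10],
               sum(inject_ectopics(rec, 0.05, c(0.4, 0.6), seed = 10)$truth))
  # Binomial(1000, 0.05): mean 50, sd 6.89; 500-seed MC error ~0.31 / 0.22
  expect_lt(abs(mean(counts) - 50), 1.5)
  expect_lt(abs(stats::sd(counts) - sqrt(1000 * 0.05 * 0.95)), 1)
})

test_that("cohort immune marginals match the requested moments", {
  coh <- simulate_cohort(2000, seed = 12, simulate_recordings = FALSE)
  marg <- cohort_marginals()$continuous
  for (v in c("cd21n_cd11cn", "b_total", "lymphocytes")) {
    m <- marg[marg$variable == v, ]
    expect_lt(abs(mean(coh$immune[[v]]) - m$mean) / m$mean, 0.05)
    expect_lt(abs(stats::sd(coh$immune[[v]]) - m$sd) / m$sd, 0.05)
    expect_true(all(coh$immune[[v]] > 0))
  }
  # the small skewed subsets have noisier SD estimators at this n: allow
  # a band consistent with their Monte-Carlo error
  for (v in c("cd21p_cd11cp", "cd21n_cd11cp", "cd21p_cd11cn")) {
    m <- marg[marg$variable == v, ]
    expect_lt(abs(mean(coh$immune[[v]]) - m$mean) / m$mean, 0.06)
    expect_lt(abs(stats::sd(coh$immune[[v]]) - m$sd) / m$sd, 0.12)
  }
  expect_lt(abs(mean(coh$immune$sex) - 25 / 81), 0.03)
})

test_that("null effect matrix produces uncorrelated parameters", {
  coh <- simulate_cohort(500, seed = 5, simulate_recordings = FALSE)
  for (v in predictor_names(FALSE)) {
    r <- stats::cor(coh$immune[[v]], coh$cas_true$alpha)
    expect_lt(abs(r), 0.1)
  }
})

test_that("specified effects are exact standardized effect sizes", {
  # realized total SD equals the dispersion scale, so a coefficient of
  # 0.48 on a standardized predictor recovers as ~0.48 in a linear fit
  cc <- vapply(1:5, function(s) {
    coh <- simulate_cohort(2000, effects = list(alpha = c(cd21p_cd11cp = 0.48)),
                           seed = 200 + s, simulate_recordings = FALSE)
    unname(stats::coef(stats::lm(scale(coh$cas_true$alpha) ~
                                   scale(coh$immune$cd21p_cd11cp)))[2])
  }, numeric(1))
  expect_lt(abs(mean(cc) - 0.48), 0.03)
  disp <- reference_cas_dispersion()
  coh <- simulate_cohort(2000, seed = 3, simulate_recordings = FALSE)
  expect_lt(abs(stats::sd(coh$cas_true$alpha) / disp[["alpha"]] - 1), 0.08)
})

test_that("cohorts are reproducible and dimensionally consistent", {
  c1 <- simulate_cohort(10, seed = 77)
  c2 <- simulate_cohort(10, seed = 77)
  expect_identical(c1$cas_true, c2$cas_true)
  expect_identical(c1$immune, c2$immune)
  expect_identical(c1$recordings[[10]], c2$recordings[[10]])
  expect_identical(c1$immune$subject_id, c1$cas_true$subject_id)
  expect_length(c1$recordings, 10)
  # every subject's parameters satisfy the invariants
  expect_true(all(c1$cas_true$alpha - c1$cas_true$beta > 0))
  expect_true(all(c1$cas_true$lam > 0 & c1$cas_true$phi > 0))
})

test_that("overloaded effects fail with a clear diagnostic", {
  expect_error(
    simulate_cohort(20, effects = list(alpha = c(cd21p_cd11cp = 1.2)),
                    seed = 1, simulate_recordings = FALSE),
    "variance")
  expect_error(effect_matrix(list(gamma = c(age = 1))), "unknown CAS")
})
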