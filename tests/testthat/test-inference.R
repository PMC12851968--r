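test_that("standardization is exact and invertible", {
  coh <- simulate_cohort(50, seed = 8, simulate_recordings = FALSE)
  out <- standardize_columns(coh$immune, predictor_names(FALSE))
  for (v in predictor_names(FALSE)) {
    expect_lt(abs(mean(out$data[[v]])), 1e-8)
    expect_lt(abs(stats::sd(out$data[[v]]) - 1), 1e-8)
    back <- unstandardize(out$data[[v]], v, out)
    expect_equal(back, coh$immune[[v]], tolerance = 1e-10)
  }
  # a subject sitting exactly at the cohort mean standardizes to zero
  df <- data.frame(b_total = c(9752.43, 9752.43 - 5513.14, 9752.43 + 5513.14))
  s <- standardize_columns(df, "b_total")
  expect_equal(s$data$b_total[1], 0)
  expect_equal(s$center[["b_total"]], 9752.43)
  expect_error(standardize_columns(data.frame(a = rep(1, 5)), "a"), "zero SD")
})

test_that("sampler posterior matches the conjugate closed form", {
  set.seed(42)
  N <- 60; P <- 4
  X <- cbind(intercept = 1, matrix(stats::rnorm(N * (P - 1)), N))
  sig <- 0.8
  y <- as.numeric(X %*% c(0.2, 0.5, -0.3, 0)) + stats::rnorm(N, 0, sig)
  spec <- regression_spec(seed = 7)
  out <- cardiosig:::run_jags_lm(y, X, spec, sigma_known = sig)
  prec <- crossprod(X) / sig^2 + diag(P) / spec$prior_sd^2
  post_mean <- solve(prec, crossprod(X, y) / sig^2)
  ess <- as.numeric(coda::effectiveSize(coda::as.mcmc(out$draws)))
  mc_se <- apply(out$draws, 2, stats::sd) / sqrt(ess)
  expect_true(all(abs(colMeans(out$draws) - post_mean) < 3 * mc_se))
  # exact post-warmup draw count: chains x sampling
  expect_identical(nrow(out$draws), 10000L)
})

test_that("pure-noise responses are dominated by the prior", {
  set.seed(11)
  N <- 20
  X <- cbind(intercept = 1, x1 = stats::rnorm(N))
  y <- stats::rnorm(N)
  out <- cardiosig:::run_jags_lm(y, X, regression_spec(seed = 3))
  sds <- apply(out$draws[, 1:2], 2, stats::sd)
  expect_true(all(sds <= 3))
  expect_true(all(abs(apply(out$draws[, 1:2], 2, stats::median)) < 1))
})

test_that("SEXIT summaries match analytic values for standard-normal draws", {
  set.seed(1)
  M <- matrix(stats::rnorm(1e6), ncol = 1, dimnames = list(NULL, "z"))
  s <- sexit_summary(M, rope_halfwidth = 0.1)
  expect_lt(abs(s$pd - 0.5), 0.002)
  expect_lt(abs(s$ps - 2 * (1 - stats::pnorm(0.1))), 0.002)
  expect_lt(abs(s$median), 0.005)
})

test_that("SEXIT handles one-sided and degenerate draws", {
  pos <- matrix(stats::rexp(2000) + 0.01, ncol = 1,
                dimnames = list(NULL, "a"))
  s <- sexit_summary(pos)
  expect_identical(s$pd, 1)
  zero <- matrix(rep(0, 2000), ncol = 1, dimnames = list(NULL, "b"))
  s0 <- sexit_summary(zero)
  expect_identical(s0$ps, 0)
  expect_identical(c(s0$hdi_low, s0$hdi_high), c(0, 0))
  expect_equal(s0$pd, 0.5)
  expect_error(sexit_summary(matrix(stats::rnorm(500), ncol = 1)), "1,000")
})

test_that("pd and ps are invariant under sign reflection", {
  set.seed(6)
  x <- stats::rnorm(5000, 0.3, 1)
  M1 <- matrix(x, ncol = 1, dimnames = list(NULL, "v"))
  M2 <- matrix(-x, ncol = 1, dimnames = list(NULL, "v"))
  s1 <- sexit_summary(M1); s2 <- sexit_summary(M2)
  expect_equal(s1$pd, s2$pd, tolerance = 1e-12)
  expect_identical(s1$ps, s2$ps)
})

test_that("the HDI is the shortest interval and lies inside the draws", {
  set.seed(2)
  for (x in list(stats::rnorm(5000), stats::rexp(5000),
                 stats::rlnorm(5000))) {
    h <- hdi(x, 0.95)
    expect_gte(h[1], min(x)); expect_lte(h[2], max(x))
    eq <- stats::quantile(x, c(0.025, 0.975))
    expect_lte(h[2] - h[1], unname(eq[2] - eq[1]) + 1e-12)
    inside <- mean(x >= h[1] & x <= h[2])
    expect_gte(inside, 0.95 - 1e-9)
  }
})

test_that("regression recovers a known standardized effect from cohort truth", {
  coh <- simulate_cohort(500, effects = list(alpha = c(cd21p_cd11cp = 0.5)),
                         seed = 44, simulate_recordings = FALSE)
  dr <- fit_cas_regression(coh$cas_true, coh$immune,
                           regression_spec(seed = 2))
  sx <- sexit_summary(dr)
  med <- sx$median[sx$coefficient == "alpha:cd21p_cd11cp"]
  expect_lt(abs(med - 0.5), 0.1)
})

test_that("posterior medians concentrate as the cohort grows", {
  err <- vapply(c(100, 500), function(n) {
    e <- vapply(1:3, function(s) {
      coh <- simulate_cohort(n, effects = list(beta = c(cd21n_cd11cn = -0.4)),
                             seed = 300 + s, simulate_recordings = FALSE)
      dr <- fit_cas_regression(coh$cas_true, coh$immune,
                               regression_spec(include_confounders = FALSE,
                                               chains = 2, warmup = 500,
                                               sampling = 500, seed = s))
      sx <- sexit_summary(dr)
      abs(sx$median[sx$coefficient == "beta:cd21n_cd11cn"] + 0.4)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.08)
})

test_that("null effects are calibrated: pd rarely exceeds 0.975", {
  n_hi <- 0
  for (r in 1:200) {
    coh <- simulate_cohort(81, seed = 9000 + r, simulate_recordings = FALSE)
    dr <- fit_cas_regression(coh$cas_true, coh$immune,
                             regression_spec(include_confounders = FALSE,
                                             chains = 2, warmup = 500,
                                             sampling = 500, seed = r))
    sx <- sexit_summary(dr)
    pd <- sx$pd[sx$coefficient == "alpha:cd21p_cd11cp"]
    n_hi <- n_hi + (pd > 0.975)
  }
  expect_lte(n_hi / 200, 0.10)
})

test_that("misaligned or incomplete inputs fail loudly", {
  coh <- simulate_cohort(30, seed = 15, simulate_recordings = FALSE)
  expect_error(fit_cas_regression(coh$cas_true[, -2], coh$immune,
                                  regression_spec(seed = 1)),
               "7 CAS columns")
  imm <- coh$immune; imm$age <- NULL
  expect_error(fit_cas_regression(coh$cas_true, imm,
                                  regression_spec(seed = 1)), "age")
  expect_error(regression_spec(chains = 1), "chains")
  expect_error(regression_spec(warmup = 100), "warmup")
})
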