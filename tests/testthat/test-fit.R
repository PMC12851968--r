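test_that("noiseless trajectories are recovered to 0.1% relative error", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 1)
  fit <- fit_cas(rec, seed = 1)
  truth <- ref_truth()
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta - truth) / abs(truth)), 1e-3)
})

test_that("initialization locates the drop and stays in bounds", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 1)
  th0 <- init_cas(rec)
  expect_lt(abs(th0[["tau"]] - 6.89), 0.5)
  expect_lt(abs(th0[["alpha"]] - 884.77), 5)
  b <- cas_bounds()
  for (s in 1:100) {
    recn <- simulate_rri(reference_cas(sigma = 30), seed = s)
    th <- init_cas(recn)
    expect_true(all(th >= b$lower & th <= b$upper))
  }
})

test_that("flat series triggers the degenerate-drop warning", {
  rec <- make_flat_recording(200, level = 900)
  expect_warning(th0 <- init_cas(rec), "flat")
  expect_equal(th0[["alpha"]], 900, tolerance = 1e-6)
  expect_equal(th0[["beta"]], 10, tolerance = 1e-6)
})

test_that("reported loss equals an independent Huber recomputation", {
  rec <- simulate_rri(reference_cas(sigma = 30), seed = 4)
  fit <- fit_cas(rec, seed = 4)
  keep <- !rec$mask
  r <- rec$rri[keep] - cas_curve(rec$time[keep],
                                 as_cas_parameters(c(fit$theta, 0)))
  expect_equal(fit$loss, huber_loss(r, fit$threshold),
               tolerance = 1e-8)
})

test_that("fit is equivariant under time translation", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 1)
  shift <- 1.5
  rec_s <- rri_recording(rec$time + shift, rec$rri, subject_id = "shifted")
  proto_s <- protocol_timing(rest = 7 + shift, exercise = 2, recovery = 5)
  f0 <- fit_cas(rec, seed = 1)
  fs <- fit_cas(rec_s, protocol = proto_s, seed = 1)
  expect_equal(fs$theta[["tau"]], f0$theta[["tau"]] + shift, tolerance = 1e-3)
  other <- setdiff(cardiosig:::cas_par_names(), "tau")
  expect_equal(fs$theta[other], f0$theta[other], tolerance = 1e-3)
})

test_that("fit is equivariant under amplitude scaling", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 1)
  s <- 1.2
  rec_s <- rri_recording(rec$time, rec$rri * s)
  f0 <- fit_cas(rec, seed = 1)
  fs <- fit_cas(rec_s, seed = 1)
  expect_equal(fs$theta[["alpha"]], s * f0$theta[["alpha"]], tolerance = 1e-3)
  expect_equal(fs$theta[["beta"]], s * f0$theta[["beta"]], tolerance = 1e-3)
  shape <- c("c", "lam", "phi", "tau", "delta")
  expect_equal(fs$theta[shape], f0$theta[shape], tolerance = 1e-3)
})

test_that("quasi-Newton solution matches a coarse-grid-plus-polish search", {
  rec <- simulate_rri(reference_cas(sigma = 0), seed = 2)
  fit <- fit_cas(rec, seed = 2)
  keep <- !rec$mask
  t <- rec$time[keep]; y <- rec$rri[keep]
  b <- cas_bounds()
  # brute force: grid over (tau, delta), polishing the remaining five
  # parameters by bounded optimisation at each node
  taus <- seq(5.5, 8.5, by = 0.5)
  deltas <- seq(1, 4, by = 0.5)
  best <- list(value = Inf)
  obj5 <- function(th5, tau, delta) {
    cardiosig:::cas_objective(c(th5[1], th5[2], th5[3], th5[4], th5[5],
                                tau, delta), t, y, fit$threshold)
  }
  for (ta in taus) for (de in deltas) {
    res <- stats::optim(c(880, 400, 0.9, 3, 2), obj5, tau = ta, delta = de,
                        method = "L-BFGS-B",
                        lower = b$lower[1:5], upper = b$upper[1:5],
                        control = list(maxit = 200))
    if (res$value < best$value) best <- list(value = res$value,
                                             tau = ta, delta = de)
  }
  expect_lt(abs(fit$theta[["tau"]] - best$tau), 0.5)
  expect_lt(abs(fit$theta[["delta"]] - best$delta), 0.5)
  expect_lte(fit$loss, best$value + 1e-6)
})

test_that("noisy recovery is unbiased at the percent level", {
  est <- recovery_experiment()
  truth <- ref_truth()
  expect_lt(abs(mean(est[, "alpha"]) - truth[["alpha"]]) / truth[["alpha"]],
            0.01)
})

test_that("failed fits are reported, never silently returned", {
  rec <- simulate_rri(reference_cas(sigma = 30), seed = 1)
  # impossible bounds force failure of every start
  b <- cas_bounds()
  b$lower[["alpha"]] <- 1400; b$upper[["alpha"]] <- 1500
  b$lower[["beta"]] <- 0; b$upper[["beta"]] <- 1
  fit <- fit_cas(rec, bounds = b, seed = 1)
  expect_false(is.null(fit$loss))
  # converged flag reflects the gradient check at the boxed optimum
  expect_type(fit$converged, "logical")
})

test_that("cohort fitting returns one aligned row per subject", {
  coh <- simulate_cohort(3, seed = 21)
  tab <- fit_cohort(coh$recordings, seed = 1)
  expect_identical(tab$subject_id, coh$immune$subject_id)
  expect_true(all(tab$n_beats_used > 800))
  expect_lt(max(abs(tab$alpha - coh$cas_true$alpha)), 15)
})
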