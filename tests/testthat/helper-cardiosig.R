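# shared fixtures and cached expensive computations

ref_truth <- function() unlist(reference_cas())[cardiosig:::cas_par_names()]

# constant-interval recording with optional Gaussian noise
make_flat_recording <- function(n, level = 800, noise = 0, seed = 1) {
  set.seed(seed)
  rri <- level + stats::rnorm(n, 0, noise)
  time <- c(0, cumsum(rri[-n])) / 60000
  rri_recording(time, rri)
}

# session-level cache so acceptance blocks can share heavy runs
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the 20-seed theta-recovery experiment at the reference parameter vector
recovery_experiment <- function() {
  cached("recovery", {
    truth <- ref_truth()
    est <- matrix(NA_real_, 20, 7, dimnames = list(NULL, names(truth)))
    for (s in 1:20) {
      rec <- simulate_rri(reference_cas(sigma = 30), protocol_timing(),
                          seed = s)
      pp <- preprocess_rri(rec)
      est[s, ] <- fit_cas(pp$recording, seed = s)$theta
    }
    est
  })
}

# default-specification regression on a small synthetic cohort
default_regression <- function() {
  cached("default_reg", {
    coh <- simulate_cohort(30, seed = 30, simulate_recordings = FALSE)
    fit_cas_regression(coh$cas_true, coh$immune,
                       regression_spec(seed = 30))
  })
}

# full two-step pipeline at n = 500 with one true effect of +0.48 on alpha
effect_recovery_run <- function() {
  cached("effect_recovery", {
    coh <- simulate_cohort(500,
                           effects = list(alpha = c(cd21p_cd11cp = 0.48)),
                           seed = 101)
    cas <- fit_cohort(coh$recordings, seed = 11)
    draws <- fit_cas_regression(cas, coh$immune, regression_spec(seed = 5))
    list(cohort = coh, cas = cas, draws = draws,
         sexit = sexit_summary(draws))
  })
}
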