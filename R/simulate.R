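#' Reference cohort-level CAS parameter vector
#'
#' Cohort-mean cardiac autonomic signature of an 81-subject older-adult
#' step-test cohort, used as the default ground truth of the synthetic
#' generator: baseline RRi 884.77 ms, exercise drop 403.99 ms, recovery
#' proportion 0.89, drop rate 3.01 min^-1, recovery rate 2.18 min^-1,
#' drop onset 6.89 min, recovery lag 2.50 min.
#'
#' @param sigma Observation noise SD (ms) attached to the vector.
#' @return A `cas_parameters` object.
#' @export
reference_cas <- function(sigma = 0) {
  cas_parameters(alpha = 884.77, beta = 403.99, c = 0.89,
                 lam = 3.01, phi = 2.18, tau = 6.89, delta = 2.50,
                 sigma = sigma)
}

#' Between-subject dispersion scale for CAS parameters
#'
#' Per-parameter scale (SD) used by [simulate_cohort()] to convert
#' standardized effects into natural units. Defaults are derived from the
#' 95% interval halfwidths reported alongside the reference cohort means,
#' read as a dispersion band (halfwidth / 1.96). See the package vignette
#' for the rationale for this calibration.
#'
#' @return Named numeric vector over the seven CAS parameters.
#' @export
reference_cas_dispersion <- function() {
  half <- c(alpha = (925.77 - 840.27) / 2,
            beta  = (451.58 - 355.60) / 2,
            c     = (0.94 - 0.84) / 2,
            lam   = (3.44 - 2.57) / 2,
            phi   = (2.71 - 1.63) / 2,
            tau   = (7.11 - 6.66) / 2,
            delta = (2.72 - 2.28) / 2)
  half / stats::qnorm(0.975)
}

#' Cohort marginals of immune predictors and covariates
#'
#' Mean and SD of the six immune-cell predictors (counts per microlitre)
#' and the continuous covariates, plus the male fraction, matching the
#' reference cohort. Immune counts are simulated as moment-matched
#' log-normals; covariates as Gaussians.
#'
#' @return A list with a `continuous` data frame (`variable`, `mean`,
#'   `sd`, `lognormal`) and `p_male`.
#' @export
cohort_marginals <- function() {
  cont <- data.frame(
    variable = c("lymphocytes", "b_total", "cd21p_cd11cn", "cd21p_cd11cp",
                 "cd21n_cd11cp", "cd21n_cd11cn", "age", "fat_pct", "muscle_kg"),
    mean = c(70686.04, 9752.43, 8351, 198, 328, 727, 70.60, 35.35, 45.19),
    sd   = c(27256.28, 5513.14, 4994, 139, 218, 488, 5.80, 8.77, 8.53),
    lognormal = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  list(continuous = cont, p_male = 25 / 81)
}

#' Predictor column names used by the cohort generator and regression
#' @param include_confounders Include the four covariate columns.
#' @return Character vector of column names.
#' @export
predictor_names <- function(include_confounders = TRUE) {
  imm <- c("lymphocytes", "b_total", "cd21p_cd11cn", "cd21p_cd11cp",
           "cd21n_cd11cp", "cd21n_cd11cn")
  if (include_confounders) c(imm, "age", "sex", "fat_pct", "muscle_kg") else imm
}

#' Simulate a single RRi trajectory
#'
#' Generates beats sequentially from time 0: at each beat time `t` the
#' interval is drawn as `cas_curve(t, params) + Normal(0, sigma)` ms, the
#' clock advances by `interval / 60000` min, and generation stops once
#' the clock exceeds the protocol span. Beat times therefore reproduce
#' the cumulative sum of the simulated intervals exactly.
#'
#' @param params `cas_parameters` (its `sigma` field sets the noise SD).
#' @param protocol `protocol_timing`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param subject_id Label for the recording.
#' @return An `rri_recording` with an all-`FALSE` artifact mask.
#' @examples
#' rec <- simulate_rri(reference_cas(sigma = 30), protocol_timing(), seed = 1)
#' @export
simulate_rri <- function(params, protocol = protocol_timing(), seed = NULL,
                         subject_id = "S1") {
  p <- as_cas_parameters(params)
  if (!inherits(protocol, "protocol_timing"))
    stop("simulate_rri: protocol must be a protocol_timing object")
  if (protocol$span <= p$tau + p$delta)
    warning("simulate_rri: protocol span does not cover the recovery onset")
  if (!is.null(seed)) set.seed(seed)
  span <- protocol$span
  # generous preallocation: shortest plausible interval ~ 200 ms
  n_max <- ceiling(span * 60000 / 200) + 10L
  times <- numeric(n_max); ints <- numeric(n_max)
  t <- 0; k <- 0L
  max_retry <- 50L
  while (t <= span) {
    mu <- p$alpha - p$beta * stats::plogis(p$lam * (t - p$tau)) +
      p$c * p$beta * stats::plogis(p$phi * (t - p$tau - p$delta))
    rri <- mu + stats::rnorm(1L, 0, p$sigma)
    if (rri <= 0) {
      tries <- 0L
      while (rri <= 0 && tries < max_retry) {
        rri <- mu + stats::rnorm(1L, 0, p$sigma)
        tries <- tries + 1L
      }
      if (rri <= 0)
        stop("simulate_rri: observation noise too large relative to the ",
             "trajectory level (nonpositive intervals persist after ",
             max_retry, " redraws)")
    }
    k <- k + 1L
    times[k] <- t; ints[k] <- rri
    t <- t + rri / 60000
  }
  rri_recording(times[seq_len(k)], ints[seq_len(k)], subject_id = subject_id)
}

#' Inject ectopic-beat artifacts into a recording
#'
#' Each beat is independently corrupted with probability `rate` by
#' multiplying its interval by `1 - u` or `1 + u`, with `u` drawn
#' uniformly from `magnitude`. The sign alternates short/long over the
#' corrupted beats. Beat times are left untouched: the corruption models
#' a detection artifact, not true physiology.
#'
#' @param rec An `rri_recording`.
#' @param rate Per-beat corruption probability in `[0, 0.5)`.
#' @param magnitude Length-2 vector of magnitude fractions in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return A list with `recording` (corrupted copy) and `truth` (logical
#'   vector marking corrupted beats).
#' @export
inject_ectopics <- function(rec, rate, magnitude = c(0.4, 0.6), seed = NULL) {
  stopifnot(inherits(rec, "rri_recording"))
  if (rate < 0 || rate >= 0.5) stop("inject_ectopics: rate must be in [0, 0.5)")
  if (length(magnitude) != 2L || any(magnitude <= 0) || any(magnitude > 1))
    stop("inject_ectopics: magnitude fractions must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(rec$rri)
  truth <- rep(FALSE, n)
  if (rate > 0) {
    hit <- stats::runif(n) < rate
    idx <- which(hit)
    if (length(idx)) {
      u <- stats::runif(length(idx), min(magnitude), max(magnitude))
      sign <- rep_len(c(-1, 1), length(idx))  # alternate short / long
      rec$rri[idx] <- rec$rri[idx] * (1 + sign * u)
      truth[idx] <- TRUE
    }
  }
  list(recording = rec, truth = truth)
}

# Moment-matched log-normal parameters for a positive variable with the
# requested mean m and SD s.
lognormal_match <- function(m, s) {
  v <- log(1 + (s / m)^2)
  list(meanlog = log(m) - v / 2, sdlog = sqrt(v))
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject immune counts (moment-matched log-normals) and
#' covariates from the cohort marginals, maps standardized predictors to
#' CAS parameters through a linear effect matrix, and simulates one RRi
#' recording per subject. The per-parameter between-subject SD is fixed
#' at `dispersion`; the linear predictor accounts for the share of that
#' variance implied by the effect matrix and the residual SD absorbs the
#' remainder, so the specified effects are exact standardized effect
#' sizes of the generated cohort.
#'
#' @param n_subjects Number of subjects.
#' @param effects 7 x 10 matrix of standardized effects (rows = CAS
#'   parameters `alpha..delta`, columns = `predictor_names()`), or `NULL`
#'   for an all-zero matrix. A partially named matrix/list is accepted via
#'   [effect_matrix()].
#' @param marginals Output of [cohort_marginals()] (or same structure).
#' @param protocol `protocol_timing` for the recordings.
#' @param sigma Beat-level observation noise SD (ms) for every subject.
#' @param cas_mean `cas_parameters` giving the cohort-mean signature.
#' @param dispersion Named per-parameter between-subject SD; defaults to
#'   [reference_cas_dispersion()].
#' @param seed Integer seed (single RNG stream drives the whole cohort).
#' @param max_retries Residual redraws allowed per subject before failing
#'   when a draw violates parameter invariants (e.g. `alpha - beta <= 0`).
#' @param simulate_recordings Set `FALSE` to return the cohort truth
#'   without generating the beat-level recordings (fast; for studies of
#'   the second stage alone).
#' @return An object of class `cas_cohort`: list with `immune`
#'   (predictor/covariate data frame), `cas_true` (per-subject parameter
#'   data frame), `recordings` (list of `rri_recording`), `effects`,
#'   `dispersion`, `cas_mean`, `sigma` and `seed`.
#' @export
simulate_cohort <- function(n_subjects,
                            effects = NULL,
                            marginals = cohort_marginals(),
                            protocol = protocol_timing(),
                            sigma = 30,
                            cas_mean = reference_cas(),
                            dispersion = reference_cas_dispersion(),
                            seed = 1,
                            max_retries = 100L,
                            simulate_recordings = TRUE) {
  stopifnot(n_subjects >= 1)
  eff <- effect_matrix(effects)
  cont <- marginals$continuous
  if (any(cont$sd <= 0) || any(cont$mean <= 0))
    stop("simulate_cohort: marginal means/SDs must be positive")
  set.seed(seed)

  draw_col <- function(v) {
    row <- cont[cont$variable == v, ]
    if (row$lognormal) {
      lp <- lognormal_match(row$mean, row$sd)
      stats::rlnorm(n_subjects, lp$meanlog, lp$sdlog)
    } else {
      stats::rnorm(n_subjects, row$mean, row$sd)
    }
  }
  imm <- data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)))
  for (v in c("lymphocytes", "b_total", "cd21p_cd11cn", "cd21p_cd11cp",
              "cd21n_cd11cp", "cd21n_cd11cn")) imm[[v]] <- draw_col(v)
  imm$age <- draw_col("age")
  imm$sex <- stats::rbinom(n_subjects, 1L, marginals$p_male)
  imm$fat_pct <- pmax(draw_col("fat_pct"), 5)
  imm$muscle_kg <- pmax(draw_col("muscle_kg"), 20)

  # standardized design used for the generative linear map (sex kept 0/1)
  X <- as.matrix(imm[, predictor_names()])
  cont_cols <- setdiff(predictor_names(), "sex")
  X[, cont_cols] <- scale(X[, cont_cols])

  pn <- cas_par_names()
  mu <- unlist(cas_mean)[pn]
  disp <- dispersion[pn]
  if (any(is.na(disp)) || any(disp <= 0))
    stop("simulate_cohort: dispersion must be positive for all 7 parameters")

  linpred <- X %*% t(eff)            # n x 7, standardized scale
  resid_sd <- vapply(seq_along(pn), function(k) {
    v_exp <- if (n_subjects > 1) stats::var(linpred[, k]) else 0
    if (v_exp >= 1)
      stop("simulate_cohort: effects on '", pn[k], "' explain >= 100% of ",
           "the between-subject variance; reduce the effect sizes")
    sqrt(1 - v_exp)
  }, numeric(1))

  theta <- matrix(NA_real_, n_subjects, 7L, dimnames = list(NULL, pn))
  for (i in seq_len(n_subjects)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- mu + disp * (linpred[i, ] + resid_sd * stats::rnorm(7L))
      valid <- cand["beta"] >= 0 && cand["lam"] > 0 && cand["phi"] > 0 &&
        cand["delta"] >= 0 && (cand["alpha"] - cand["beta"]) > 0
      if (valid) { theta[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      stop("simulate_cohort: could not draw invariant-satisfying CAS ",
           "parameters for subject ", imm$subject_id[i],
           " (effects/dispersion produce invalid trajectories)")
  }

  recordings <- NULL
  if (simulate_recordings) {
    recordings <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      p <- do.call(cas_parameters, c(as.list(theta[i, ]), list(sigma = sigma)))
      recordings[[i]] <- simulate_rri(p, protocol, seed = NULL,
                                      subject_id = imm$subject_id[i])
    }
  }

  cas_true <- data.frame(subject_id = imm$subject_id, theta,
                         sigma = sigma, stringsAsFactors = FALSE)
  structure(list(immune = imm, cas_true = cas_true, recordings = recordings,
                 effects = eff, dispersion = disp, cas_mean = mu,
                 sigma = sigma, seed = seed, protocol = protocol),
            class = "cas_cohort")
}

#' Build a CAS effect matrix
#'
#' Convenience constructor for the 7 x 10 standardized effect matrix used
#' by [simulate_cohort()]. Accepts `NULL` (all zero), a full matrix, or a
#' named list like `list(alpha = c(cd21p_cd11cp = 0.48))`.
#'
#' @param spec `NULL`, a 7 x 10 matrix, or a named list of named vectors.
#' @return A 7 x 10 numeric matrix with rows `alpha..delta` and columns
#'   `predictor_names()`.
#' @export
effect_matrix <- function(spec = NULL) {
  pn <- cas_par_names(); cols <- predictor_names()
  eff <- matrix(0, 7L, length(cols), dimnames = list(pn, cols))
  if (is.null(spec)) return(eff)
  if (is.matrix(spec)) {
    if (!all(dim(spec) == dim(eff)))
      stop("effect_matrix: matrix must be 7 x ", length(cols))
    dimnames(spec) <- dimnames(eff)
    return(spec)
  }
  if (is.list(spec)) {
    for (k in names(spec)) {
      if (!k %in% pn) stop("effect_matrix: unknown CAS parameter '", k, "'")
      v <- spec[[k]]
      if (is.null(names(v)) || !all(names(v) %in% cols))
        stop("effect_matrix: effects for '", k, "' must be named by predictor")
      eff[k, names(v)] <- v
    }
    return(eff)
  }
  stop("effect_matrix: unsupported specification")
}

#' @export
print.cas_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CAS cohort: %d subjects, seed %d, sigma %.1f ms\n",
              nrow(x$immune), x$seed, x$sigma))
  invisible(x)
}
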