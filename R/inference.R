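#' Second-stage regression specification
#'
#' Sampler and prior configuration for the multivariate regression of
#' CAS parameters on immune predictors. Defaults follow the reference
#' analysis: Normal(0, 3) coefficient priors, five chains, 2,000 warm-up
#' and 2,000 sampling iterations per chain (10,000 post-warmup draws per
#' parameter).
#'
#' @param include_confounders Add age, sex, body-fat and muscle-mass
#'   terms (the confounder-adjusted model).
#' @param prior_sd Coefficient prior SD (> 0).
#' @param chains Number of MCMC chains (>= 2).
#' @param warmup Warm-up iterations per chain (>= 500).
#' @param sampling Post-warmup iterations per chain (>= 500).
#' @param seed Integer seed (drives per-chain RNG initialisation).
#' @return A `regression_spec` object.
#' @export
regression_spec <- function(include_confounders = TRUE, prior_sd = 3,
                            chains = 5L, warmup = 2000L, sampling = 2000L,
                            seed = 1L) {
  if (chains < 2) stop("regression_spec: chains must be >= 2")
  if (warmup < 500 || sampling < 500)
    stop("regression_spec: warmup and sampling must be >= 500")
  if (prior_sd <= 0) stop("regression_spec: prior_sd must be > 0")
  structure(list(include_confounders = isTRUE(include_confounders),
                 prior_sd = prior_sd, chains = as.integer(chains),
                 warmup = as.integer(warmup), sampling = as.integer(sampling),
                 seed = as.integer(seed)),
            class = "regression_spec")
}

#' Standardize data-frame columns
#'
#' Centers each requested column to its mean and scales by its SD,
#' retaining the applied means/SDs as metadata for back-transformation.
#'
#' @param df Data frame.
#' @param cols Columns to standardize (must have SD > 0).
#' @return List with `data` (transformed data frame), `center`, `scale`
#'   (named vectors over `cols`).
#' @export
standardize_columns <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("standardize_columns: missing columns: ",
                         paste(miss, collapse = ", "))
  center <- scale_ <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    x <- df[[cl]]
    if (anyNA(x)) stop("standardize_columns: NA in column '", cl, "'")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("standardize_columns: column '", cl, "' has zero SD")
    m <- mean(x)
    df[[cl]] <- (x - m) / s
    center[cl] <- m; scale_[cl] <- s
  }
  list(data = df, center = center, scale = scale_)
}

#' Invert a standardization
#'
#' @param x Standardized values.
#' @param col Column name.
#' @param meta Metadata list returned by [standardize_columns()].
#' @return Values on the original scale.
#' @export
unstandardize <- function(x, col, meta) {
  x * meta$scale[[col]] + meta$center[[col]]
}

jags_lm_model <- "model {
  for (i in 1:N) { y[i] ~ dnorm(mu[i], isig2) }
  mu <- X %*% b
  for (j in 1:P) { b[j] ~ dnorm(0, prior_prec) }
  sigma ~ dt(0, sigma_prec, 3) T(0,)
  isig2 <- 1 / (sigma * sigma)
}"

jags_lm_model_fixed_sigma <- "model {
  for (i in 1:N) { y[i] ~ dnorm(mu[i], isig2) }
  mu <- X %*% b
  for (j in 1:P) { b[j] ~ dnorm(0, prior_prec) }
  isig2 <- 1 / (sigma_known * sigma_known)
}"

# Run the Gaussian linear model for one response by Gibbs sampling
# (JAGS). Returns a draws matrix (chains * sampling) x (P + 1) with
# columns b[1..P], sigma, plus chain / iteration indices.
run_jags_lm <- function(y, X, spec, seed_offset = 0L, sigma_known = NULL) {
  N <- length(y); P <- ncol(X)
  fixed <- !is.null(sigma_known)
  data <- list(y = as.numeric(y), X = X, N = N, P = P,
               prior_prec = 1 / spec$prior_sd^2)
  if (fixed) data$sigma_known <- sigma_known else data$sigma_prec <- 1 / 2.5^2
  model_str <- if (fixed) jags_lm_model_fixed_sigma else jags_lm_model
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (spec$seed * 1000L + seed_offset * 10L + ch) %% 2147483629L)
  })
  n_adapt <- min(1000L, spec$warmup)
  m <- rjags::jags.model(textConnection(model_str), data = data,
                         inits = inits, n.chains = spec$chains,
                         n.adapt = n_adapt, quiet = TRUE)
  if (spec$warmup > n_adapt)
    stats::update(m, n.iter = spec$warmup - n_adapt, progress.bar = "none")
  vars <- if (fixed) "b" else c("b", "sigma")
  samp <- rjags::coda.samples(m, variable.names = vars,
                              n.iter = spec$sampling, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  bad <- !is.finite(draws)
  if (any(bad))
    stop("run_jags_lm: sampler produced non-finite draws")
  chain <- rep(seq_len(spec$chains), each = spec$sampling)
  iteration <- rep(seq_len(spec$sampling), times = spec$chains)
  list(draws = draws, chain = chain, iteration = iteration)
}

#' Multivariate Bayesian regression of CAS parameters on immune predictors
#'
#' Regresses each of the seven (standardized) CAS parameter estimates on
#' the six standardized immune-cell predictors, optionally adding age,
#' sex, body-fat and muscle-mass confounder terms. Each response is a
#' Gaussian linear model with Normal(0, `prior_sd`) coefficient priors
#' and a half-Student-t(3, 0, 2.5) residual-SD prior, sampled by MCMC
#' (Gibbs, via JAGS) with the configured chains and iterations; residuals
#' are modelled independently across responses.
#'
#' Because both predictors and responses are standardized, the
#' coefficients are standardized effect sizes and the conventional ROPE
#' of +/- 0.1 response SDs is the interval (-0.1, 0.1).
#'
#' @param cas_table Per-subject CAS estimates (`subject_id` plus the
#'   seven parameter columns), e.g. from [fit_cohort()].
#' @param immune Per-subject predictor/covariate data frame with the
#'   columns of [predictor_names()] plus `subject_id`.
#' @param spec A `regression_spec`.
#' @return An object of class `cas_draws`: `draws` (matrix, one column
#'   per coefficient named `response:term`), `chain`, `iteration`,
#'   `responses`, `terms`, `spec`, `standardization` (metadata for
#'   predictors and responses) and `warnings`.
#' @export
fit_cas_regression <- function(cas_table, immune, spec = regression_spec()) {
  stopifnot(inherits(spec, "regression_spec"))
  if (!all(c("subject_id", cas_par_names()) %in% names(cas_table)))
    stop("fit_cas_regression: cas_table must contain subject_id and the 7 CAS columns")
  pred_cols <- predictor_names(spec$include_confounders)
  if (!all(c("subject_id", pred_cols) %in% names(immune)))
    stop("fit_cas_regression: immune table missing columns: ",
         paste(setdiff(c("subject_id", pred_cols), names(immune)), collapse = ", "))

  dat <- merge(cas_table[, c("subject_id", cas_par_names())],
               immune[, c("subject_id", pred_cols)], by = "subject_id")
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(pred_cols) + 2L)
    stop("fit_cas_regression: too few complete cases (", nrow(dat), ")")

  cont_pred <- setdiff(pred_cols, "sex")
  sp <- standardize_columns(dat, cont_pred)
  sr <- standardize_columns(sp$data, cas_par_names())
  dat_s <- sr$data

  terms <- c("intercept", pred_cols)
  X <- cbind(intercept = 1, as.matrix(dat_s[, pred_cols]))
  warn <- character(0)
  kap <- kappa(X, exact = TRUE)
  if (kap > 30) {
    warn <- c(warn, sprintf("design condition number %.1f > 30 (collinear predictors)", kap))
    warning("fit_cas_regression: ", warn[length(warn)])
  }

  resp <- cas_par_names()
  all_draws <- NULL; chain <- iteration <- NULL
  for (k in seq_along(resp)) {
    out <- run_jags_lm(dat_s[[resp[k]]], X, spec, seed_offset = k)
    cols <- c(paste0(resp[k], ":", terms), paste0(resp[k], ":sigma"))
    colnames(out$draws) <- cols
    if (is.null(all_draws)) {
      all_draws <- out$draws; chain <- out$chain; iteration <- out$iteration
    } else {
      all_draws <- cbind(all_draws, out$draws)
    }
  }
  structure(list(draws = all_draws, chain = chain, iteration = iteration,
                 responses = resp, terms = terms, spec = spec,
                 n_subjects = nrow(dat_s),
                 standardization = list(predictors = list(center = sp$center,
                                                          scale = sp$scale),
                                        responses = list(center = sr$center,
                                                         scale = sr$scale)),
                 warnings = warn),
            class = "cas_draws")
}

#' @export
print.cas_draws <- function(x, ...) {
  cat(sprintf("CAS posterior draws: %d draws x %d coefficients (%d chains)\n",
              nrow(x$draws), ncol(x$draws), x$spec$chains))
  invisible(x)
}

#' Shortest 95% highest-density interval of a sample
#'
#' Scans contiguous windows of the sorted draws and returns the shortest
#' interval containing the requested probability mass.
#'
#' @param x Numeric draws.
#' @param prob Probability mass (default 0.95).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) stop("hdi: no finite draws")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Probability of direction
#'
#' The larger of the posterior probabilities that the effect is strictly
#' positive or strictly negative. Draws exactly at zero count half to
#' each side, so a point mass at zero yields 0.5.
#'
#' @param x Numeric draws.
#' @return Scalar in `[0.5, 1]`.
#' @export
p_direction <- function(x) {
  pos <- mean(x > 0) + 0.5 * mean(x == 0)
  max(pos, 1 - pos)
}

#' SEXIT posterior summary
#'
#' Sequential-effect-existence-and-significance summary per coefficient:
#' posterior median, 95% highest-density interval, probability of
#' direction (pd), and the posterior mass outside the region of practical
#' equivalence (ps). With standardized responses the default ROPE
#' halfwidth of 0.1 corresponds to +/- 0.1 response SDs.
#'
#' @param draws A `cas_draws` object, or a numeric matrix of draws with
#'   one column per coefficient.
#' @param rope_halfwidth ROPE halfwidth in standardized units.
#' @param include_sigma Include the residual-SD columns (default FALSE).
#' @return Data frame with columns `coefficient`, `median`, `hdi_low`,
#'   `hdi_high`, `pd`, `ps`, `rope_halfwidth`.
#' @export
sexit_summary <- function(draws, rope_halfwidth = 0.1, include_sigma = FALSE) {
  M <- if (inherits(draws, "cas_draws")) draws$draws else as.matrix(draws)
  if (is.null(colnames(M))) colnames(M) <- paste0("par", seq_len(ncol(M)))
  if (!include_sigma) M <- M[, !grepl(":sigma$", colnames(M)), drop = FALSE]
  if (nrow(M) < 1000L)
    stop("sexit_summary: need at least 1,000 draws per coefficient")
  rows <- lapply(colnames(M), function(cn) {
    x <- M[, cn]
    h <- hdi(x, 0.95)
    data.frame(coefficient = cn,
               median = stats::median(x),
               hdi_low = h[1], hdi_high = h[2],
               pd = p_direction(x),
               ps = mean(abs(x) > rope_halfwidth),
               rope_halfwidth = rope_halfwidth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
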