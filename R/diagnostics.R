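# Rank-normalize pooled draws: replace values by normal scores of their
# fractional ranks (offset 3/8, as in modern split-Rhat practice).
rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# Classic split-Rhat on a (iterations x chains) matrix.
split_rhat_raw <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  sm <- cbind(m[seq_len(half), , drop = FALSE],
              m[(n - half + 1):n, , drop = FALSE])
  W <- mean(apply(sm, 2, stats::var))
  B <- half * stats::var(colMeans(sm))
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws
#' after splitting each chain in half, so both poor mixing and chains
#' stuck in different regions inflate the statistic.
#'
#' @param m Matrix of draws, iterations in rows, chains in columns
#'   (>= 2 chains).
#' @return Scalar R-hat.
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("split_rhat: need at least 2 chains")
  z <- matrix(rank_normalize(as.numeric(m)), nrow(m), ncol(m))
  split_rhat_raw(z)
}

#' MCMC convergence diagnostics for a CAS regression
#'
#' Computes rank-normalized split R-hat and the effective sample size
#' for every sampled coefficient and flags parameters violating the
#' conventional thresholds (R-hat >= 1.01 or ESS <= 1,000).
#'
#' @param draws A `cas_draws` object (>= 2 chains).
#' @param rhat_limit Flagging threshold for R-hat.
#' @param ess_limit Flagging threshold for ESS.
#' @return Data frame with `coefficient`, `rhat`, `ess`, `flagged`.
#' @export
mcmc_diagnostics <- function(draws, rhat_limit = 1.01, ess_limit = 1000) {
  stopifnot(inherits(draws, "cas_draws") || is.list(draws))
  M <- draws$draws; chain <- draws$chain
  n_chain <- length(unique(chain))
  if (n_chain < 2L) stop("mcmc_diagnostics: need at least 2 chains")
  rows <- lapply(colnames(M), function(cn) {
    by_chain <- matrix(M[, cn], ncol = n_chain)
    rh <- split_rhat(by_chain)
    ess <- as.numeric(coda::effectiveSize(coda::as.mcmc(M[, cn])))
    data.frame(coefficient = cn, rhat = rh, ess = ess,
               flagged = rh >= rhat_limit || ess <= ess_limit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior predictive check for a CAS regression
#'
#' Draws replicated response vectors from a posterior subsample of the
#' fitted linear model and compares their mean, SD and quartiles with the
#' observed (standardized) responses. Requires the data used in the fit.
#'
#' @param draws A `cas_draws` object.
#' @param cas_table,immune The tables passed to [fit_cas_regression()].
#' @param n_rep Number of replicated datasets per response.
#' @return Data frame with one row per response and summary statistic:
#'   observed value, replicated mean and central 95% band.
#' @export
posterior_predictive_check <- function(draws, cas_table, immune, n_rep = 200L) {
  stopifnot(inherits(draws, "cas_draws"))
  spec <- draws$spec
  pred_cols <- predictor_names(spec$include_confounders)
  dat <- merge(cas_table[, c("subject_id", cas_par_names())],
               immune[, c("subject_id", pred_cols)], by = "subject_id")
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  sp <- standardize_columns(dat, setdiff(pred_cols, "sex"))
  sr <- standardize_columns(sp$data, cas_par_names())
  dat_s <- sr$data
  X <- cbind(intercept = 1, as.matrix(dat_s[, pred_cols]))

  stat_fns <- list(mean = mean, sd = stats::sd,
                   q25 = function(x) stats::quantile(x, 0.25),
                   q75 = function(x) stats::quantile(x, 0.75))
  idx <- round(seq(1, nrow(draws$draws), length.out = n_rep))
  rows <- list()
  for (resp in draws$responses) {
    bcols <- paste0(resp, ":", draws$terms)
    scol <- paste0(resp, ":sigma")
    y_obs <- dat_s[[resp]]
    rep_stats <- matrix(NA_real_, length(idx), length(stat_fns))
    for (j in seq_along(idx)) {
      b <- draws$draws[idx[j], bcols]
      sg <- if (scol %in% colnames(draws$draws)) draws$draws[idx[j], scol] else 1
      yrep <- as.numeric(X %*% b) + stats::rnorm(nrow(X), 0, sg)
      rep_stats[j, ] <- vapply(stat_fns, function(f) f(yrep), numeric(1))
    }
    for (s in seq_along(stat_fns)) {
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, statistic = names(stat_fns)[s],
        observed = stat_fns[[s]](y_obs),
        rep_mean = mean(rep_stats[, s]),
        rep_low = stats::quantile(rep_stats[, s], 0.025),
        rep_high = stats::quantile(rep_stats[, s], 0.975),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
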