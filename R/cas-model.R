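#' Cardiac autonomic signature (CAS) parameter vector
#'
#' Bundles the seven parameters of the coupled-logistic RRi-vs-time
#' trajectory together with the beat-level observation-noise standard
#' deviation. The trajectory drops from a resting plateau `alpha` by
#' `beta` milliseconds during exercise and recovers a proportion `c` of
#' that drop afterwards, so the late-recovery asymptote is
#' `alpha - beta * (1 - c)`.
#'
#' @param alpha Baseline (resting) RRi level in ms.
#' @param beta Exercise-induced RRi drop magnitude in ms (>= 0).
#' @param c Recovery proportion relative to `beta` (dimensionless).
#' @param lam Drop steepness in min^-1 (> 0).
#' @param phi Recovery steepness in min^-1 (> 0).
#' @param tau Drop onset time in min.
#' @param delta Lag from drop onset to recovery onset in min (>= 0).
#' @param sigma Observation noise SD in ms (>= 0).
#'
#' @return An object of class `cas_parameters` (a named list).
#' @examples
#' cas_parameters(alpha = 900, beta = 400, c = 0.9, lam = 3, phi = 2,
#'                tau = 7, delta = 2.5, sigma = 30)
#' @export
cas_parameters <- function(alpha, beta, c, lam, phi, tau, delta, sigma = 0) {
  p <- list(alpha = alpha, beta = beta, c = c, lam = lam, phi = phi,
            tau = tau, delta = delta, sigma = sigma)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("cas_parameters: `", nm, "` must be a finite numeric scalar")
  }
  if (beta < 0) stop("cas_parameters: beta must be >= 0")
  if (lam <= 0) stop("cas_parameters: lam must be > 0")
  if (phi <= 0) stop("cas_parameters: phi must be > 0")
  if (delta < 0) stop("cas_parameters: delta must be >= 0")
  if (sigma < 0) stop("cas_parameters: sigma must be >= 0")
  if (alpha - beta <= 0)
    stop("cas_parameters: alpha - beta must be > 0 (RRi positive at the nadir)")
  structure(p, class = "cas_parameters")
}

#' @export
print.cas_parameters <- function(x, ...) {
  cat("CAS parameters:\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

# Names of the seven trajectory parameters, in canonical order.
cas_par_names <- function() c("alpha", "beta", "c", "lam", "phi", "tau", "delta")

#' Coerce a numeric vector to CAS parameters
#'
#' @param x Named or positionally ordered numeric vector of length 7
#'   (`alpha, beta, c, lam, phi, tau, delta`) or 8 (with `sigma`).
#' @return A `cas_parameters` object.
#' @export
as_cas_parameters <- function(x) {
  if (inherits(x, "cas_parameters")) return(x)
  x <- unlist(x)
  nms <- c(cas_par_names(), "sigma")
  if (!is.null(names(x)) && all(cas_par_names() %in% names(x))) {
    s <- if ("sigma" %in% names(x)) unname(x[["sigma"]]) else 0
    return(cas_parameters(x[["alpha"]], x[["beta"]], x[["c"]], x[["lam"]],
                          x[["phi"]], x[["tau"]], x[["delta"]], s))
  }
  if (length(x) < 7L) stop("as_cas_parameters: need 7 or 8 values")
  s <- if (length(x) >= 8L) x[[8L]] else 0
  do.call(cas_parameters, c(as.list(unname(x[1:7])), list(sigma = s)))
}

#' Rest-exercise-recovery protocol timing
#'
#' The default emulates a step-test protocol with a 7-min seated rest
#' segment, a 2-min stepping exercise bout and a 5-min seated recovery
#' (14 min total recording span).
#'
#' @param rest Rest segment duration in min.
#' @param exercise Exercise segment duration in min.
#' @param recovery Recovery segment duration in min.
#' @return An object of class `protocol_timing` with a `span` field
#'   (total duration, min).
#' @export
protocol_timing <- function(rest = 7, exercise = 2, recovery = 5) {
  if (rest <= 0 || exercise <= 0 || recovery <= 0)
    stop("protocol_timing: all segment durations must be strictly positive")
  structure(list(rest = rest, exercise = exercise, recovery = recovery,
                 span = rest + exercise + recovery),
            class = "protocol_timing")
}

#' Evaluate the coupled-logistic RRi trajectory
#'
#' The canonical form is a pair of mirrored smooth steps,
#' \deqn{f(t) = \alpha - \beta S(t; \lambda, \tau) +
#'       c\,\beta\, S(t; \phi, \tau + \delta),}
#' where \eqn{S(t; r, t_0) = 1 / (1 + e^{-r (t - t_0)})} rises from 0 to 1.
#' Under this convention `alpha` is the rest baseline, the exercise nadir
#' approaches `alpha - beta`, and the late-recovery asymptote is
#' `alpha - beta * (1 - c)`.
#'
#' `form = "plateau"` evaluates the algebraically equivalent
#' falling-step variant
#' \eqn{f(t) = \alpha' + \beta / (1 + e^{\lambda (t-\tau)}) -
#'      c \beta / (1 + e^{\phi (t-\tau-\delta)})},
#' in which the rest plateau sits at `alpha' + beta * (1 - c)` and the
#' curve tends to `alpha'` at late times. The two forms are related by a
#' shift of the baseline parameter:
#' `cas_curve(t, p)` equals `cas_curve(t, p', form = "plateau")` where
#' `p'` has `alpha' = alpha - beta * (1 - c)` and all other entries equal.
#'
#' @param t Time(s) in min; vectorized.
#' @param params A `cas_parameters` object (or coercible vector).
#' @param form `"canonical"` (default) or `"plateau"`.
#' @return Predicted RRi in ms, same length as `t`.
#' @examples
#' p <- cas_parameters(884.77, 403.99, 0.89, 3.01, 2.18, 6.89, 2.50)
#' cas_curve(c(0, 8, 14), p)
#' @export
cas_curve <- function(t, params, form = c("canonical", "plateau")) {
  form <- match.arg(form)
  p <- as_cas_parameters(params)
  s1 <- stats::plogis(p$lam * (t - p$tau))
  s2 <- stats::plogis(p$phi * (t - p$tau - p$delta))
  if (form == "canonical") {
    p$alpha - p$beta * s1 + p$c * p$beta * s2
  } else {
    # 1/(1 + e^{r(t-t0)}) = 1 - S(t; r, t0)
    p$alpha + p$beta * (1 - s1) - p$c * p$beta * (1 - s2)
  }
}

# Gradient of cas_curve w.r.t. (alpha, beta, c, lam, phi, tau, delta),
# canonical form; returns length(t) x 7 matrix.
cas_curve_grad <- function(t, theta) {
  alpha <- theta[1L]; beta <- theta[2L]; cc <- theta[3L]
  lam <- theta[4L]; phi <- theta[5L]; tau <- theta[6L]; delta <- theta[7L]
  s1 <- stats::plogis(lam * (t - tau))
  s2 <- stats::plogis(phi * (t - tau - delta))
  d1 <- s1 * (1 - s1)
  d2 <- s2 * (1 - s2)
  cbind(
    alpha = rep(1, length(t)),
    beta  = -s1 + cc * s2,
    c     = beta * s2,
    lam   = -beta * d1 * (t - tau),
    phi   = cc * beta * d2 * (t - tau - delta),
    tau   = beta * lam * d1 - cc * beta * phi * d2,
    delta = -cc * beta * phi * d2
  )
}

#' Huber loss
#'
#' Quadratic for residuals within `threshold`, linear beyond it:
#' \eqn{\rho(r) = r^2/2} for \eqn{|r| \le k} and
#' \eqn{\rho(r) = k (|r| - k/2)} otherwise. Returns the sum over all
#' residuals, the objective minimized by [fit_cas()].
#'
#' @param residuals Numeric vector of residuals (ms).
#' @param threshold Huber threshold k (ms, > 0).
#' @return Scalar objective value.
#' @examples
#' huber_loss(c(0.5, 10), threshold = 1)  # 0.125 + 9.5
#' @export
huber_loss <- function(residuals, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("huber_loss: threshold must be a positive scalar")
  a <- abs(residuals)
  quad <- a <= threshold
  sum(ifelse(quad, a^2 / 2, threshold * (a - threshold / 2)))
}

# Huber influence function psi(r) = d rho / d r.
huber_psi <- function(r, threshold) {
  pmin(pmax(r, -threshold), threshold)
}
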