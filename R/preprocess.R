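#' Low-pass filter configuration
#'
#' Butterworth design for the zero-phase smoothing step. The cutoff is a
#' normalized frequency on the beat-index axis (1 = Nyquist, i.e. half a
#' cycle per beat). The defaults (order 3, cutoff 0.10) suppress
#' beat-to-beat fluctuation while preserving the minute-scale rest,
#' exercise and recovery trends.
#'
#' @param order Filter order (>= 1).
#' @param cutoff Normalized cutoff in (0, 1).
#' @return A `filter_config` object.
#' @export
filter_config <- function(order = 3L, cutoff = 0.10) {
  if (order < 1) stop("filter_config: order must be >= 1")
  if (cutoff <= 0 || cutoff >= 1) stop("filter_config: cutoff must be in (0, 1)")
  structure(list(order = as.integer(order), cutoff = cutoff),
            class = "filter_config")
}

#' Ectopic-rejection configuration
#'
#' Beats are flagged when the absolute residual from a local polynomial
#' regression exceeds `mad_multiplier` times the MAD of the residuals.
#' With `mad_scaled = TRUE` the MAD carries the 1.4826 Gaussian
#' consistency constant, so the default threshold of twice the scaled MAD
#' corresponds to about 2 residual SDs under Gaussian noise.
#'
#' @param span Fraction of the series entering each local fit, in (0, 1].
#' @param mad_multiplier Threshold factor (> 0, default 2).
#' @param mad_scaled Apply the 1.4826 consistency constant (default TRUE).
#' @param degree Local polynomial degree (default 2, quadratic).
#' @return An `ectopic_config` object.
#' @export
ectopic_config <- function(span = 0.25, mad_multiplier = 2, mad_scaled = TRUE,
                           degree = 2L) {
  if (span <= 0 || span > 1) stop("ectopic_config: span must be in (0, 1]")
  if (mad_multiplier <= 0) stop("ectopic_config: mad_multiplier must be > 0")
  structure(list(span = span, mad_multiplier = mad_multiplier,
                 mad_scaled = isTRUE(mad_scaled), degree = as.integer(degree)),
            class = "ectopic_config")
}

# Direct-form-II-transposed IIR filter with explicit initial state.
# b, a: coefficient vectors (a[1] == 1 after normalisation); zi: initial
# state scaled to the signal's leading value for step-steady-state start.
iir_apply <- function(b, a, x, zi) {
  nb <- length(b); na <- length(a)
  n <- max(nb, na)
  b <- c(b, rep(0, n - nb)); a <- c(a, rep(0, n - na))
  b <- b / a[1]; a <- a / a[1]
  z <- c(zi, 0)  # z[n] stays 0
  y <- numeric(length(x))
  for (k in seq_along(x)) {
    xk <- x[k]
    yk <- b[1] * xk + z[1]
    if (n > 1) {
      for (j in seq_len(n - 1)) {
        z[j] <- b[j + 1] * xk + z[j + 1] - a[j + 1] * yk
      }
    }
    y[k] <- yk
  }
  y
}

# Steady-state filter state for a unit-level constant input (the analogue
# of scipy's lfilter_zi for direct form II transposed): with this state a
# constant signal passes through with no start-up transient.
iir_steady_state <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b))); a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  # steady state with x = y = 1: z_j = sum_{m > j} (b_m - a_m)
  rev(cumsum(rev(b[-1] - a[-1])))
}

#' Zero-phase Butterworth low-pass filtering of an RRi series
#'
#' Applies the configured Butterworth filter forward and then backward
#' over the unmasked intervals (treated as uniformly sampled in beat
#' index), so the net phase shift is zero. Endpoints are handled by odd
#' reflection padding combined with steady-state filter initialisation;
#' a constant series therefore passes through unchanged. Masked beats are
#' skipped and left untouched.
#'
#' @param rec An `rri_recording`.
#' @param cfg A `filter_config`.
#' @return The recording with smoothed intervals at unmasked positions.
#' @export
rri_lowpass <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "rri_recording"))
  if (!inherits(cfg, "filter_config")) stop("rri_lowpass: cfg must be a filter_config")
  x <- rec$rri[!rec$mask]
  n <- length(x)
  min_n <- 3L * cfg$order + 1L
  if (n < min_n)
    stop("rri_lowpass: need at least ", min_n, " usable beats for order ",
         cfg$order, " (got ", n, ")")
  bf <- signal::butter(cfg$order, cfg$cutoff, type = "low")
  b <- bf$b; a <- bf$a
  zi <- iir_steady_state(b, a)
  pad <- min(n - 1L, max(3L * cfg$order, 12L))
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_apply(b, a, xe, zi * xe[1])
  y <- rev(y)
  y <- iir_apply(b, a, y, zi * y[1])
  y <- rev(y)[(pad + 1):(pad + n)]
  replace_kept(rec, y)
}

#' Ectopic-beat rejection by local regression and MAD thresholding
#'
#' Fits a local polynomial regression (tricube-weighted, single pass) of
#' interval on beat index over the unmasked beats, computes residuals,
#' and flags beats whose absolute residual exceeds
#' `mad_multiplier * MAD(residuals)`. Flagged beats are marked in the
#' artifact mask and excluded from downstream fitting; they are never
#' interpolated. If the residual MAD is exactly zero, only beats with a
#' nonzero residual are flagged.
#'
#' @param rec An `rri_recording`.
#' @param cfg An `ectopic_config`.
#' @return A list with `recording` (mask updated) and `removed` (logical
#'   vector over all beats, `TRUE` where newly flagged).
#' @export
remove_ectopic <- function(rec, cfg = ectopic_config()) {
  stopifnot(inherits(rec, "rri_recording"))
  if (!inherits(cfg, "ectopic_config")) stop("remove_ectopic: cfg must be an ectopic_config")
  keep <- !rec$mask
  if (sum(keep) < 20L) stop("remove_ectopic: need at least 20 usable beats")
  y <- rec$rri[keep]
  idx <- seq_along(y)
  fit <- stats::loess(y ~ idx, span = cfg$span, degree = cfg$degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  r <- y - stats::fitted(fit)
  const <- if (cfg$mad_scaled) 1.4826 else 1
  m <- stats::mad(r, constant = const)
  flag <- if (m == 0) abs(r) > 0 else abs(r) > cfg$mad_multiplier * m
  if (all(flag)) stop("remove_ectopic: every beat flagged; signal unusable")
  removed <- rep(FALSE, length(rec$rri))
  removed[which(keep)[flag]] <- TRUE
  rec$mask <- rec$mask | removed
  list(recording = rec, removed = removed)
}

#' Preprocess an RRi recording
#'
#' Runs ectopic rejection and zero-phase low-pass filtering. The default
#' order removes spikes first so the filter cannot smear them into
#' neighbouring beats; `order = "filter_first"` applies the smoother to
#' the raw series before rejection.
#'
#' @param rec An `rri_recording`.
#' @param filter_cfg `filter_config`.
#' @param ectopic_cfg `ectopic_config`.
#' @param order `"ectopic_first"` (default) or `"filter_first"`.
#' @return A list with `recording` (cleaned and smoothed), `removed`
#'   (logical vector of newly flagged beats) and `report` (cleaning
#'   summary: beat counts, removal fraction, config echo).
#' @export
preprocess_rri <- function(rec, filter_cfg = filter_config(),
                           ectopic_cfg = ectopic_config(),
                           order = c("ectopic_first", "filter_first")) {
  order <- match.arg(order)
  n0 <- length(rec$rri)
  if (order == "ectopic_first") {
    ec <- remove_ectopic(rec, ectopic_cfg)
    out <- rri_lowpass(ec$recording, filter_cfg)
    removed <- ec$removed
  } else {
    sm <- rri_lowpass(rec, filter_cfg)
    ec <- remove_ectopic(sm, ectopic_cfg)
    out <- ec$recording
    removed <- ec$removed
  }
  report <- list(subject_id = rec$subject_id,
                 n_beats = n0,
                 n_removed = sum(removed),
                 removal_fraction = sum(removed) / n0,
                 order = order,
                 filter = unclass(filter_cfg),
                 ectopic = unclass(ectopic_cfg))
  list(recording = out, removed = removed, report = report)
}
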