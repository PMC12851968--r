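#' Beat-to-beat RRi recording
#'
#' Container for a single subject's R-R interval series: beat times in
#' minutes, interval values in milliseconds, and a per-beat artifact
#' mask (`TRUE` = excluded from analysis).
#'
#' @param time Numeric vector of beat times (min), strictly increasing.
#' @param rri Numeric vector of R-R intervals (ms), all > 0, aligned to
#'   `time`.
#' @param mask Logical artifact mask, same length (default all `FALSE`).
#' @param subject_id Opaque subject label.
#' @return An object of class `rri_recording`.
#' @export
rri_recording <- function(time, rri, mask = NULL, subject_id = "S1") {
  time <- as.numeric(time); rri <- as.numeric(rri)
  n <- length(rri)
  if (length(time) != n) stop("rri_recording: time and rri lengths differ")
  if (n == 0L) stop("rri_recording: empty recording")
  if (any(!is.finite(time)) || any(!is.finite(rri)))
    stop("rri_recording: non-finite values")
  if (any(diff(time) <= 0)) stop("rri_recording: beat times must be strictly increasing")
  if (any(rri <= 0)) stop("rri_recording: intervals must be > 0")
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n || !is.logical(mask))
    stop("rri_recording: mask must be a logical vector matching rri")
  structure(list(time = time, rri = rri, mask = mask,
                 subject_id = as.character(subject_id)),
            class = "rri_recording")
}

#' @export
print.rri_recording <- function(x, ...) {
  cat(sprintf("RRi recording '%s': %d beats over %.2f min (%d masked)\n",
              x$subject_id, length(x$rri), diff(range(x$time)), sum(x$mask)))
  invisible(x)
}

#' Number of usable (unmasked) beats
#' @param rec An `rri_recording`.
#' @return Integer count of beats with `mask == FALSE`.
#' @export
n_kept <- function(rec) sum(!rec$mask)

# Replace the interval values at unmasked positions; used by filters.
replace_kept <- function(rec, values) {
  stopifnot(length(values) == n_kept(rec))
  rec$rri[!rec$mask] <- values
  rec
}
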