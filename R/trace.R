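#' Construct a uniformly sampled signal trace
#'
#' A `trace` carries one channel of a recording session: membrane potential,
#' LFP or juxtacellular signal in mV, or whisker angle in degrees. Samples
#' are uniformly spaced; sample `i` (1-based) sits at time
#' `t0_s + (i - 1) / rate_hz` and is taken to cover the half-open period
#' `[t, t + 1/rate_hz)`.
#'
#' @param values Numeric vector of samples (finite, length >= 1).
#' @param rate_hz Sampling rate in samples/s (> 0).
#' @param t0_s Session time of the first sample, seconds.
#' @param units Unit string, e.g. `"mV"` or `"deg"` (metadata only).
#' @return An object of class `trace`.
#' @export
trace <- function(values, rate_hz, t0_s = 0, units = "mV") {
  tr <- structure(
    list(values = as.numeric(values), rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s), units = as.character(units)),
    class = "trace")
  validate_trace(tr)
  tr
}

#' Validate a trace object
#'
#' @param tr A `trace`.
#' @return `tr`, invisibly; stops on violation.
#' @export
validate_trace <- function(tr) {
  if (!inherits(tr, "trace")) stop("not a trace object")
  if (length(tr$values) < 1) stop("trace validation error: values must have length >= 1")
  if (!all(is.finite(tr$values))) stop("trace validation error: values must be finite")
  if (!is.finite(tr$rate_hz) || tr$rate_hz <= 0)
    stop("trace validation error: rate_hz must be > 0")
  if (!is.finite(tr$t0_s)) stop("trace validation error: t0_s must be finite")
  invisible(tr)
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz, t = [%g, %g) s, units %s\n",
              length(x$values), x$rate_hz, x$t0_s,
              x$t0_s + length(x$values) / x$rate_hz, x$units))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param tr A `trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(tr) {
  tr$t0_s + (seq_along(tr$values) - 1) / tr$rate_hz
}

#' Duration of a trace in seconds
#'
#' Half-open span: the trace covers `[t0_s, t0_s + n/rate_hz)`.
#'
#' @param tr A `trace`.
#' @return Duration in seconds.
#' @export
trace_duration <- function(tr) length(tr$values) / tr$rate_hz

#' Index range of samples falling in a half-open time window
#'
#' @param tr A `trace`.
#' @param start_s,end_s Window `[start_s, end_s)` in session time.
#' @return Integer vector `c(i0, i1)` (1-based, inclusive), or `NULL` when no
#'   sample falls inside the window.
#' @keywords internal
trace_index_range <- function(tr, start_s, end_s) {
  # small epsilon guards against float jitter when boundaries coincide with
  # sample times
  eps <- 0.25 / tr$rate_hz
  i0 <- ceiling((start_s - tr$t0_s) * tr$rate_hz - eps) + 1
  i1 <- ceiling((end_s - tr$t0_s) * tr$rate_hz - eps)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(length(tr$values), as.integer(i1))
  if (i1 < i0) return(NULL)
  c(i0, i1)
}

#' Extract the samples of a trace inside a half-open window
#'
#' @inheritParams trace_index_range
#' @return A `trace` restricted to `[start_s, end_s)`, or `NULL` if empty.
#' @export
trace_window <- function(tr, start_s, end_s) {
  rng <- trace_index_range(tr, start_s, end_s)
  if (is.null(rng)) return(NULL)
  trace(tr$values[rng[1]:rng[2]], tr$rate_hz,
        tr$t0_s + (rng[1] - 1) / tr$rate_hz, tr$units)
}

#' Logical mask of trace samples covered by an interval set
#'
#' @param tr A `trace`.
#' @param iset An `interval_set`.
#' @return Logical vector, one element per sample.
#' @export
trace_mask <- function(tr, iset) {
  mask <- logical(length(tr$values))
  if (n_intervals(iset) == 0) return(mask)
  for (k in seq_len(n_intervals(iset))) {
    rng <- trace_index_range(tr, iset$start[k], iset$end[k])
    if (!is.null(rng)) mask[rng[1]:rng[2]] <- TRUE
  }
  mask
}

# centered boxcar moving average; edges use the partial window so output
# length equals input length and no NA is introduced
boxcar_smooth <- function(x, width_samples) {
  w <- as.integer(width_samples)
  if (w <= 1) return(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  i0 <- pmax(seq_len(n) - half, 1L)
  i1 <- pmin(seq_len(n) + half, n)
  (cs[i1 + 1] - cs[i0]) / (i1 - i0 + 1)
}

# decimate by an integer factor (every k-th sample, starting at the first)
decimate_trace <- function(tr, target_rate_hz) {
  if (tr$rate_hz == target_rate_hz) return(tr)
  factor <- tr$rate_hz / target_rate_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop(sprintf("cannot decimate %g Hz to %g Hz: non-integer factor",
                 tr$rate_hz, target_rate_hz))
  factor <- as.integer(round(factor))
  trace(tr$values[seq(1, length(tr$values), by = factor)],
        target_rate_hz, tr$t0_s, tr$units)
}
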