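#' Parameters for behavioral/cortical state segmentation
#'
#' @param whisk_speed_threshold_deg_per_s Whisker speed threshold separating
#'   whisking from rest, degrees/s. Strict inequality: a speed exactly at
#'   the threshold is classified not-whisking.
#' @param whisk_smooth_ms Boxcar span for smoothing the whisker speed, ms.
#' @param min_epoch_s Minimum accepted epoch length, seconds.
#' @param merge_gap_s Gaps shorter than this are merged, seconds.
#' @param low_pctl,high_pctl Percentiles of the per-recording 1-5 Hz power
#'   distribution delimiting the Low and High power states.
#' @param transition_buffer_s Unassigned margin trimmed around whisking
#'   epochs before defining not-whisking, seconds.
#' @return A validated list of class `state_params`.
#' @export
state_params <- function(whisk_speed_threshold_deg_per_s = 50,
                         whisk_smooth_ms = 25,
                         min_epoch_s = 0.2,
                         merge_gap_s = 0.1,
                         low_pctl = 40,
                         high_pctl = 60,
                         transition_buffer_s = 0.05) {
  p <- as.list(environment())
  if (p$low_pctl >= p$high_pctl)
    stop("configuration error: low_pctl must be < high_pctl")
  if (p$whisk_speed_threshold_deg_per_s <= 0)
    stop("configuration error: whisk speed threshold must be > 0")
  if (p$min_epoch_s < 0 || p$merge_gap_s < 0 || p$transition_buffer_s < 0)
    stop("configuration error: epoch cleanup parameters must be >= 0")
  class(p) <- "state_params"
  p
}

#' Detect whisking (W) and not-whisking (NW) epochs
#'
#' Whisker speed is `|d(angle)/dt|` smoothed with a boxcar of
#' `whisk_smooth_ms`. Samples with speed strictly above the threshold form
#' W; NW is the remainder after removing a transition buffer around each W
#' epoch. Both sets get the merge-gap/min-epoch cleanup, so their union may
#' be a strict subset of the recording.
#'
#' @param whisker A whisker-angle [trace()] sampled at >= 100 Hz.
#' @param params A [state_params()].
#' @return List with `W` and `NW` [interval_set()]s.
#' @export
detect_whisking <- function(whisker, params = state_params()) {
  validate_trace(whisker)
  if (whisker$rate_hz < 100)
    stop("detect_whisking requires a whisker trace sampled at >= 100 Hz")
  n <- length(whisker$values)
  if ((n - 1) / whisker$rate_hz < params$min_epoch_s) {
    warning("whisker trace shorter than min_epoch_s; returning empty sets")
    return(list(W = interval_set("W"), NW = interval_set("NW")))
  }
  dt <- 1 / whisker$rate_hz
  speed <- abs(diff(whisker$values)) / dt
  w_sm <- max(1L, as.integer(round(params$whisk_smooth_ms / 1000 / dt)))
  speed <- boxcar_smooth(speed, w_sm)
  # speed sample j (from samples j, j+1) covers [t0+(j-1)dt, t0+j dt)
  whisking <- speed > params$whisk_speed_threshold_deg_per_s
  W <- intervals_from_logical(whisking, whisker$t0_s, dt, "W")
  W <- interval_clean(W, params$min_epoch_s, params$merge_gap_s)
  span <- interval_set("span", whisker$t0_s, whisker$t0_s + (n - 1) * dt)
  NW <- interval_difference(span,
                            interval_dilate(W, params$transition_buffer_s),
                            label = "NW")
  NW <- interval_clean(NW, params$min_epoch_s, params$merge_gap_s)
  NW$label <- "NW"
  list(W = W, NW = NW)
}

#' Sliding-window 1-5 Hz LFP band power
#'
#' The LFP is decimated to 2000 Hz, low-pass filtered at 200 Hz with a
#' zero-phase (forward-reverse) 4th-order Butterworth filter, and the power
#' in the 1-5 Hz band is computed by a sliding FFT: rectangular windows of
#' 2 s advanced by 10 ms, power summed as squared DFT magnitudes over the
#' frequency bins in `[1, 5]` Hz inclusive. Each value is attributed to the
#' window's center time.
#'
#' @param lfp An LFP [trace()] at >= 2000 Hz, duration >= `window_s`.
#' @param window_s Window length, seconds.
#' @param step_s Window advance, seconds.
#' @param band Band edges in Hz, inclusive.
#' @param analysis_rate_hz Decimation target, Hz.
#' @param lp_cutoff_hz Zero-phase low-pass corner, Hz.
#' @return A `band_power_series`: list with `times_s` (window centers),
#'   `power` (mV^2, arbitrary consistent scale), `window_s`, `step_s`.
#' @export
lfp_band_power <- function(lfp, window_s = 2, step_s = 0.01, band = c(1, 5),
                           analysis_rate_hz = 2000, lp_cutoff_hz = 200) {
  validate_trace(lfp)
  if (lfp$rate_hz < analysis_rate_hz)
    stop("lfp_band_power requires rate >= ", analysis_rate_hz, " Hz")
  if (trace_duration(lfp) < window_s)
    stop("lfp_band_power requires duration >= ", window_s, " s")
  dec <- decimate_trace(lfp, analysis_rate_hz)
  lp <- signal::butter(4, lp_cutoff_hz / (analysis_rate_hz / 2), type = "low")
  x <- signal::filtfilt(lp, dec$values)
  fs <- analysis_rate_hz
  N <- as.integer(round(window_s * fs))
  step <- as.integer(round(step_s * fs))
  starts <- seq(1L, length(x) - N + 1L, by = step)
  kbins <- seq(ceiling(band[1] * window_s), floor(band[2] * window_s))
  ang <- outer(0:(N - 1), kbins, function(nn, k) -2 * pi * k * nn / N)
  Ecos <- cos(ang); Esin <- sin(ang)
  power <- numeric(length(starts))
  blk <- 2048L
  for (b0 in seq(1L, length(starts), by = blk)) {
    b1 <- min(b0 + blk - 1L, length(starts))
    idx <- outer(0:(N - 1), starts[b0:b1] - 1L, "+") + 1L
    Xm <- matrix(x[idx], nrow = N)
    Re <- crossprod(Ecos, Xm); Im <- crossprod(Esin, Xm)
    power[b0:b1] <- colSums(Re * Re + Im * Im)
  }
  structure(list(times_s = dec$t0_s + (starts - 1) / fs + window_s / 2,
                 power = power, window_s = window_s, step_s = step_s),
            class = "band_power_series")
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf("<band_power_series> %d windows of %g s, step %g s\n",
              length(x$power), x$window_s, x$step_s))
  invisible(x)
}

#' Classify Low/High 1-5 Hz LFP power states
#'
#' Percentile thresholds are computed over the full per-recording
#' distribution of window power values (linear interpolation). A window is
#' Low (L) when its power is strictly below the `low_pctl` percentile and
#' High (H) when strictly above the `high_pctl` percentile; windows in
#' between are unassigned. Each window's label is attributed to the step
#' period starting at its center time; contiguous same-label runs become
#' intervals, then merge-gap/min-epoch cleanup is applied.
#'
#' @param bp A `band_power_series` from [lfp_band_power()].
#' @param params A [state_params()].
#' @return List with `L` and `H` [interval_set()]s.
#' @export
classify_lfp_state <- function(bp, params = state_params()) {
  if (!length(bp$power)) stop("empty band power series")
  p_lo <- quantile(bp$power, params$low_pctl / 100, type = 7, names = FALSE)
  p_hi <- quantile(bp$power, params$high_pctl / 100, type = 7, names = FALSE)
  low <- bp$power < p_lo
  high <- bp$power > p_hi
  t0 <- bp$times_s[1]
  L <- interval_clean(intervals_from_logical(low, t0, bp$step_s, "L"),
                      params$min_epoch_s, params$merge_gap_s)
  H <- interval_clean(intervals_from_logical(high, t0, bp$step_s, "H"),
                      params$min_epoch_s, params$merge_gap_s)
  list(L = L, H = H)
}

#' Define the joint Quiet/Active states
#'
#' Active = whisking with low 1-5 Hz LFP power (`W` intersect `L`);
#' Quiet = not-whisking with high power (`NW` intersect `H`). The discordant
#' combinations remain unassigned.
#'
#' @param W,NW,L,H [interval_set()]s on a common timeline.
#' @return List with `Active` and `Quiet` [interval_set()]s.
#' @export
define_quiet_active <- function(W, NW, L, H) {
  list(Active = interval_intersect(W, L, label = "Active"),
       Quiet = interval_intersect(NW, H, label = "Quiet"))
}

#' Classify a stimulus into Quiet/Active/Unassigned
#'
#' A stimulus at time `t` belongs to a state only when the window
#' `[t - 20 ms, t + 30 ms)` lies entirely inside a single interval of that
#' state's set.
#'
#' @param stim_time_s Stimulus onset time(s), seconds (vectorized).
#' @param active,quiet [interval_set()]s.
#' @param pre_s,post_s Required continuous margins, seconds.
#' @return Character vector: `"Active"`, `"Quiet"` or `"Unassigned"`.
#' @export
classify_stimulus_state <- function(stim_time_s, active, quiet,
                                    pre_s = 0.020, post_s = 0.030) {
  vapply(stim_time_s, function(t) {
    if (interval_covers(active, t - pre_s, t + post_s)) "Active"
    else if (interval_covers(quiet, t - pre_s, t + post_s)) "Quiet"
    else "Unassigned"
  }, character(1))
}

#' Segment a whole session into states
#'
#' Convenience wrapper running [detect_whisking()], [lfp_band_power()],
#' [classify_lfp_state()] and [define_quiet_active()] on a session's
#' `whisker_angle` and `lfp` traces.
#'
#' @param ses A [session()] with `whisker_angle` and `lfp` traces.
#' @param params A [state_params()].
#' @return The session with `W`, `NW`, `L`, `H`, `Active`, `Quiet` interval
#'   sets added to `ses$states`.
#' @export
classify_session_states <- function(ses, params = state_params()) {
  validate_session(ses)
  if (is.null(ses$traces$whisker_angle) || is.null(ses$traces$lfp))
    stop("classify_session_states needs whisker_angle and lfp traces")
  wk <- detect_whisking(ses$traces$whisker_angle, params)
  bp <- lfp_band_power(ses$traces$lfp)
  lh <- classify_lfp_state(bp, params)
  qa <- define_quiet_active(wk$W, wk$NW, lh$L, lh$H)
  ses$states <- modifyList(ses$states,
                           list(W = wk$W, NW = wk$NW, L = lh$L, H = lh$H,
                                Active = qa$Active, Quiet = qa$Quiet))
  ses
}
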