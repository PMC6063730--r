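#' Detect action potentials on an intracellular or juxtacellular trace
#'
#' Candidate events are upward crossings of the rate-of-rise threshold; each
#' candidate is accepted when the local maximum within the following 2 ms
#' exceeds `peak_min_mV`. One event is returned per suprathreshold
#' excursion, with a 2 ms absolute refractory period between accepted
#' peaks.
#'
#' @param tr A [trace()] sampled at >= 10 kHz.
#' @param dvdt_threshold_V_per_s Rate-of-rise threshold, V/s (= mV/ms).
#' @param peak_min_mV Minimum peak value, mV.
#' @param refractory_ms Minimum separation between accepted peaks, ms.
#' @return Numeric vector of spike peak times, seconds.
#' @export
detect_aps <- function(tr, dvdt_threshold_V_per_s = 20, peak_min_mV = -10,
                       refractory_ms = 2) {
  validate_trace(tr)
  if (tr$rate_hz < 10000)
    stop("detect_aps requires a trace sampled at >= 10 kHz")
  v <- tr$values
  n <- length(v)
  dvdt <- diff(v) * tr$rate_hz / 1000  # mV/ms == V/s
  fast <- dvdt > dvdt_threshold_V_per_s
  onsets <- which(diff(c(FALSE, fast)) == 1)
  if (!length(onsets)) return(numeric(0))
  look <- as.integer(round(0.002 * tr$rate_hz))
  peaks <- numeric(0)
  refr <- refractory_ms / 1000
  last_peak <- -Inf
  for (i in onsets) {
    hi <- min(n, i + look)
    ipk <- i + which.max(v[i:hi]) - 1L
    if (v[ipk] < peak_min_mV) next
    tpk <- tr$t0_s + (ipk - 1) / tr$rate_hz
    if (tpk - last_peak < refr) next
    peaks <- c(peaks, tpk)
    last_peak <- tpk
  }
  peaks
}

# interval set of excision windows around spikes and after stimuli
spontaneous_exclusions <- function(spikes, stim_times,
                                   spike_pre_s = 0.001, spike_post_s = 0.004,
                                   stim_post_s = 0.050) {
  s <- numeric(0); e <- numeric(0)
  if (length(spikes)) {
    s <- c(s, spikes - spike_pre_s); e <- c(e, spikes + spike_post_s)
  }
  if (length(stim_times)) {
    s <- c(s, stim_times); e <- c(e, stim_times + stim_post_s)
  }
  if (!length(s)) return(interval_set("excluded"))
  m <- merge_raw_intervals(s, e)
  interval_set("excluded", m$start, m$end)
}

#' State-resolved mean and SD of the membrane potential
#'
#' Pools the Vm samples inside the state's intervals, excising a window
#' around every spike peak (default -1 ms to +4 ms) and a 50 ms response
#' window after every optogenetic stimulus so the statistics describe
#' spontaneous activity. The SD is the population SD of the pooled samples.
#'
#' @param vm A Vm [trace()].
#' @param state An [interval_set()].
#' @param spikes Spike peak times from [detect_aps()], seconds.
#' @param stim_times Optogenetic stimulus onsets, seconds.
#' @param spike_pre_s,spike_post_s Excision window around spike peaks, s.
#' @param stim_post_s Excision window after each stimulus, s.
#' @return List: `mean_mV`, `sd_mV`, `n_samples`, `defined`. When no sample
#'   survives the exclusions the result is flagged `defined = FALSE` with
#'   `NA` statistics (never silently zero).
#' @export
vm_mean_sd <- function(vm, state, spikes = numeric(0),
                       stim_times = numeric(0),
                       spike_pre_s = 0.001, spike_post_s = 0.004,
                       stim_post_s = 0.050) {
  validate_trace(vm)
  validate_interval_set(state)
  keep <- interval_difference(
    state, spontaneous_exclusions(spikes, stim_times, spike_pre_s,
                                  spike_post_s, stim_post_s))
  mask <- trace_mask(vm, keep)
  n <- sum(mask)
  if (n == 0)
    return(list(mean_mV = NA_real_, sd_mV = NA_real_, n_samples = 0L,
                defined = FALSE))
  x <- vm$values[mask]
  m <- mean(x)
  list(mean_mV = m, sd_mV = sqrt(mean((x - m)^2)), n_samples = n,
       defined = TRUE)
}

#' Spontaneous AP rate within a state
#'
#' @param spikes Spike peak times, seconds.
#' @param state An [interval_set()].
#' @return List: `rate_hz`, `n_spikes`, `duration_s`, `defined` (`FALSE`
#'   when the state has zero duration).
#' @export
ap_rate <- function(spikes, state) {
  validate_interval_set(state)
  dur <- interval_total_duration(state)
  if (dur <= 0)
    return(list(rate_hz = NA_real_, n_spikes = 0L, duration_s = 0,
                defined = FALSE))
  n <- sum(interval_contains(state, spikes))
  list(rate_hz = n / dur, n_spikes = as.integer(n), duration_s = dur,
       defined = TRUE)
}

# greedy non-overlapping segments of seg_s fully inside the interval set
segment_starts <- function(state, seg_s) {
  out <- numeric(0)
  for (k in seq_len(n_intervals(state))) {
    nseg <- floor((state$end[k] - state$start[k]) / seg_s + 1e-9)
    if (nseg >= 1)
      out <- c(out, state$start[k] + seg_s * (seq_len(nseg) - 1))
  }
  out
}

#' State-resolved Vm FFT amplitude spectrum and 1-5 Hz band amplitude
#'
#' The Vm is median-filtered to remove spikes, cut into non-overlapping 1 s
#' segments fully inside the state's intervals (greedy from each interval's
#' start), and each segment's single-sided FFT amplitude spectrum
#' (`2 |X(f)| / N`, DC excluded) is averaged across segments. The band
#' amplitude is the mean amplitude over the bins at 1, 2, 3, 4 and 5 Hz
#' (1 Hz resolution of the 1 s window).
#'
#' @param vm A Vm [trace()].
#' @param state An [interval_set()].
#' @param median_filter_ms Median filter span, ms (0 disables).
#' @param stim_times Stimulus onsets whose 50 ms response windows are
#'   avoided when placing segments, seconds.
#' @param seg_s Segment length, seconds.
#' @param max_freq_hz Highest frequency retained in the returned spectrum.
#' @return List: `freq_hz`, `amplitude_mV` (averaged spectrum),
#'   `band_amp_1_5_mV`, `n_segments`, `defined`.
#' @export
vm_fft_amplitude <- function(vm, state, median_filter_ms = 8,
                             stim_times = numeric(0), seg_s = 1,
                             max_freq_hz = 100) {
  validate_trace(vm)
  validate_interval_set(state)
  usable <- if (length(stim_times))
    interval_difference(state,
                        spontaneous_exclusions(numeric(0), stim_times))
  else state
  starts <- segment_starts(usable, seg_s)
  if (!length(starts))
    return(list(freq_hz = numeric(0), amplitude_mV = numeric(0),
                band_amp_1_5_mV = NA_real_, n_segments = 0L,
                defined = FALSE))
  N <- as.integer(round(seg_s * vm$rate_hz))
  kmax <- min(as.integer(floor(max_freq_hz * seg_s)), N %/% 2)
  med_k <- if (median_filter_ms > 0) {
    k <- as.integer(round(median_filter_ms / 1000 * vm$rate_hz))
    if (k %% 2 == 0) k <- k + 1L
    k
  } else 1L
  acc <- numeric(kmax)
  n_used <- 0L
  for (s0 in starts) {
    rng <- trace_index_range(vm, s0, s0 + seg_s)
    if (is.null(rng) || rng[2] - rng[1] + 1 < N) next
    seg <- vm$values[rng[1]:(rng[1] + N - 1)]
    if (med_k > 1) seg <- as.numeric(runmed(seg, med_k, endrule = "median"))
    X <- fft(seg)
    acc <- acc + 2 * Mod(X[2:(kmax + 1)]) / N
    n_used <- n_used + 1L
  }
  if (n_used == 0)
    return(list(freq_hz = numeric(0), amplitude_mV = numeric(0),
                band_amp_1_5_mV = NA_real_, n_segments = 0L,
                defined = FALSE))
  amp <- acc / n_used
  freq <- (1:kmax) / seg_s
  band <- freq >= 1 & freq <= 5
  list(freq_hz = freq, amplitude_mV = amp,
       band_amp_1_5_mV = mean(amp[band]), n_segments = n_used,
       defined = TRUE)
}

#' Vm-LFP cross-correlation within a state
#'
#' Both signals are resampled to a common rate (the LFP additionally gets a
#' zero-phase 200 Hz low-pass), cut into 1 s segments fully inside the
#' state, and each segment of each signal is mean-subtracted and normalized
#' by its population SD. The correlation
#' `r(lag) = mean(vm_z(t) * lfp_z(t + lag))` is averaged across segments
#' over lags in `[-max_lag_s, +max_lag_s]`; the peak is the extremum of
#' largest absolute value (signed value reported). Positive lag means the
#' LFP lags the Vm.
#'
#' @param vm,lfp [trace()]s.
#' @param state An [interval_set()].
#' @param max_lag_s Maximum lag, seconds.
#' @param stim_times Stimulus onsets to avoid, seconds.
#' @param analysis_rate_hz Common analysis rate, Hz.
#' @param seg_s Segment length, seconds.
#' @return List: `peak_xcorr`, `peak_lag_s`, `lags_s`, `xcorr` (averaged
#'   function), `n_segments`, `defined`.
#' @export
vm_lfp_xcorr <- function(vm, lfp, state, max_lag_s = 0.1,
                         stim_times = numeric(0), analysis_rate_hz = 2000,
                         seg_s = 1) {
  validate_trace(vm); validate_trace(lfp)
  validate_interval_set(state)
  vmr <- decimate_trace(vm, analysis_rate_hz)
  lfr <- decimate_trace(lfp, analysis_rate_hz)
  lp <- signal::butter(4, 200 / (analysis_rate_hz / 2), type = "low")
  lfr$values <- as.numeric(signal::filtfilt(lp, lfr$values))
  usable <- if (length(stim_times))
    interval_difference(state,
                        spontaneous_exclusions(numeric(0), stim_times))
  else state
  starts <- segment_starts(usable, seg_s)
  N <- as.integer(round(seg_s * analysis_rate_hz))
  L <- as.integer(round(max_lag_s * analysis_rate_hz))
  lags <- (-L):L
  acc <- numeric(length(lags))
  n_used <- 0L
  for (s0 in starts) {
    rv <- trace_index_range(vmr, s0, s0 + seg_s)
    rl <- trace_index_range(lfr, s0, s0 + seg_s)
    if (is.null(rv) || is.null(rl)) next
    if (rv[2] - rv[1] + 1 < N || rl[2] - rl[1] + 1 < N) next
    x <- vmr$values[rv[1]:(rv[1] + N - 1)]
    y <- lfr$values[rl[1]:(rl[1] + N - 1)]
    sx <- sqrt(mean((x - mean(x))^2)); sy <- sqrt(mean((y - mean(y))^2))
    if (sx == 0 || sy == 0) next  # zero-variance segment skipped
    x <- (x - mean(x)) / sx
    y <- (y - mean(y)) / sy
    r <- vapply(lags, function(l) {
      if (l >= 0) sum(x[1:(N - l)] * y[(1 + l):N]) / N
      else sum(x[(1 - l):N] * y[1:(N + l)]) / N
    }, numeric(1))
    acc <- acc + r
    n_used <- n_used + 1L
  }
  if (n_used == 0)
    return(list(peak_xcorr = NA_real_, peak_lag_s = NA_real_,
                lags_s = lags / analysis_rate_hz, xcorr = acc,
                n_segments = 0L, defined = FALSE))
  avg <- acc / n_used
  ipk <- which.max(abs(avg))
  list(peak_xcorr = avg[ipk], peak_lag_s = lags[ipk] / analysis_rate_hz,
       lags_s = lags / analysis_rate_hz, xcorr = avg,
       n_segments = n_used, defined = TRUE)
}

#' All Fig-2-style Vm statistics for one state
#'
#' Bundles [vm_mean_sd()], [ap_rate()], [vm_fft_amplitude()] and
#' [vm_lfp_xcorr()] for a session and one state label.
#'
#' @param ses A [session()] with a `vm` trace (and `lfp` for the
#'   cross-correlation) whose `states` contain `state_label`.
#' @param state_label Name of the state in `ses$states`.
#' @param spikes Optional precomputed spike times; detected when `NULL`.
#' @param ... Passed to the underlying functions.
#' @return List of class `vm_state_stats`.
#' @export
vm_state_stats <- function(ses, state_label, spikes = NULL, ...) {
  validate_session(ses)
  state <- ses$states[[state_label]]
  if (is.null(state)) stop("session has no state '", state_label, "'")
  vm <- ses$traces$vm
  if (is.null(vm)) stop("session has no vm trace")
  if (is.null(spikes)) spikes <- detect_aps(vm)
  ms <- vm_mean_sd(vm, state, spikes, ses$stim_times_s)
  ar <- ap_rate(spikes, state)
  sp <- vm_fft_amplitude(vm, state, stim_times = ses$stim_times_s)
  xc <- if (!is.null(ses$traces$lfp))
    vm_lfp_xcorr(vm, ses$traces$lfp, state, stim_times = ses$stim_times_s)
  else list(peak_xcorr = NA_real_, peak_lag_s = NA_real_, n_segments = 0L,
            defined = FALSE)
  structure(list(state = state_label,
                 mean_vm_mV = ms$mean_mV, sd_vm_mV = ms$sd_mV,
                 ap_rate_hz = ar$rate_hz,
                 fft_freq_hz = sp$freq_hz,
                 fft_amplitude_mV = sp$amplitude_mV,
                 band_amp_1_5_mV = sp$band_amp_1_5_mV,
                 peak_xcorr = xc$peak_xcorr,
                 peak_xcorr_lag_s = xc$peak_lag_s,
                 n_segments = sp$n_segments,
                 defined = ms$defined && ar$defined),
            class = "vm_state_stats")
}
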