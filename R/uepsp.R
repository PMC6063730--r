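#' Optogenetically evoked AP statistics of the presynaptic cell
#'
#' Spikes are detected on the juxtacellular trace; an AP counts as evoked
#' when its peak falls within 10 ms after light onset, i.e. in
#' `(t_stim, t_stim + 10 ms]`. The first such AP per stimulus defines the
#' latency; jitter is the SD of the latencies.
#'
#' @param juxta Juxtacellular [trace()].
#' @param stim_times Stimulus onsets, seconds.
#' @param state Optional [interval_set()]; with `state2` given, stimuli are
#'   first restricted via [classify_stimulus_state()] to those assigned to
#'   `state`. With only `state`, stimuli inside its intervals are used.
#' @param evoked_window_s Evoked acceptance window after light onset, s.
#' @param dvdt_threshold_V_per_s,peak_min_mV Passed to [detect_aps()]
#'   (defaults tuned for a juxtacellular signal in mV).
#' @return List of class `evoked_ap_stats`: `n_stimuli`, `n_evoked`,
#'   `reliability`, `latency_ms`, `jitter_ms`, `defined`.
#' @export
evoked_ap_stats <- function(juxta, stim_times, state = NULL,
                            evoked_window_s = 0.010,
                            dvdt_threshold_V_per_s = 2, peak_min_mV = 0.5) {
  validate_trace(juxta)
  spikes <- detect_aps(juxta, dvdt_threshold_V_per_s, peak_min_mV)
  stims <- stim_times
  if (!is.null(state)) stims <- stims[interval_contains(state, stims)]
  if (!length(stims))
    return(structure(list(n_stimuli = 0L, n_evoked = 0L,
                          reliability = NA_real_, latency_ms = NA_real_,
                          jitter_ms = NA_real_, defined = FALSE),
                     class = "evoked_ap_stats"))
  lat <- vapply(stims, function(t) {
    cand <- spikes[spikes > t & spikes <= t + evoked_window_s]
    if (length(cand)) (cand[1] - t) * 1000 else NA_real_
  }, numeric(1))
  ev <- !is.na(lat)
  structure(list(n_stimuli = length(stims), n_evoked = sum(ev),
                 reliability = mean(ev),
                 latency_ms = if (any(ev)) mean(lat[ev]) else NA_real_,
                 jitter_ms = if (sum(ev) > 1) sd(lat[ev]) else
                   if (sum(ev) == 1) 0 else NA_real_,
                 defined = TRUE),
            class = "evoked_ap_stats")
}

#' Stimulus-triggered average Vm waveform
#'
#' Stimuli are excluded when any postsynaptic spike peak falls in the 50 ms
#' window starting 20 ms before light onset (`[t - 20 ms, t + 30 ms)`), and
#' optionally restricted to one state via [classify_stimulus_state()]. The
#' surviving stimulus-locked segments (-20 to +50 ms) are averaged and
#' smoothed with a boxcar (default 0.5 ms).
#'
#' @param vm Postsynaptic Vm [trace()].
#' @param stim_times Stimulus onsets, seconds.
#' @param spikes Postsynaptic spike peak times, seconds (from
#'   [detect_aps()]).
#' @param active,quiet Optional [interval_set()]s; with both given plus
#'   `state_label`, only stimuli classified into `state_label` are used.
#' @param state_label `"Active"`, `"Quiet"` or `NULL` (no state filter).
#' @param pre_s,post_s Segment extent around the stimulus, seconds.
#' @param excl_pre_s,excl_post_s Spike exclusion window around the
#'   stimulus, seconds.
#' @param smooth_ms Boxcar span applied to the average, ms.
#' @return List of class `triggered_average`: `waveform` (a [trace()] with
#'   `t0_s = -pre_s`, stimulus-locked), `n_stimuli_used`, `excluded_spike`,
#'   `excluded_state`, `defined`.
#' @export
triggered_average <- function(vm, stim_times, spikes = numeric(0),
                              active = NULL, quiet = NULL,
                              state_label = NULL,
                              pre_s = 0.020, post_s = 0.050,
                              excl_pre_s = 0.020, excl_post_s = 0.030,
                              smooth_ms = 0.5) {
  validate_trace(vm)
  stims <- stim_times
  excluded_state <- 0L
  if (!is.null(state_label)) {
    if (is.null(active) || is.null(quiet))
      stop("state filtering requires both active and quiet interval sets")
    cls <- classify_stimulus_state(stims, active, quiet)
    excluded_state <- sum(cls != state_label)
    stims <- stims[cls == state_label]
  }
  has_spike <- vapply(stims, function(t)
    any(spikes >= t - excl_pre_s & spikes < t + excl_post_s), logical(1))
  excluded_spike <- sum(has_spike)
  stims <- stims[!has_spike]
  npre <- as.integer(round(pre_s * vm$rate_hz))
  npost <- as.integer(round(post_s * vm$rate_hz))
  offs <- (-npre):(npost - 1L)
  n <- length(vm$values)
  centers <- as.integer(round((stims - vm$t0_s) * vm$rate_hz)) + 1L
  ok <- centers - npre >= 1L & centers + npost - 1L <= n
  centers <- centers[ok]
  if (!length(centers))
    return(structure(list(waveform = NULL, n_stimuli_used = 0L,
                          excluded_spike = excluded_spike,
                          excluded_state = excluded_state, defined = FALSE),
                     class = "triggered_average"))
  segs <- matrix(vm$values[outer(offs, centers, "+")], nrow = length(offs))
  avg <- rowMeans(segs)
  w <- max(1L, as.integer(round(smooth_ms / 1000 * vm$rate_hz)))
  avg <- boxcar_smooth(avg, w)
  structure(list(waveform = trace(avg, vm$rate_hz, -pre_s, "mV"),
                 n_stimuli_used = length(centers),
                 excluded_spike = excluded_spike,
                 excluded_state = excluded_state, defined = TRUE),
            class = "triggered_average")
}

#' Quantify a uEPSP from a stimulus-locked average waveform
#'
#' Onset is the first post-stimulus time at which the smoothed first
#' derivative of the average exceeds the class threshold (100 mV/s for PV,
#' 60 mV/s for Sst); the peak is the first subsequent time the smoothed
#' derivative becomes negative. Amplitude is the difference between the
#' mean over a 0.25 ms window centered at the peak and the mean over the
#' 0.25 ms baseline window immediately before onset; the 20-80% rise time
#' is obtained by linear interpolation on the rising phase. When the
#' derivative never exceeds the threshold within the search horizon, a
#' "no uEPSP detected" result is returned (amplitude undefined, not zero).
#'
#' @param avg Stimulus-locked average [trace()] (time 0 = stimulus onset),
#'   covering at least `[0, search_end_s]`, e.g. from
#'   [triggered_average()]`$waveform`.
#' @param cell_class `"PV"` or `"Sst"` (sets the derivative threshold), or
#'   supply `dvdt_threshold_mV_per_s` directly.
#' @param dvdt_threshold_mV_per_s Override of the onset threshold, mV/s.
#' @param deriv_smooth_ms Boxcar span for the derivative, ms.
#' @param amp_window_ms Averaging window for peak and baseline, ms.
#' @param search_end_s Onset search horizon after the stimulus, seconds.
#' @param n_stimuli_used Trial count carried into the result.
#' @return List of class `uepsp_measurement`: `amplitude_mV`,
#'   `onset_latency_ms`, `peak_time_ms`, `rise_time_20_80_ms`,
#'   `baseline_vm_mV`, `n_stimuli_used`, `detected`.
#' @export
quantify_uepsp <- function(avg, cell_class = c("PV", "Sst"),
                           dvdt_threshold_mV_per_s = NULL,
                           deriv_smooth_ms = 1.0, amp_window_ms = 0.25,
                           search_end_s = 0.030, n_stimuli_used = NA_integer_) {
  validate_trace(avg)
  if (is.null(dvdt_threshold_mV_per_s)) {
    cell_class <- match.arg(cell_class)
    dvdt_threshold_mV_per_s <- if (cell_class == "PV") 100 else 60
  }
  fs <- avg$rate_hz
  t <- trace_times(avg)
  if (t[length(t)] < search_end_s)
    stop("average waveform must cover [0, ", search_end_s, "] s post stimulus")
  v <- avg$values
  n <- length(v)
  # centered first derivative in mV/s, boxcar-smoothed
  d <- c(NA_real_, (v[3:n] - v[1:(n - 2)]) * fs / 2, NA_real_)
  d[1] <- d[2]; d[n] <- d[n - 1]
  wd <- max(1L, as.integer(round(deriv_smooth_ms / 1000 * fs)))
  d <- boxcar_smooth(d, wd)
  undetected <- structure(
    list(amplitude_mV = NA_real_, onset_latency_ms = NA_real_,
         peak_time_ms = NA_real_, rise_time_20_80_ms = NA_real_,
         baseline_vm_mV = NA_real_, n_stimuli_used = n_stimuli_used,
         detected = FALSE),
    class = "uepsp_measurement")
  searchable <- which(t > 0 & t <= search_end_s)
  ion <- searchable[d[searchable] > dvdt_threshold_mV_per_s][1]
  if (is.na(ion)) return(undetected)
  after <- which(d < 0 & seq_len(n) > ion)
  if (!length(after)) return(undetected)
  ipk <- after[1]
  win <- amp_window_ms / 1000
  base_rng <- trace_index_range(avg, t[ion] - win, t[ion])
  peak_rng <- trace_index_range(avg, t[ipk] - win / 2, t[ipk] + win / 2)
  if (is.null(base_rng) || is.null(peak_rng)) return(undetected)
  baseline <- mean(v[base_rng[1]:base_rng[2]])
  peak_v <- mean(v[peak_rng[1]:peak_rng[2]])
  amplitude <- peak_v - baseline
  ## 20-80% crossing times on the rising phase, linear interpolation
  lvl20 <- baseline + 0.2 * amplitude
  lvl80 <- baseline + 0.8 * amplitude
  cross_time <- function(level) {
    seg <- ion:ipk
    above <- which(v[seg] >= level)
    if (!length(above)) return(NA_real_)
    j <- seg[above[1]]
    if (j == ion || v[j] == v[j - 1]) return(t[j])
    t[j - 1] + (level - v[j - 1]) / (v[j] - v[j - 1]) / fs * 1  # frac * dt
  }
  t20 <- cross_time(lvl20); t80 <- cross_time(lvl80)
  structure(
    list(amplitude_mV = amplitude,
         onset_latency_ms = t[ion] * 1000,
         peak_time_ms = t[ipk] * 1000,
         rise_time_20_80_ms = if (is.na(t20) || is.na(t80)) NA_real_
         else (t80 - t20) * 1000,
         baseline_vm_mV = baseline,
         n_stimuli_used = n_stimuli_used,
         detected = TRUE),
    class = "uepsp_measurement")
}

#' Per-state uEPSP measurement for a session
#'
#' Runs [triggered_average()] restricted to one state and [quantify_uepsp()]
#' on the result.
#'
#' @param ses A [session()] with `vm` trace, stimuli, and `Active`/`Quiet`
#'   states present in `ses$states`.
#' @param state_label `"Active"` or `"Quiet"`.
#' @param spikes Optional precomputed postsynaptic spike times.
#' @param ... Passed to [quantify_uepsp()].
#' @return A `uepsp_measurement` with an added `state` field and the
#'   average `waveform`; `detected = FALSE` when no eligible stimulus
#'   remained.
#' @export
measure_state_uepsp <- function(ses, state_label, spikes = NULL, ...) {
  validate_session(ses)
  vm <- ses$traces$vm
  if (is.null(vm)) stop("session has no vm trace")
  if (is.null(ses$states$Active) || is.null(ses$states$Quiet))
    stop("session must carry Active and Quiet states; run classify_session_states()")
  if (is.null(spikes)) spikes <- detect_aps(vm)
  ta <- triggered_average(vm, ses$stim_times_s, spikes,
                          active = ses$states$Active,
                          quiet = ses$states$Quiet,
                          state_label = state_label)
  if (!ta$defined) {
    out <- structure(
      list(amplitude_mV = NA_real_, onset_latency_ms = NA_real_,
           peak_time_ms = NA_real_, rise_time_20_80_ms = NA_real_,
           baseline_vm_mV = NA_real_, n_stimuli_used = 0L,
           detected = FALSE),
      class = "uepsp_measurement")
    out$state <- state_label; out$waveform <- NULL
    return(out)
  }
  m <- quantify_uepsp(ta$waveform,
                      cell_class = if (ses$cell_class %in% c("PV", "Sst"))
                        ses$cell_class else "PV",
                      n_stimuli_used = ta$n_stimuli_used, ...)
  m$state <- state_label
  m$waveform <- ta$waveform
  m
}

#' Paired Active-minus-Quiet uEPSP contrasts across cells
#'
#' Takes one (Active, Quiet) measurement pair per cell, forms the paired
#' amplitude and baseline-Vm differences, and tests them with the exact
#' one-tailed Wilcoxon signed-rank test in the direction hypothesized for
#' the cell class: PV cells are predicted to increase uEPSP amplitude and
#' depolarize at baseline during Active states, Sst cells the opposite.
#' Cells missing either state are dropped with a message.
#'
#' @param measurements List of per-cell lists with elements `Active` and
#'   `Quiet`, each a `uepsp_measurement`.
#' @param cell_class `"PV"` or `"Sst"`.
#' @return List: `differences` (data frame of per-cell amplitude and
#'   baseline differences), `amplitude_test`, `baseline_test`
#'   ([signed_rank_exact()] results), `direction`, `n_cells_used`.
#' @export
state_contrast <- function(measurements, cell_class = c("PV", "Sst")) {
  cell_class <- match.arg(cell_class)
  amp_d <- numeric(0); base_d <- numeric(0); cells <- integer(0)
  for (i in seq_along(measurements)) {
    m <- measurements[[i]]
    ok <- !is.null(m$Active) && !is.null(m$Quiet) &&
      isTRUE(m$Active$detected) && isTRUE(m$Quiet$detected)
    if (!ok) {
      message("state_contrast: cell ", i, " lacks a measured state; dropped")
      next
    }
    amp_d <- c(amp_d, m$Active$amplitude_mV - m$Quiet$amplitude_mV)
    base_d <- c(base_d, m$Active$baseline_vm_mV - m$Quiet$baseline_vm_mV)
    cells <- c(cells, i)
  }
  direction <- if (cell_class == "PV") "greater" else "less"
  list(differences = data.frame(cell = cells, amplitude_diff_mV = amp_d,
                                baseline_diff_mV = base_d),
       amplitude_test = if (length(amp_d))
         signed_rank_exact(amp_d, sided = "one", direction = direction)
       else NULL,
       baseline_test = if (length(base_d))
         signed_rank_exact(base_d, sided = "one", direction = direction)
       else NULL,
       direction = direction, n_cells_used = length(cells))
}
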