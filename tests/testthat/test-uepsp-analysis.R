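# closed-form double-exponential written out independently of the package
dexp_kernel <- function(t, tr = 0.5e-3, td = 5e-3) {
  tp <- tr * td / (td - tr) * log(td / tr)
  pk <- exp(-tp / td) - exp(-tp / tr)
  ifelse(t >= 0, (exp(-t / td) - exp(-t / tr)) / pk, 0)
}

# gaussian juxtacellular spike bump
add_juxta_spike <- function(v, fs, t_peak, amp = 2) {
  ipk <- round(t_peak * fs) + 1
  idx <- (ipk - 20):(ipk + 20)
  v[idx] <- v[idx] + amp * exp(-0.5 * ((idx - ipk) / (0.0002 * fs))^2)
  v
}

test_that("evoked AP window, latency and jitter follow the 10 ms rule", {
  fs <- 20000
  v <- numeric(3 * fs)
  v <- add_juxta_spike(v, fs, 0.505)  # 5 ms after stim 1 -> evoked
  v <- add_juxta_spike(v, fs, 1.512)  # 12 ms after stim 2 -> not evoked
  v <- add_juxta_spike(v, fs, 2.505)  # 5 ms after stim 3 -> evoked
  jx <- trace(v, fs, 0, "mV")
  r <- evoked_ap_stats(jx, c(0.5, 1.5, 2.5))
  expect_equal(r$n_stimuli, 3)
  expect_equal(r$n_evoked, 2)
  expect_equal(r$reliability, 2 / 3)
  expect_equal(r$latency_ms, 5, tolerance = 0.1)
  expect_equal(r$jitter_ms, 0, tolerance = 0.1)  # identical latencies
  # no stimuli in the requested state -> flagged undefined
  r2 <- evoked_ap_stats(jx, c(0.5, 1.5, 2.5), state = interval_set("s", 10, 11))
  expect_false(r2$defined)
})

test_that("generator presynaptic spikes are reliably evoked at low jitter", {
  cfg <- generator_config(duration_s = 60, seed = 3, channels = "juxta")
  g <- generate_session(cfg)
  r <- evoked_ap_stats(g$session$traces$juxta, g$session$stim_times_s)
  expect_equal(r$reliability, 1.0)
  expect_equal(r$latency_ms, cfg$pre_ap_latency_ms, tolerance = 0.2)
  expect_equal(r$jitter_ms, cfg$pre_ap_jitter_ms, tolerance = 0.15)
  expect_lte(r$latency_ms, 10)
})

test_that("stimuli with postsynaptic spikes in [-20, +30) ms are excluded", {
  fs <- 20000
  vm <- trace(rep(-60, 5 * fs), fs, 0, "mV")
  stims <- c(1, 2, 3, 4)
  # spike 10 ms after stim 2 -> excluded; 40 ms after stim 3 -> retained
  r <- triggered_average(vm, stims, spikes = c(2.010, 3.040))
  expect_equal(r$n_stimuli_used, 3)
  expect_equal(r$excluded_spike, 1)
  # spike 20 ms before a stimulus also excludes it (closed left edge)
  r2 <- triggered_average(vm, stims, spikes = 1 - 0.020)
  expect_equal(r2$n_stimuli_used, 3)
  # all stimuli excluded -> flagged undefined
  r3 <- triggered_average(vm, 2.5, spikes = 2.5)
  expect_false(r3$defined)
})

test_that("eligible-stimulus counts match a brute-force recount", {
  cfg <- generator_config(duration_s = 120, seed = 19)
  g <- generate_session(cfg)
  ses <- classify_session_states(g$session)
  spk <- detect_aps(ses$traces$vm)
  for (st in c("Active", "Quiet")) {
    ta <- triggered_average(ses$traces$vm, ses$stim_times_s, spk,
                            active = ses$states$Active,
                            quiet = ses$states$Quiet, state_label = st)
    manual <- 0
    for (t in ses$stim_times_s) {
      if (classify_stimulus_state(t, ses$states$Active,
                                  ses$states$Quiet) != st) next
      if (any(spk >= t - 0.020 & spk < t + 0.030)) next
      manual <- manual + 1
    }
    expect_equal(ta$n_stimuli_used, manual)
  }
})

test_that("uEPSP quantification matches the closed-form kernel", {
  fs <- 20000
  t <- seq(-0.020, 0.050 - 1 / fs, by = 1 / fs)
  onset <- 0.004
  avg <- trace(-60 + 2.00 * dexp_kernel(t - onset), fs, -0.020, "mV")
  m <- quantify_uepsp(avg, "PV", deriv_smooth_ms = 0.25)
  expect_true(m$detected)
  expect_equal(m$amplitude_mV, 2.00, tolerance = 0.02)
  expect_equal(m$onset_latency_ms, onset * 1000, tolerance = 0.3)
  expect_equal(m$baseline_vm_mV, -60, tolerance = 0.01)
  # analytic 20-80% rise time from the closed form on a fine grid
  tp <- uepsp_kernel_peak_time(0.5, 5)
  fine <- seq(0, tp, by = 1e-7)
  kf <- dexp_kernel(fine)
  t20 <- fine[which(kf >= 0.2)[1]]; t80 <- fine[which(kf >= 0.8)[1]]
  expect_equal(m$rise_time_20_80_ms, (t80 - t20) * 1000, tolerance = 0.1 *
                 (t80 - t20) * 1000 + 0.05)
  expect_lt(abs(m$peak_time_ms - (onset + tp) * 1000), 0.5)
  # flat waveform: no uEPSP detected, amplitude undefined rather than zero
  flat <- trace(rep(-60, length(t)), fs, -0.020, "mV")
  expect_false(quantify_uepsp(flat, "PV")$detected)
  # the lower Sst derivative threshold can only move the onset earlier
  m_sst <- quantify_uepsp(avg, "Sst", deriv_smooth_ms = 0.25)
  expect_lte(m_sst$onset_latency_ms, m$onset_latency_ms)
})

test_that("amplitude recovery is unbiased and tightens with trial count", {
  fs <- 20000
  run_once <- function(n_stim, seed) {
    set.seed(seed)
    dur <- n_stim + 1
    stims <- seq(0.5, dur - 0.6, by = 1)[1:n_stim]
    t_rel <- seq(0, 0.03, by = 1 / fs)
    v <- rnorm(dur * fs, sd = 0.3) - 60
    for (ts in stims) {
      i0 <- round((ts + 0.004) * fs) + 1
      v[i0:(i0 + length(t_rel) - 1)] <- v[i0:(i0 + length(t_rel) - 1)] +
        1.0 * dexp_kernel(t_rel)
    }
    ta <- triggered_average(trace(v, fs, 0, "mV"), stims)
    quantify_uepsp(ta$waveform, "PV")$amplitude_mV
  }
  amp80 <- vapply(1:6, function(s) run_once(80, 100 + s), numeric(1))
  amp20 <- vapply(1:6, function(s) run_once(20, 200 + s), numeric(1))
  expect_lt(abs(mean(amp80) - 1.0), 0.05)       # bias < 5% of planted
  expect_lt(sd(amp80), sd(amp20) + 0.02)        # variance shrinks with n
})

test_that("paired state contrasts run the hypothesized one-tailed tests", {
  fake <- function(a_amp, q_amp, a_base = -57, q_base = -60) {
    mk <- function(amp, base) structure(
      list(amplitude_mV = amp, baseline_vm_mV = base, detected = TRUE),
      class = "uepsp_measurement")
    list(Active = mk(a_amp, a_base), Quiet = mk(q_amp, q_base))
  }
  cells <- lapply(c(0.4, 0.5, 0.3, 0.6, 0.2), function(d)
    fake(1 + d, 1))
  r <- state_contrast(cells, "PV")
  expect_equal(r$amplitude_test$p_value, 1 / 32)
  expect_equal(r$amplitude_test$direction, "greater")
  expect_equal(r$baseline_test$p_value, 1 / 32)
  # all-zero differences hit the degenerate tie branch
  zero_cells <- lapply(1:4, function(i) fake(1, 1, -60, -60))
  rz <- state_contrast(zero_cells, "PV")
  expect_true(rz$amplitude_test$degenerate)
  expect_equal(rz$amplitude_test$p_value, 1)
  # Sst direction flips; all-concordant-positive differences then give
  # p = P(W+ <= max) = 1
  r_sst <- state_contrast(cells, "Sst")
  expect_equal(r_sst$direction, "less")
  expect_equal(r_sst$amplitude_test$p_value, 1)
  # cells with a missing state are dropped with a message
  broken <- cells
  broken[[3]]$Active$detected <- FALSE
  expect_message(r2 <- state_contrast(broken, "PV"), "dropped")
  expect_equal(r2$n_cells_used, 4)
})

test_that("equal planted amplitudes rarely produce a significant contrast", {
  # type-I control at the measurement level: paired contrasts on pure-noise
  # differences of 5 cells should reject at about the nominal 1/32 rate
  set.seed(71)
  rejections <- 0
  for (b in 1:20) {
    diffs <- rnorm(5, mean = 0, sd = 0.05)
    p <- signed_rank_exact(diffs, sided = "one", direction = "greater")$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)
})
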