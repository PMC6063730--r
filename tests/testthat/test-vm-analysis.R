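# triangular spike bump used to build hand-made traces
add_spike <- function(v, fs, t_peak, height = 70, base = -60,
                      half_ms = 1) {
  half <- round(half_ms / 1000 * fs)
  ipk <- round(t_peak * fs) + 1
  idx <- (ipk - half):(ipk + half)
  tri <- height * (1 - abs(idx - ipk) / half)
  v[idx] <- v[idx] + tri
  v
}

test_that("AP detection finds planted spikes exactly once each", {
  fs <- 20000
  v <- rep(-60, fs)  # 1 s flat
  v <- add_spike(v, fs, 0.30)
  v <- add_spike(v, fs, 0.60)
  spk <- detect_aps(trace(v, fs, 0, "mV"))
  expect_equal(length(spk), 2)
  expect_equal(spk, c(0.30, 0.60), tolerance = 1e-3)
  # spike-free trace -> nothing
  expect_equal(length(detect_aps(trace(rep(-60, fs), fs, 0, "mV"))), 0)
  # two excursions 1 ms apart merge under the 2 ms refractory rule
  v2 <- rep(-60, fs)
  v2 <- add_spike(v2, fs, 0.500, half_ms = 0.4)
  v2 <- add_spike(v2, fs, 0.501, half_ms = 0.4)
  expect_equal(length(detect_aps(trace(v2, fs, 0, "mV"))), 1)
})

test_that("generator spike times are recovered with recall and precision 1", {
  cfg <- generator_config(duration_s = 60, seed = 23, stim_rate_hz = 0,
                          channels = "vm")
  g <- generate_session(cfg)
  spk <- detect_aps(g$session$traces$vm)
  gt <- g$ground_truth$spike_times_s
  expect_gt(length(gt), 5)
  expect_equal(length(spk), length(gt))
  expect_true(all(vapply(gt, function(t) min(abs(spk - t)) < 1e-3,
                         logical(1))))
})

test_that("state-resolved Vm mean/SD excises spikes and stimulus windows", {
  fs <- 20000
  whole <- interval_set("s", 0, 1)
  # constant trace: mean -60, SD 0
  r <- vm_mean_sd(trace(rep(-60, fs), fs, 0, "mV"), whole)
  expect_equal(r$mean_mV, -60)
  expect_equal(r$sd_mV, 0)
  # adding spikes changes nothing once they are excised
  v <- add_spike(rep(-60, fs), fs, 0.5)
  spk <- detect_aps(trace(v, fs, 0, "mV"))
  r2 <- vm_mean_sd(trace(v, fs, 0, "mV"), whole, spikes = spk)
  expect_equal(r2$mean_mV, -60, tolerance = 1e-6)
  expect_lt(r2$sd_mV, 0.05)
  # SD excluding APs <= SD including them
  r3 <- vm_mean_sd(trace(v, fs, 0, "mV"), whole)
  expect_lte(r2$sd_mV, r3$sd_mV)
  # stimulus response windows are excluded from "spontaneous" statistics
  v4 <- rep(-60, fs); v4[10001:10500] <- -50  # 25 ms artifact after t = 0.5
  r4 <- vm_mean_sd(trace(v4, fs, 0, "mV"), whole, stim_times = 0.5)
  expect_equal(r4$mean_mV, -60)
  # zero retained samples -> flagged, not zero
  r5 <- vm_mean_sd(trace(rep(-60, fs), fs, 0, "mV"),
                   interval_set("s", 5, 6))
  expect_false(r5$defined)
  expect_true(is.na(r5$mean_mV))
})

test_that("Active-minus-Quiet mean recovers the planted state shift", {
  cfg <- generator_config(duration_s = 60, seed = 29, vm_noise_sd_mV = 0,
                          vm_delta_coupling = 0, ap_threshold_mV = Inf,
                          stim_rate_hz = 0, channels = "vm")
  g <- generate_session(cfg)
  gt <- g$ground_truth
  mq <- vm_mean_sd(g$session$traces$vm, gt$planted_quiet)
  ma <- vm_mean_sd(g$session$traces$vm, gt$planted_active)
  expect_equal(ma$mean_mV - mq$mean_mV, cfg$vm_state_shift_mV,
               tolerance = 0.1)
})

test_that("AP rate is spikes per second of state time", {
  st <- interval_set("s", c(0, 10), c(3, 12))  # 5 s total
  expect_equal(ap_rate(seq(0.1, 2.9, length.out = 10), st)$rate_hz, 2.0)
  expect_equal(ap_rate(numeric(0), st)$rate_hz, 0)
  # spikes outside the state do not count
  expect_equal(ap_rate(c(1, 5, 6, 11), st)$rate_hz, 0.4)
  expect_false(ap_rate(1, interval_set("s"))$defined)
})

test_that("FFT amplitude of an integer-frequency tone is exact", {
  fs <- 20000
  t <- (0:(4 * fs - 1)) / fs
  vm <- trace(5 * sin(2 * pi * 4 * t), fs, 0, "mV")
  r <- vm_fft_amplitude(vm, interval_set("s", 0, 4), median_filter_ms = 0)
  expect_equal(r$n_segments, 4)
  expect_equal(r$amplitude_mV[r$freq_hz == 4], 5, tolerance = 5e-6)
  expect_lt(max(r$amplitude_mV[r$freq_hz %in% c(1, 2, 3, 5)]), 1e-9)
  expect_equal(r$band_amp_1_5_mV, 1.0, tolerance = 1e-6)
})

test_that("pipeline spectra equal a direct DFT oracle on noise segments", {
  set.seed(41)
  fs <- 2000
  vm <- trace(rnorm(3 * fs), fs, 0, "mV")
  r <- vm_fft_amplitude(vm, interval_set("s", 0, 3), median_filter_ms = 0,
                        max_freq_hz = 20)
  oracle <- sapply(0:2, function(k)
    oracle_segment_amplitude(vm$values[(k * fs + 1):((k + 1) * fs)], 20))
  expect_equal(r$amplitude_mV, rowMeans(oracle), tolerance = 1e-9)
  # no complete segment -> flagged undefined
  r2 <- vm_fft_amplitude(vm, interval_set("s", 0, 0.5))
  expect_false(r2$defined)
})

test_that("quiet-state slow Vm fluctuations exceed active-state ones", {
  for (seed in c(3, 4)) {
    cfg <- generator_config(duration_s = 60, seed = seed, stim_rate_hz = 0,
                            ap_threshold_mV = Inf, channels = "vm")
    g <- generate_session(cfg)
    gt <- g$ground_truth
    bq <- vm_fft_amplitude(g$session$traces$vm, gt$planted_quiet)
    ba <- vm_fft_amplitude(g$session$traces$vm, gt$planted_active)
    expect_gt(bq$band_amp_1_5_mV, ba$band_amp_1_5_mV)
  }
})

test_that("Vm-LFP cross-correlation obeys its normalization contract", {
  set.seed(55)
  fs <- 2000
  # slow (< 20 Hz) content so the 200 Hz LFP conditioning is transparent
  x <- signal::filtfilt(signal::butter(4, 20 / (fs / 2), "low"),
                        rnorm(10 * fs))
  whole <- interval_set("s", 0, 10)
  vm <- trace(x, fs, 0, "mV")
  # identical traces: peak 1 at lag 0
  r <- vm_lfp_xcorr(vm, vm, whole)
  expect_equal(r$peak_xcorr, 1.0, tolerance = 1e-6)
  expect_equal(r$peak_lag_s, 0)
  # delayed copy: peak at the planted 20 ms lag
  lag_n <- round(0.020 * fs)
  y <- c(rep(0, lag_n), x[1:(length(x) - lag_n)])
  r2 <- vm_lfp_xcorr(vm, trace(y, fs, 0, "mV"), whole)
  expect_equal(abs(r2$peak_lag_s), 0.020, tolerance = 1e-3)
  expect_gt(r2$peak_xcorr, 0.9)
  # independent noise: small peak
  set.seed(56)
  a <- trace(rnorm(30 * fs), fs, 0, "mV")
  b <- trace(rnorm(30 * fs), fs, 0, "mV")
  r3 <- vm_lfp_xcorr(a, b, interval_set("s", 0, 30))
  expect_equal(r3$n_segments, 30)
  expect_lt(abs(r3$peak_xcorr), 0.15)
  expect_lte(max(abs(r3$xcorr)), 1)
})
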