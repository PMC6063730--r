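#' Configuration for the synthetic session generator
#'
#' Defines the statistical structure of a simulated awake-cortex recording:
#' a two-state behavioral alternation (quiet/active), a 1-5 Hz LFP "delta"
#' component whose amplitude is state-dependent, whisking bouts confined to
#' active epochs, a membrane potential built from a resting level, a signed
#' active-state shift, LFP-delta coupling, band-limited noise, planted
#' unitary EPSPs following optogenetically evoked presynaptic spikes, and
#' threshold-crossing action potentials.
#'
#' Directions of the cell-class effects follow the biology being emulated:
#' PV-like cells depolarize in the active state with strong delta coupling,
#' Sst-like cells hyperpolarize with weak coupling; both fire less in the
#' active state because the large slow fluctuations that drive threshold
#' crossings collapse.
#'
#' @param duration_s Session length, seconds.
#' @param seed Integer seed; fully determines the output.
#' @param epoch_dwell_s Mean dwell time of each behavioral state, seconds
#'   (exponential, truncated below at `min_dwell_s`).
#' @param min_dwell_s Minimum epoch length, seconds.
#' @param quiet_lfp_delta_amp_mV,active_lfp_delta_amp_mV RMS amplitude of the
#'   1-5 Hz LFP component in quiet / active epochs, mV.
#' @param delta_pure_tone_hz If non-`NULL`, replace the narrowband-noise
#'   delta carrier with a pure sinusoid at this frequency (analytic tests).
#' @param lfp_noise_sd_mV Broadband LFP noise SD, mV.
#' @param whisk_amp_deg,whisk_freq_hz Whisking bout sinusoid amplitude
#'   (degrees) and frequency (Hz).
#' @param whisk_ramp_s On/off taper of each whisking bout, seconds.
#' @param whisk_noise_deg Whisker angle measurement noise SD, degrees.
#' @param whisker_rest_deg Resting whisker angle, degrees.
#' @param cell_class `"PV"`, `"Sst"` or `"NC"`.
#' @param vm_rest_mV Baseline membrane potential, mV.
#' @param vm_state_shift_mV Signed active-minus-quiet mean Vm shift, mV
#'   (positive for PV-like, negative for Sst-like).
#' @param vm_delta_coupling Dimensionless gain from the LFP delta component
#'   into Vm (high for PV-like, near 0 for Sst-like).
#' @param vm_noise_sd_mV Band-limited Vm noise SD, mV.
#' @param vm_noise_bw_hz Low-pass corner of the Vm noise, Hz.
#' @param ap_threshold_mV Spike threshold on the subthreshold Vm, mV
#'   (`Inf` disables spiking).
#' @param ap_refractory_ms Absolute refractory period, ms.
#' @param ap_amp_mV Spike peak height above threshold, mV.
#' @param ap_width_ms Spike template width, ms.
#' @param stim_rate_hz Optogenetic pulse rate, Hz (0 disables stimulation).
#' @param uepsp_amp_quiet_mV,uepsp_amp_active_mV Planted uEPSP peak
#'   amplitudes by behavioral state, mV.
#' @param uepsp_tau_rise_ms,uepsp_tau_decay_ms Double-exponential kinetics, ms.
#' @param uepsp_latency_ms Synaptic delay after the presynaptic AP peak, ms.
#' @param pre_ap_latency_ms,pre_ap_jitter_ms Mean and SD of the evoked
#'   presynaptic AP peak latency after light onset, ms.
#' @param juxta_spike_amp_mV,juxta_noise_sd_mV Juxtacellular spike height and
#'   noise SD, mV.
#' @param disagreement_fraction Probability that an epoch's LFP amplitude is
#'   swapped relative to its behavioral state (exercises the Unassigned
#'   categories; 0 means whisking and low LFP power coincide exactly).
#' @param channels Which traces to synthesize (subset of `vm`, `lfp`,
#'   `whisker_angle`, `juxta`).
#' @param vm_rate_hz,lfp_rate_hz,whisker_rate_hz,juxta_rate_hz Sampling
#'   rates, Hz.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(duration_s = 120,
                             seed = 1L,
                             epoch_dwell_s = 8,
                             min_dwell_s = 1,
                             quiet_lfp_delta_amp_mV = 0.5,
                             active_lfp_delta_amp_mV = 0.125,
                             delta_pure_tone_hz = NULL,
                             lfp_noise_sd_mV = 0.05,
                             whisk_amp_deg = 20,
                             whisk_freq_hz = 8,
                             whisk_ramp_s = 0.05,
                             whisk_noise_deg = 0,
                             whisker_rest_deg = 0,
                             cell_class = "PV",
                             vm_rest_mV = -60,
                             vm_state_shift_mV = 3,
                             vm_delta_coupling = 6,
                             vm_noise_sd_mV = 0.5,
                             vm_noise_bw_hz = 100,
                             ap_threshold_mV = -53.5,
                             ap_refractory_ms = 5,
                             ap_amp_mV = 60,
                             ap_width_ms = 2,
                             stim_rate_hz = 1,
                             uepsp_amp_quiet_mV = 1.0,
                             uepsp_amp_active_mV = 1.5,
                             uepsp_tau_rise_ms = 0.5,
                             uepsp_tau_decay_ms = 5,
                             uepsp_latency_ms = 1.5,
                             pre_ap_latency_ms = 2.5,
                             pre_ap_jitter_ms = 0.3,
                             juxta_spike_amp_mV = 2,
                             juxta_noise_sd_mV = 0.05,
                             disagreement_fraction = 0,
                             channels = c("vm", "lfp", "whisker_angle", "juxta"),
                             vm_rate_hz = 20000,
                             lfp_rate_hz = 20000,
                             whisker_rate_hz = 200,
                             juxta_rate_hz = 20000) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly; stops with a configuration error on violation.
#' @export
validate_generator_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("configuration error: ", what)
  chk(cfg$duration_s > 0, "duration_s must be > 0")
  chk(cfg$epoch_dwell_s > 0 && cfg$min_dwell_s > 0 &&
        cfg$min_dwell_s <= cfg$epoch_dwell_s,
      "epoch dwell times must be positive with min_dwell_s <= epoch_dwell_s")
  chk(cfg$uepsp_tau_rise_ms > 0 && cfg$uepsp_tau_decay_ms > 0,
      "uEPSP time constants must be > 0")
  chk(cfg$uepsp_tau_rise_ms < cfg$uepsp_tau_decay_ms,
      "uepsp_tau_rise_ms must be < uepsp_tau_decay_ms")
  chk(cfg$uepsp_latency_ms > 0 && cfg$pre_ap_latency_ms > 0,
      "synaptic and presynaptic latencies must be > 0")
  chk(cfg$pre_ap_jitter_ms >= 0, "pre_ap_jitter_ms must be >= 0")
  chk(all(c(cfg$quiet_lfp_delta_amp_mV, cfg$active_lfp_delta_amp_mV,
            cfg$uepsp_amp_quiet_mV, cfg$uepsp_amp_active_mV,
            cfg$vm_noise_sd_mV, cfg$lfp_noise_sd_mV) >= 0),
      "amplitudes and noise SDs must be >= 0")
  chk(cfg$stim_rate_hz >= 0, "stim_rate_hz must be >= 0")
  chk(cfg$disagreement_fraction >= 0 && cfg$disagreement_fraction <= 1,
      "disagreement_fraction must be in [0, 1]")
  chk(length(cfg$channels) >= 1 &&
        all(cfg$channels %in% c("vm", "lfp", "whisker_angle", "juxta")),
      "channels must be a non-empty subset of vm/lfp/whisker_angle/juxta")
  chk(cfg$cell_class %in% c("PV", "Sst", "NC"), "unknown cell_class")
  chk(all(c(cfg$vm_rate_hz, cfg$lfp_rate_hz, cfg$whisker_rate_hz,
            cfg$juxta_rate_hz) > 0), "sampling rates must be > 0")
  chk(cfg$ap_width_ms > 0 && cfg$ap_refractory_ms > 0 && cfg$ap_amp_mV > 0,
      "AP template parameters must be > 0")
  invisible(cfg)
}

#' Normalized double-exponential uEPSP kernel
#'
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / k_peak` for `t >= 0`,
#' 0 before; the peak equals exactly 1 at
#' `t_peak = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param t_s Times relative to uEPSP onset, seconds.
#' @param tau_rise_ms,tau_decay_ms Kinetics, ms (`tau_rise < tau_decay`).
#' @return Kernel values, unit peak.
#' @export
uepsp_kernel <- function(t_s, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms / 1000; td <- tau_decay_ms / 1000
  tp <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-tp / td) - exp(-tp / tr)
  out <- numeric(length(t_s))
  pos <- t_s >= 0
  out[pos] <- (exp(-t_s[pos] / td) - exp(-t_s[pos] / tr)) / peak
  out
}

#' Time of the uEPSP kernel peak
#' @inheritParams uepsp_kernel
#' @return Seconds after onset.
#' @export
uepsp_kernel_peak_time <- function(tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms / 1000; td <- tau_decay_ms / 1000
  tr * td / (td - tr) * log(td / tr)
}

# alternate quiet/active epochs over [0, duration); returns data.frame
draw_epochs <- function(duration_s, dwell_s, min_dwell_s) {
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  state <- if (runif(1) < 0.5) "quiet" else "active"
  t <- 0
  while (t < duration_s) {
    d <- if (dwell_s > min_dwell_s)
      min_dwell_s + rexp(1, rate = 1 / (dwell_s - min_dwell_s))
    else min_dwell_s
    e <- min(t + d, duration_s)
    starts <- c(starts, t); ends <- c(ends, e); states <- c(states, state)
    t <- e
    state <- if (state == "quiet") "active" else "quiet"
  }
  data.frame(start = starts, end = ends, state = states,
             stringsAsFactors = FALSE)
}

# band-limited unit-RMS 1-5 Hz carrier on a low-rate grid
delta_carrier <- function(n, fs, pure_tone_hz = NULL, t = NULL) {
  if (!is.null(pure_tone_hz)) {
    return(sqrt(2) * sin(2 * pi * pure_tone_hz * t))
  }
  bp <- signal::butter(2, c(1, 5) / (fs / 2), type = "pass")
  z <- signal::filtfilt(bp, rnorm(n))
  z / sd(z)
}

#' Generate one synthetic session with planted ground truth
#'
#' Builds the channels requested in `cfg$channels`: membrane potential
#' (rest + state shift + delta coupling + band-limited noise + uEPSP train +
#' threshold-crossing spikes), LFP (state-modulated 1-5 Hz component +
#' broadband noise), whisker angle (stationary in quiet epochs, tapered
#' sinusoidal bouts in active epochs) and a juxtacellular trace carrying the
#' presynaptic evoked spikes. Stimuli are periodic at `stim_rate_hz`.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements `session` (a [session()], including
#'   `planted_active` / `planted_quiet` / `planted_lfp_low` /
#'   `planted_lfp_high` interval sets) and `ground_truth` (planted state
#'   intervals, planted per-state uEPSP amplitudes, postsynaptic and
#'   presynaptic spike times, per-stimulus behavioral state, the low-rate
#'   delta carrier used, and per-epoch subthreshold Vm means).
#' @export
generate_session <- function(cfg) {
  validate_generator_config(cfg)
  set.seed(cfg$seed)
  dur <- cfg$duration_s

  ## planted behavioral states -------------------------------------------
  ep <- draw_epochs(dur, cfg$epoch_dwell_s, cfg$min_dwell_s)
  act <- ep$state == "active"
  planted_active <- interval_set("planted_active", ep$start[act], ep$end[act])
  planted_quiet <- interval_set("planted_quiet", ep$start[!act], ep$end[!act])

  ## per-epoch LFP amplitude assignment (optionally discordant) ----------
  flip <- runif(nrow(ep)) < cfg$disagreement_fraction
  lfp_low_epoch <- xor(act, flip)   # TRUE -> low delta amplitude
  planted_lfp_low <- interval_set("planted_lfp_low",
                                  ep$start[lfp_low_epoch], ep$end[lfp_low_epoch])
  planted_lfp_high <- interval_set("planted_lfp_high",
                                   ep$start[!lfp_low_epoch], ep$end[!lfp_low_epoch])

  ## low-rate (200 Hz) slow components ------------------------------------
  fs_lr <- 200
  n_lr <- as.integer(round(dur * fs_lr)) + 1L
  t_lr <- (seq_len(n_lr) - 1) / fs_lr
  carrier <- delta_carrier(n_lr, fs_lr, cfg$delta_pure_tone_hz, t_lr)
  amp_env <- ifelse(interval_contains(planted_lfp_low, pmin(t_lr, dur - 1e-9)),
                    cfg$active_lfp_delta_amp_mV, cfg$quiet_lfp_delta_amp_mV)
  delta_lr <- amp_env * carrier
  active_ind_lr <- as.numeric(interval_contains(planted_active,
                                                pmin(t_lr, dur - 1e-9)))

  ## stimulation and presynaptic spikes -----------------------------------
  stim_times <- if (cfg$stim_rate_hz > 0)
    seq(0.5, dur - 0.2, by = 1 / cfg$stim_rate_hz) else numeric(0)
  stim_state <- character(length(stim_times))
  if (length(stim_times)) {
    in_act <- interval_contains(planted_active, stim_times)
    stim_state <- ifelse(in_act, "Active", "Quiet")
  }
  pre_times <- stim_times + cfg$pre_ap_latency_ms / 1000 +
    if (length(stim_times)) rnorm(length(stim_times),
                                  sd = cfg$pre_ap_jitter_ms / 1000) else 0

  traces <- list()
  gt_spikes <- numeric(0)
  per_epoch_vm <- NULL

  ## whisker ---------------------------------------------------------------
  if ("whisker_angle" %in% cfg$channels) {
    fs_w <- cfg$whisker_rate_hz
    n_w <- as.integer(round(dur * fs_w))
    t_w <- (seq_len(n_w) - 1) / fs_w
    ang <- rep(cfg$whisker_rest_deg, n_w)
    for (k in which(act)) {
      s <- ep$start[k]; e <- ep$end[k]
      sel <- which(t_w >= s & t_w < e)
      if (!length(sel)) next
      tt <- t_w[sel] - s
      ramp <- pmin(1, tt / cfg$whisk_ramp_s, (e - s - tt) / cfg$whisk_ramp_s)
      ramp <- pmax(ramp, 0)
      ang[sel] <- ang[sel] +
        cfg$whisk_amp_deg * ramp * sin(2 * pi * cfg$whisk_freq_hz * tt)
    }
    if (cfg$whisk_noise_deg > 0)
      ang <- ang + rnorm(n_w, sd = cfg$whisk_noise_deg)
    traces$whisker_angle <- trace(ang, fs_w, 0, "deg")
  }

  ## LFP -------------------------------------------------------------------
  if ("lfp" %in% cfg$channels) {
    fs_l <- cfg$lfp_rate_hz
    n_l <- as.integer(round(dur * fs_l))
    t_l <- (seq_len(n_l) - 1) / fs_l
    lfp <- approx(t_lr, delta_lr, xout = t_l, rule = 2)$y
    if (cfg$lfp_noise_sd_mV > 0)
      lfp <- lfp + rnorm(n_l, sd = cfg$lfp_noise_sd_mV)
    traces$lfp <- trace(lfp, fs_l, 0, "mV")
  }

  ## juxtacellular (presynaptic spikes) ------------------------------------
  if ("juxta" %in% cfg$channels) {
    fs_j <- cfg$juxta_rate_hz
    n_j <- as.integer(round(dur * fs_j))
    jx <- if (cfg$juxta_noise_sd_mV > 0)
      rnorm(n_j, sd = cfg$juxta_noise_sd_mV) else numeric(n_j)
    sigma <- 0.0002 * fs_j  # 0.2 ms gaussian spike
    half <- as.integer(round(0.0008 * fs_j))
    shape <- cfg$juxta_spike_amp_mV * exp(-0.5 * ((-half:half) / sigma)^2)
    snapped <- numeric(length(pre_times))
    for (m in seq_along(pre_times)) {
      ipk <- as.integer(round(pre_times[m] * fs_j)) + 1L
      snapped[m] <- (ipk - 1) / fs_j
      lo <- max(1L, ipk - half); hi <- min(n_j, ipk + half)
      if (lo > hi) next
      jx[lo:hi] <- jx[lo:hi] + shape[(lo - ipk + half + 1):(hi - ipk + half + 1)]
    }
    pre_times <- snapped
    traces$juxta <- trace(jx, fs_j, 0, "mV")
  }

  ## membrane potential -----------------------------------------------------
  if ("vm" %in% cfg$channels) {
    fs_v <- cfg$vm_rate_hz
    n_v <- as.integer(round(dur * fs_v))
    t_v <- (seq_len(n_v) - 1) / fs_v
    slow_lr <- cfg$vm_rest_mV + cfg$vm_state_shift_mV * active_ind_lr +
      cfg$vm_delta_coupling * delta_lr
    vm <- approx(t_lr, slow_lr, xout = t_v, rule = 2)$y
    if (cfg$vm_noise_sd_mV > 0) {
      fs_nz <- 2000
      n_nz <- as.integer(round(dur * fs_nz)) + 1L
      lp <- signal::butter(4, cfg$vm_noise_bw_hz / (fs_nz / 2), type = "low")
      nz <- signal::filtfilt(lp, rnorm(n_nz))
      nz <- nz * (cfg$vm_noise_sd_mV / sd(nz))
      vm <- vm + approx((seq_len(n_nz) - 1) / fs_nz, nz, xout = t_v, rule = 2)$y
    }
    if (length(pre_times) && max(cfg$uepsp_amp_quiet_mV,
                                 cfg$uepsp_amp_active_mV) > 0) {
      klen <- as.integer(round(8 * cfg$uepsp_tau_decay_ms / 1000 * fs_v))
      ker <- uepsp_kernel((0:(klen - 1)) / fs_v,
                          cfg$uepsp_tau_rise_ms, cfg$uepsp_tau_decay_ms)
      for (m in seq_along(pre_times)) {
        amp <- if (stim_state[m] == "Active") cfg$uepsp_amp_active_mV
        else cfg$uepsp_amp_quiet_mV
        i0 <- as.integer(round((pre_times[m] + cfg$uepsp_latency_ms / 1000) *
                                 fs_v)) + 1L
        if (i0 > n_v) next
        i1 <- min(n_v, i0 + klen - 1L)
        vm[i0:i1] <- vm[i0:i1] + amp * ker[1:(i1 - i0 + 1)]
      }
    }
    ## per-epoch subthreshold means (ground truth, before spikes)
    cs <- cumsum(vm)
    em <- vapply(seq_len(nrow(ep)), function(k) {
      i0 <- as.integer(floor(ep$start[k] * fs_v)) + 1L
      i1 <- min(n_v, as.integer(ceiling(ep$end[k] * fs_v)))
      (cs[i1] - if (i0 > 1) cs[i0 - 1] else 0) / (i1 - i0 + 1)
    }, numeric(1))
    per_epoch_vm <- data.frame(start = ep$start, end = ep$end,
                               state = ep$state, mean_vm_mV = em,
                               stringsAsFactors = FALSE)
    ## threshold-crossing spikes
    if (is.finite(cfg$ap_threshold_mV)) {
      thr <- cfg$ap_threshold_mV
      cross <- which(vm[-1] >= thr & vm[-n_v] < thr) + 1L
      if (length(cross)) {
        refr <- cfg$ap_refractory_ms / 1000 * fs_v
        keep <- cross[1]; last <- cross[1]
        for (i in cross[-1]) {
          if (i - last >= refr) { keep <- c(keep, i); last <- i }
        }
        half_w <- as.integer(round(cfg$ap_width_ms / 2 / 1000 * fs_v))
        for (i in keep) {
          ipk <- min(i + half_w, n_v)
          h <- (thr + cfg$ap_amp_mV) - vm[ipk]
          lo <- i; hi <- min(n_v, i + 2L * half_w)
          tri <- 1 - abs((lo:hi) - ipk) / half_w
          tri[tri < 0] <- 0
          vm[lo:hi] <- vm[lo:hi] + h * tri
          gt_spikes <- c(gt_spikes, (ipk - 1) / fs_v)
        }
      }
    }
    traces$vm <- trace(vm, fs_v, 0, "mV")
  }

  meta <- list(generator = "statephys", seed = cfg$seed,
               cell_class = cfg$cell_class, duration_s = dur)
  ses <- session(traces, stim_times_s = stim_times,
                 cell_class = cfg$cell_class,
                 states = list(planted_active = planted_active,
                               planted_quiet = planted_quiet,
                               planted_lfp_low = planted_lfp_low,
                               planted_lfp_high = planted_lfp_high),
                 meta = meta)
  gt <- list(planted_active = planted_active,
             planted_quiet = planted_quiet,
             planted_lfp_low = planted_lfp_low,
             planted_lfp_high = planted_lfp_high,
             planted_uepsp_amp_mV = c(Quiet = cfg$uepsp_amp_quiet_mV,
                                      Active = cfg$uepsp_amp_active_mV),
             spike_times_s = gt_spikes,
             pre_spike_times_s = pre_times,
             stim_state = stim_state,
             per_epoch_mean_vm = per_epoch_vm,
             delta_lr = list(t_s = t_lr, values = delta_lr, rate_hz = fs_lr),
             active_ind_lr = active_ind_lr,
             config = cfg)
  list(session = ses, ground_truth = gt)
}

#' Generate a cohort of sessions with per-cell parameter jitter
#'
#' Cell seeds are derived deterministically from `master_seed`. Per-cell
#' jitter: resting Vm gets additive normal jitter (the spike threshold is
#' shifted along with it, so each cell keeps the same operating point
#' relative to threshold), the state shift gets additive normal jitter, and
#' both planted uEPSP amplitudes are scaled by a shared log-normal factor
#' (so the planted quiet/active ordering is preserved in every cell).
#'
#' @param n_cells Number of cells (>= 1).
#' @param cfg Base [generator_config()].
#' @param master_seed Integer master seed.
#' @param jitter Named list: `vm_rest_sd_mV` (default 1),
#'   `vm_state_shift_sd_mV` (default 0.5), `uepsp_amp_cv` (default 0.1).
#'   Set all to 0 for identical planted parameters across cells.
#' @return List of `n_cells` elements, each `list(session, ground_truth)`.
#' @export
generate_cohort <- function(n_cells, cfg, master_seed = cfg$seed,
                            jitter = list()) {
  if (n_cells < 1) stop("configuration error: n_cells must be >= 1")
  jit <- modifyList(list(vm_rest_sd_mV = 1, vm_state_shift_sd_mV = 0.5,
                         uepsp_amp_cv = 0.1), jitter)
  lapply(seq_len(n_cells), function(i) {
    cell_seed <- as.integer((as.numeric(master_seed) + 104729 * i) %%
                              2147483587)
    set.seed(cell_seed)
    ci <- cfg
    rest_jit <- rnorm(1, sd = jit$vm_rest_sd_mV)
    ci$vm_rest_mV <- cfg$vm_rest_mV + rest_jit
    if (is.finite(cfg$ap_threshold_mV))
      ci$ap_threshold_mV <- cfg$ap_threshold_mV + rest_jit
    ci$vm_state_shift_mV <- cfg$vm_state_shift_mV +
      rnorm(1, sd = jit$vm_state_shift_sd_mV)
    fac <- exp(rnorm(1, sd = jit$uepsp_amp_cv))
    ci$uepsp_amp_quiet_mV <- cfg$uepsp_amp_quiet_mV * fac
    ci$uepsp_amp_active_mV <- cfg$uepsp_amp_active_mV * fac
    ci$seed <- as.integer((cell_seed + 37) %% 2147483587)
    generate_session(ci)
  })
}
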