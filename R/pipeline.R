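#' Configuration for an end-to-end cohort run
#'
#' Bundles every parameter block of a full simulate-classify-analyze-test
#' run so that a run is fully reproducible from its configuration.
#'
#' @param pv_config,sst_config [generator_config()]s for the PV-like and
#'   Sst-like cohorts (set one to `NULL` to skip that class).
#' @param n_cells Cells per class.
#' @param seed Master seed; per-cell seeds are derived deterministically.
#' @param state_params A [state_params()].
#' @param jitter Per-cell parameter jitter, see [generate_cohort()].
#' @param measure_uepsp Run the uEPSP branch (requires `stim_rate_hz > 0`
#'   and the `vm`/`juxta` channels in the generator configs).
#' @return List of class `run_config`.
#' @export
run_config <- function(pv_config = generator_config(cell_class = "PV"),
                       sst_config = generator_config(
                         cell_class = "Sst", vm_state_shift_mV = -3,
                         vm_delta_coupling = 0.3, ap_threshold_mV = -58.75,
                         uepsp_amp_active_mV = 1.0),
                       n_cells = 5, seed = 1L,
                       state_params = statephys::state_params(),
                       jitter = list(), measure_uepsp = TRUE) {
  cfg <- as.list(environment())
  if (cfg$n_cells < 1) stop("configuration error: n_cells must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

# analyze one generated cell end-to-end; returns per-state stats
analyze_cell <- function(gen, params, measure_uepsp) {
  ses <- classify_session_states(gen$session, params)
  spikes <- if (!is.null(ses$traces$vm)) detect_aps(ses$traces$vm)
  else numeric(0)
  out <- list(cell_class = ses$cell_class)
  for (st in c("Quiet", "Active")) {
    vs <- vm_state_stats(ses, st, spikes = spikes)
    out[[st]] <- list(mean_vm_mV = vs$mean_vm_mV, sd_vm_mV = vs$sd_vm_mV,
                      ap_rate_hz = vs$ap_rate_hz,
                      band_amp_1_5_mV = vs$band_amp_1_5_mV,
                      peak_xcorr = vs$peak_xcorr,
                      defined = vs$defined)
  }
  if (measure_uepsp && length(ses$stim_times_s)) {
    out$uepsp <- list(
      Active = measure_state_uepsp(ses, "Active", spikes = spikes),
      Quiet = measure_state_uepsp(ses, "Quiet", spikes = spikes))
  }
  ## ground-truth comparison table
  out$truth <- list(
    planted_shift_mV = gen$ground_truth$config$vm_state_shift_mV,
    planted_uepsp_amp_mV = gen$ground_truth$planted_uepsp_amp_mV,
    state_agreement = {
      pa <- gen$ground_truth$planted_active
      pq <- gen$ground_truth$planted_quiet
      num <- interval_total_duration(interval_intersect(ses$states$Active, pa)) +
        interval_total_duration(interval_intersect(ses$states$Quiet, pq))
      den <- interval_total_duration(ses$states$Active) +
        interval_total_duration(ses$states$Quiet)
      if (den > 0) num / den else NA_real_
    })
  out
}

# per-class cohort summary: paired Quiet-vs-Active tests on the Fig-2-style
# quantities, box stats, and the one-tailed uEPSP contrasts
summarize_class <- function(cells, cell_class, measure_uepsp) {
  get2 <- function(field) {
    q <- vapply(cells, function(cl) cl$Quiet[[field]], numeric(1))
    a <- vapply(cells, function(cl) cl$Active[[field]], numeric(1))
    data.frame(quiet = q, active = a, diff = a - q)
  }
  fields <- c("mean_vm_mV", "sd_vm_mV", "ap_rate_hz", "band_amp_1_5_mV")
  per_cell <- lapply(fields, get2)
  names(per_cell) <- fields
  tests <- lapply(per_cell, function(df) {
    ok <- is.finite(df$diff)
    if (sum(ok) >= 1) signed_rank_exact(df$diff[ok], sided = "two") else NULL
  })
  safe_box <- function(v) if (any(is.finite(v))) box_stats(v) else NULL
  boxes <- lapply(per_cell, function(df)
    list(Quiet = safe_box(df$quiet), Active = safe_box(df$active)))
  out <- list(cell_class = cell_class, per_cell = per_cell,
              paired_tests = tests, box_stats = boxes)
  if (measure_uepsp) {
    ms <- lapply(cells, function(cl) cl$uepsp)
    has <- vapply(ms, function(m) !is.null(m), logical(1))
    if (any(has))
      out$uepsp_contrast <- state_contrast(ms[has], cell_class = cell_class)
  }
  out
}

#' Run a full synthetic cohort analysis
#'
#' Generates PV-like and Sst-like cohorts, segments every session into
#' Quiet/Active states from its own whisker and LFP channels, computes
#' state-resolved Vm statistics and (optionally) per-state uEPSP
#' measurements, and assembles cohort-level box statistics, paired
#' two-tailed signed-rank tests on the Quiet-vs-Active quantities, unpaired
#' rank-sum comparisons between classes, and the one-tailed uEPSP state
#' contrasts. Undefined per-cell results propagate as `NA`, never as zero.
#'
#' @param cfg A [run_config()].
#' @return List of class `cohort_report`: `config` echo, `cells` (per-cell
#'   results including ground-truth agreement), `PV` / `Sst` class
#'   summaries, `between_class` rank-sum tests on the Quiet-state mean Vm
#'   and the Active-minus-Quiet mean-Vm difference.
#' @export
run_cohort_analysis <- function(cfg = run_config()) {
  classes <- list()
  cells <- list()
  for (cl in c("PV", "Sst")) {
    gcfg <- if (cl == "PV") cfg$pv_config else cfg$sst_config
    if (is.null(gcfg)) next
    seed_off <- if (cl == "PV") 0L else 500000L
    gens <- generate_cohort(cfg$n_cells, gcfg,
                            master_seed = cfg$seed + seed_off,
                            jitter = cfg$jitter)
    res <- lapply(gens, analyze_cell, params = cfg$state_params,
                  measure_uepsp = cfg$measure_uepsp)
    cells[[cl]] <- res
    classes[[cl]] <- summarize_class(res, cl, cfg$measure_uepsp)
  }
  between <- NULL
  if (!is.null(classes$PV) && !is.null(classes$Sst)) {
    between <- list(
      quiet_mean_vm = rank_sum_exact(
        classes$PV$per_cell$mean_vm_mV$quiet,
        classes$Sst$per_cell$mean_vm_mV$quiet, sided = "two"),
      mean_vm_shift = rank_sum_exact(
        classes$PV$per_cell$mean_vm_mV$diff,
        classes$Sst$per_cell$mean_vm_mV$diff, sided = "two"))
  }
  structure(list(config = cfg, cells = cells, PV = classes$PV,
                 Sst = classes$Sst, between_class = between),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  for (cl in c("PV", "Sst")) {
    s <- x[[cl]]
    if (is.null(s)) next
    d <- s$per_cell$mean_vm_mV$diff
    cat(sprintf("  %s (n = %d): mean Vm Active-Quiet median %+.2f mV; ",
                cl, length(d), median(d)))
    if (!is.null(s$uepsp_contrast) && !is.null(s$uepsp_contrast$amplitude_test))
      cat(sprintf("uEPSP amplitude one-tailed p = %.3f",
                  s$uepsp_contrast$amplitude_test$p_value))
    cat("\n")
  }
  invisible(x)
}

#' Serialize a cohort report to JSON
#'
#' Every number in the report traces back to an operation and the echoed
#' configuration block.
#'
#' @param report A `cohort_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "trace")) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(path)
}
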