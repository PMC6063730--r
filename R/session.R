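#' Construct a recording session bundle
#'
#' A session bundles the simultaneously recorded channels of one cell
#' (any subset of the roles `vm`, `lfp`, `whisker_angle`, `juxta`),
#' optogenetic stimulus onset times, the recorded cell's class, named state
#' interval sets, and free-form metadata.
#'
#' @param traces Named list of [trace()] objects; names are channel roles.
#' @param stim_times_s Strictly increasing numeric vector of optogenetic
#'   pulse onset times, seconds (may be empty).
#' @param cell_class One of `"PV"`, `"Sst"`, `"NC"`, `"presynaptic"`.
#' @param states Named list of [interval_set()] objects.
#' @param meta Free-form named list (animal id, seed, generator parameters).
#' @return An object of class `session`.
#' @export
session <- function(traces, stim_times_s = numeric(0), cell_class = "NC",
                    states = list(), meta = list()) {
  ses <- structure(
    list(traces = traces, stim_times_s = as.numeric(stim_times_s),
         cell_class = as.character(cell_class), states = states, meta = meta),
    class = "session")
  validate_session(ses)
  ses
}

#' Validate a session object
#'
#' Checks trace and interval-set invariants, role names, strictly increasing
#' stimulus times and a known cell class.
#'
#' @param ses A `session`.
#' @return `ses`, invisibly; stops on violation.
#' @export
validate_session <- function(ses) {
  if (!inherits(ses, "session")) stop("not a session object")
  if (length(ses$traces) < 1) stop("session validation error: needs at least one trace")
  roles <- c("vm", "lfp", "whisker_angle", "juxta")
  if (is.null(names(ses$traces)) || !all(names(ses$traces) %in% roles))
    stop("session validation error: trace roles must be among ",
         paste(roles, collapse = ", "))
  for (tr in ses$traces) validate_trace(tr)
  if (!ses$cell_class %in% c("PV", "Sst", "NC", "presynaptic"))
    stop("session validation error: unknown cell_class '", ses$cell_class, "'")
  st <- ses$stim_times_s
  if (length(st) > 1 && is.unsorted(st, strictly = TRUE))
    stop("session validation error: stim_times_s must be strictly increasing")
  for (iset in ses$states) validate_interval_set(iset)
  invisible(ses)
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> cell_class %s, %d stimuli, states: %s\n",
              x$cell_class, length(x$stim_times_s),
              if (length(x$states)) paste(names(x$states), collapse = ", ")
              else "none"))
  for (role in names(x$traces)) {
    tr <- x$traces[[role]]
    cat(sprintf("  %-13s %d samples @ %g Hz [%s]\n", role,
                length(tr$values), tr$rate_hz, tr$units))
  }
  invisible(x)
}

#' Common time span covered by all traces of a session
#'
#' @param ses A `session`.
#' @return `c(start_s, end_s)` of the intersection of all trace spans.
#' @export
session_span <- function(ses) {
  s <- max(vapply(ses$traces, function(tr) tr$t0_s, numeric(1)))
  e <- min(vapply(ses$traces, function(tr) tr$t0_s + trace_duration(tr),
                  numeric(1)))
  c(s, e)
}
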