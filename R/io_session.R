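#' Write a session to a directory
#'
#' On-disk layout: `meta.json` holds rates, units, roles, cell class,
#' stimulus times and free metadata; `states.json` holds the interval sets;
#' each channel is stored as raw little-endian float64 in `<role>.f64`
#' (`whisker_angle` maps to `whisker.f64`). The layout round-trips bitwise
#' through [read_session()].
#'
#' @param ses A valid [session()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(ses, path) {
  validate_session(ses)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory '", path, "'")
  }
  chan_file <- function(role) {
    paste0(if (role == "whisker_angle") "whisker" else role, ".f64")
  }
  traces_meta <- lapply(names(ses$traces), function(role) {
    tr <- ses$traces[[role]]
    list(role = role, file = chan_file(role), rate_hz = tr$rate_hz,
         t0_s = tr$t0_s, units = tr$units, n = length(tr$values))
  })
  names(traces_meta) <- names(ses$traces)
  meta <- list(format = "statephys-session", format_version = 1L,
               cell_class = ses$cell_class,
               stim_times_s = ses$stim_times_s,
               traces = traces_meta,
               meta = ses$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  states <- lapply(ses$states, function(iset) {
    if (n_intervals(iset) == 0) list() else
      lapply(seq_len(n_intervals(iset)),
             function(k) c(iset$start[k], iset$end[k]))
  })
  jsonlite::write_json(states, file.path(path, "states.json"),
                       auto_unbox = TRUE, digits = NA)
  for (role in names(ses$traces)) {
    con <- file(file.path(path, chan_file(role)), "wb")
    writeBin(ses$traces[[role]]$values, con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]: restores traces (rates and units taken from
#' `meta.json`, never guessed), stimulus times, cell class, state interval
#' sets and metadata, and validates every invariant.
#'
#' @param path Session directory written by [write_session()].
#' @return A [session()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("I/O error: no such session directory '", path, "'")
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("format error: missing meta.json")
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  for (key in c("cell_class", "traces"))
    if (is.null(meta[[key]]))
      stop("format error: meta.json missing mandatory key '", key, "'")
  traces <- list()
  for (role in names(meta$traces)) {
    tm <- meta$traces[[role]]
    for (key in c("file", "rate_hz", "t0_s", "units", "n"))
      if (is.null(tm[[key]]))
        stop("format error: trace '", role, "' missing metadata key '", key, "'")
    f <- file.path(path, tm$file)
    if (!file.exists(f)) stop("format error: missing channel file '", tm$file, "'")
    con <- file(f, "rb")
    vals <- readBin(con, what = "double", n = as.integer(tm$n), size = 8,
                    endian = "little")
    close(con)
    if (length(vals) != tm$n)
      stop("format error: channel '", role, "' truncated")
    traces[[role]] <- trace(vals, tm$rate_hz, tm$t0_s, tm$units)
  }
  states <- list()
  states_file <- file.path(path, "states.json")
  if (file.exists(states_file)) {
    raw <- jsonlite::read_json(states_file, simplifyVector = FALSE)
    for (label in names(raw)) {
      ivs <- raw[[label]]
      start <- vapply(ivs, function(p) as.numeric(p[[1]]), numeric(1))
      end <- vapply(ivs, function(p) as.numeric(p[[2]]), numeric(1))
      states[[label]] <- interval_set(label, start, end)
    }
  }
  stim <- as.numeric(unlist(meta$stim_times_s))
  if (is.null(stim)) stim <- numeric(0)
  session(traces, stim_times_s = stim, cell_class = meta$cell_class,
          states = states, meta = meta$meta)
}
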