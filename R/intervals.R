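#' Construct a labeled set of half-open time intervals
#'
#' Interval sets carry state epochs (Whisking/Not-Whisking, High/Low 1-5 Hz
#' LFP power, Quiet/Active) and planted ground-truth annotations. Intervals
#' are half-open `[start, end)`, sorted ascending and pairwise disjoint.
#'
#' @param label State name, e.g. `"W"`, `"NW"`, `"L"`, `"H"`, `"Active"`,
#'   `"Quiet"`.
#' @param start,end Numeric vectors of equal length: interval bounds in
#'   seconds, `start < end` elementwise.
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(label, start = numeric(0), end = numeric(0)) {
  iset <- structure(
    list(label = as.character(label), start = as.numeric(start),
         end = as.numeric(end)),
    class = "interval_set")
  validate_interval_set(iset)
  iset
}

#' Validate an interval set
#'
#' Checks `start < end` for every interval, ascending order and pairwise
#' disjointness.
#'
#' @param iset An `interval_set`.
#' @return `iset`, invisibly; stops on violation.
#' @export
validate_interval_set <- function(iset) {
  if (!inherits(iset, "interval_set")) stop("not an interval_set object")
  s <- iset$start; e <- iset$end
  if (length(s) != length(e))
    stop("interval validation error: start/end length mismatch")
  if (length(s) == 0) return(invisible(iset))
  if (!all(is.finite(s)) || !all(is.finite(e)))
    stop("interval validation error: non-finite bounds")
  if (any(s >= e))
    stop("interval validation error: start must be < end for every interval")
  if (is.unsorted(s, strictly = TRUE))
    stop("interval validation error: intervals must be sorted ascending")
  if (length(s) > 1 && any(e[-length(e)] > s[-1]))
    stop("interval validation error: intervals overlap")
  invisible(iset)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> '%s': %d intervals, total %.3f s\n",
              x$label, n_intervals(x), interval_total_duration(x)))
  invisible(x)
}

#' Number of intervals in a set
#' @param iset An `interval_set`.
#' @return Integer count.
#' @export
n_intervals <- function(iset) length(iset$start)

#' Total duration covered by an interval set
#' @param iset An `interval_set`.
#' @return Seconds.
#' @export
interval_total_duration <- function(iset) sum(iset$end - iset$start)

# merge touching/overlapping sorted raw intervals into a canonical disjoint set
merge_raw_intervals <- function(start, end) {
  if (length(start) == 0) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me) {
      me <- max(me, end[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[k]; me <- end[k]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Intersection of two interval sets
#'
#' @param a,b `interval_set` objects.
#' @param label Label for the result (default `"<a> & <b>"`).
#' @return An `interval_set` covering the times in both `a` and `b`.
#' @export
interval_intersect <- function(a, b, label = paste0(a$label, "&", b$label)) {
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= n_intervals(a) && j <= n_intervals(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  interval_set(label, out_s, out_e)
}

#' Union of two interval sets
#'
#' @inheritParams interval_intersect
#' @return An `interval_set` covering the times in either set.
#' @export
interval_union <- function(a, b, label = paste0(a$label, "|", b$label)) {
  m <- merge_raw_intervals(c(a$start, b$start), c(a$end, b$end))
  interval_set(label, m$start, m$end)
}

#' Set difference of two interval sets
#'
#' @inheritParams interval_intersect
#' @return An `interval_set` covering times in `a` but not in `b`.
#' @export
interval_difference <- function(a, b, label = a$label) {
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(n_intervals(a))) {
    cur_s <- a$start[i]; cur_e <- a$end[i]
    ov <- which(b$start < cur_e & b$end > cur_s)
    pos <- cur_s
    for (j in ov) {
      if (b$start[j] > pos) { out_s <- c(out_s, pos); out_e <- c(out_e, b$start[j]) }
      pos <- max(pos, b$end[j])
    }
    if (pos < cur_e) { out_s <- c(out_s, pos); out_e <- c(out_e, cur_e) }
  }
  interval_set(label, out_s, out_e)
}

#' Pad every interval outward by a fixed margin
#'
#' Used to build unassigned transition buffers around state epochs;
#' overlapping padded intervals are merged.
#'
#' @param iset An `interval_set`.
#' @param pad_s Margin in seconds added on both sides.
#' @return An `interval_set`.
#' @export
interval_dilate <- function(iset, pad_s) {
  if (n_intervals(iset) == 0 || pad_s <= 0) return(iset)
  m <- merge_raw_intervals(iset$start - pad_s, iset$end + pad_s)
  interval_set(iset$label, m$start, m$end)
}

#' Merge short gaps, then drop short epochs
#'
#' Cleanup applied after thresholding: gaps shorter than `merge_gap_s` are
#' bridged, then intervals shorter than `min_epoch_s` are removed.
#'
#' @param iset An `interval_set`.
#' @param min_epoch_s Minimum accepted epoch length, seconds.
#' @param merge_gap_s Gaps strictly shorter than this are merged, seconds.
#' @return A cleaned `interval_set`.
#' @export
interval_clean <- function(iset, min_epoch_s = 0.2, merge_gap_s = 0.1) {
  n <- n_intervals(iset)
  if (n == 0) return(iset)
  s <- iset$start; e <- iset$end
  if (n > 1 && merge_gap_s > 0) {
    keep_s <- s[1]; out_s <- numeric(0); out_e <- numeric(0); cur_e <- e[1]
    for (k in 2:n) {
      if (s[k] - cur_e < merge_gap_s) {
        cur_e <- e[k]
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- s[k]; cur_e <- e[k]
      }
    }
    s <- c(out_s, keep_s); e <- c(out_e, cur_e)
  }
  keep <- (e - s) >= min_epoch_s
  interval_set(iset$label, s[keep], e[keep])
}

#' Build an interval set from runs of TRUE in a logical vector
#'
#' Element `i` is taken to cover `[t0_s + (i-1)*dt, t0_s + i*dt)`.
#'
#' @param flag Logical vector.
#' @param t0_s Time of the first element's period start, seconds.
#' @param dt Element period, seconds.
#' @param label Label for the resulting set.
#' @return An `interval_set`.
#' @export
intervals_from_logical <- function(flag, t0_s, dt, label = "state") {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  interval_set(label,
               t0_s + (starts[sel] - 1) * dt,
               t0_s + ends[sel] * dt)
}

#' Jaccard index between two interval sets
#'
#' Ratio of the duration of the intersection to the duration of the union;
#' 1 means identical coverage.
#'
#' @param a,b `interval_set` objects.
#' @return Numeric in `[0, 1]` (`NaN` when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  inter <- interval_total_duration(interval_intersect(a, b))
  uni <- interval_total_duration(interval_union(a, b))
  inter / uni
}

#' Does one interval of the set fully contain a time window?
#'
#' @param iset An `interval_set`.
#' @param start_s,end_s Window `[start_s, end_s)`, seconds.
#' @return `TRUE` when some single interval `[s, e)` satisfies
#'   `s <= start_s` and `end_s <= e`.
#' @export
interval_covers <- function(iset, start_s, end_s) {
  any(iset$start <= start_s & iset$end >= end_s)
}

#' Which points fall inside an interval set?
#'
#' @param iset An `interval_set`.
#' @param t_s Numeric vector of time points, seconds.
#' @return Logical vector: point inside some `[start, end)`.
#' @export
interval_contains <- function(iset, t_s) {
  if (n_intervals(iset) == 0) return(rep(FALSE, length(t_s)))
  idx <- findInterval(t_s, iset$start)
  idx > 0 & t_s < iset$end[pmax(idx, 1L)]
}
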