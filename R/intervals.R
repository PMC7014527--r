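# Interval utilities. Intervals are data.frames with numeric columns
# `start`, `end` in seconds, half-open [start, end). Endpoints are
# real-valued; detector output is sample-aligned but references need not be.

#' Construct a set of time intervals
#'
#' @param start,end numeric vectors of equal length, seconds. Each pair must
#'   satisfy `0 <= start <= end`.
#' @return a data.frame with columns `start`, `end`, sorted by `start`.
#' @export
intervals <- function(start = numeric(), end = numeric()) {
  if (length(start) != length(end))
    stop("start and end must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval endpoints must be finite")
  if (any(start < 0)) stop("interval starts must be >= 0")
  if (any(end < start)) stop("interval end must be >= start")
  out <- data.frame(start = start, end = end)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Coalesce overlapping or abutting intervals
#'
#' Computes the point-set union of a collection of half-open intervals.
#' Overlapping and abutting intervals are merged; the result is sorted and
#' non-overlapping.
#'
#' @param x a data.frame of intervals (columns `start`, `end`).
#' @return a sorted, non-overlapping interval data.frame covering the same
#'   point set.
#' @export
interval_union <- function(x) {
  x <- intervals(x$start, x$end)
  n <- nrow(x)
  if (n <= 1L) return(x)
  s <- x$start; e <- x$end
  out_s <- numeric(n); out_e <- numeric(n)
  k <- 1L; out_s[1L] <- s[1L]; out_e[1L] <- e[1L]
  for (i in 2L:n) {
    if (s[i] <= out_e[k]) {               # overlap or abutment
      if (e[i] > out_e[k]) out_e[k] <- e[i]
    } else {
      k <- k + 1L; out_s[k] <- s[i]; out_e[k] <- e[i]
    }
  }
  data.frame(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

#' Fuse chewing segments from multiple sources
#'
#' Merges per-channel segment lists into one list by taking the union of all
#' intervals, coalescing any overlap between sources (e.g., bilateral EMG
#' channels that detect the same chewing bout).
#'
#' @param lists a list of interval data.frames, one per source/channel.
#' @return a sorted, non-overlapping interval data.frame.
#' @export
fuse_sources <- function(lists) {
  stopifnot(is.list(lists))
  if (length(lists) == 0L) return(intervals())
  interval_union(do.call(rbind, lists))
}

#' Merge temporally close segments (gap elimination)
#'
#' Free-living eating is frequently interrupted (conversation, cutlery use),
#' so one eating occasion appears as several chewing segments. Adjacent
#' segments whose separating gap is strictly smaller than `t_gap` are merged
#' into one eating event.
#'
#' @param x a sorted, non-overlapping interval data.frame.
#' @param t_gap gap threshold in seconds (default 300 s = 5 min).
#' @return interval data.frame whose remaining gaps are all `>= t_gap`.
#'   Covered time never decreases; the operation is idempotent.
#' @export
eliminate_gaps <- function(x, t_gap = 300) {
  stopifnot(is.numeric(t_gap), length(t_gap) == 1L, t_gap >= 0)
  x <- interval_union(x)
  n <- nrow(x)
  if (n <= 1L) return(x)
  s <- x$start; e <- x$end
  out_s <- numeric(n); out_e <- numeric(n)
  k <- 1L; out_s[1L] <- s[1L]; out_e[1L] <- e[1L]
  for (i in 2L:n) {
    if (s[i] - out_e[k] < t_gap) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L; out_s[k] <- s[i]; out_e[k] <- e[i]
    }
  }
  data.frame(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

# total covered time of a non-overlapping interval set
covered_time <- function(x) sum(x$end - x$start)
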