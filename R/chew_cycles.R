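# Chewing-cycle onset detection (Abbink-style EMG onset principle adapted to
# chewing). A window of w samples slides one sample at a time over the
# rectified signal; the conditional count
#   index = #{first half < theta_C} + #{second half > theta_C}
# is maximal (= w) when a muscle contraction starts exactly mid-window, so
# local maxima of the index series above theta_P * w mark chewing-cycle
# onsets.

#' Estimate the burst amplitude threshold from baseline noise
#'
#' The burst threshold separating baseline noise from muscle activity is
#' `mu + 3 * sigma`, where `mu` and `sigma` are the mean and (population)
#' standard deviation of pre-processed baseline (non-eating) samples. With
#' approximately Gaussian baseline noise this puts the threshold beyond the
#' 99th percentile of the rectified noise amplitude.
#'
#' @param baseline numeric vector of pre-processed (rectified) amplitude
#'   samples drawn from non-eating portions of training data.
#' @return the scalar threshold `theta_C`.
#' @export
estimate_burst_threshold <- function(baseline) {
  baseline <- as.numeric(baseline)
  if (length(baseline) == 0L) stop("empty baseline")
  mu <- mean(baseline)
  sigma <- sqrt(mean((baseline - mu)^2))
  mu + 3 * sigma
}

# theta_C from pooled first/second moments (used by LOPO folds, where
# per-participant baseline moments are pre-computed once).
threshold_from_moments <- function(n, s1, s2) {
  mu <- s1 / n
  mu + 3 * sqrt(pmax(s2 / n - mu^2, 0))
}

#' Compute the windowed conditional-count index series
#'
#' Slides a window of `w` samples one sample at a time and counts samples
#' below `theta_C` in the first half-window plus samples above `theta_C` in
#' the second half-window. The count is maintained incrementally (O(1) per
#' step) and is identical to a per-window recount.
#'
#' @param x pre-processed (rectified) amplitude sequence, length > `w`.
#' @param w window length in samples; even, >= 2.
#' @param theta_C burst amplitude threshold (same units as `x`).
#' @return an object of class `index_series`: list with integer `values`
#'   (one per window position, each in `[0, w]`), `offset` (sample index of
#'   the first window start, always 1) and `w`.
#' @export
compute_index_series <- function(x, w, theta_C) {
  w <- as.integer(w)
  if (w < 2L || w %% 2L != 0L) stop("w must be an even integer >= 2")
  if (length(x) <= w) stop("signal must be longer than w")
  vals <- index_series_cpp(as.numeric(x), w, theta_C)
  structure(list(values = vals, offset = 1L, w = w), class = "index_series")
}

#' Detect chewing-cycle onsets from an index series
#'
#' Onsets are strict local maxima of the index series exceeding
#' `theta_P * w`. After an accepted onset the scan skips
#' `round(t_interval * fs)` positions, enforcing the physiological minimum
#' spacing between chewing cycles. Each onset is reported at the centre of
#' its window (window start + `w/2`), the below/above transition point where
#' the contraction starts.
#'
#' @param I an `index_series` from [compute_index_series()].
#' @param theta_P peak threshold fraction in `[0, 1]` (default 0.7).
#' @param t_interval minimum onset spacing in seconds (default 1/3 s).
#' @param fs sampling rate in Hz.
#' @return an object of class `onset_list`: strictly increasing integer
#'   sample indices (1-based) with attributes `fs` and `channel`.
#' @export
detect_onsets <- function(I, theta_P = 0.7, t_interval = 1 / 3, fs) {
  stopifnot(inherits(I, "index_series"))
  if (theta_P < 0 || theta_P > 1) stop("theta_P must lie in [0, 1]")
  if (t_interval <= 0) stop("t_interval must be positive")
  skip <- as.integer(round(t_interval * fs))
  pos <- onset_scan_cpp(I$values, theta_P * I$w, skip)   # 0-based in I
  onsets <- pos + I$offset + I$w %/% 2L
  structure(as.integer(onsets), class = "onset_list", fs = fs, channel = NA)
}

#' @export
print.onset_list <- function(x, ...) {
  cat(sprintf("Chewing-cycle onsets: %d onset(s)", length(x)))
  ch <- attr(x, "channel")
  if (!is.na(ch)) cat(sprintf(" [channel %s]", ch))
  cat("\n")
  invisible(x)
}

#' Onset times in seconds
#' @param onsets an `onset_list` (1-based sample indices).
#' @param fs sampling rate in Hz; defaults to the list's `fs` attribute.
#' @export
onset_times <- function(onsets, fs = attr(onsets, "fs")) {
  (as.numeric(onsets) - 1) / fs
}

#' Detect chewing cycles on every channel of a pre-processed recording
#'
#' @param xp a `preprocessed_emg` from [preprocess()].
#' @param theta_C burst amplitude threshold, shared across channels
#'   (estimated once from pooled non-eating training data, see
#'   [estimate_burst_threshold()]).
#' @param w window length in samples (default 100, i.e., 0.4 s at 256 Hz —
#'   no longer than one chewing cycle, whose rate spans roughly
#'   0.94–2.17 Hz).
#' @param theta_P peak threshold fraction (default 0.7).
#' @param t_interval minimum onset spacing in seconds (default 1/3 s).
#' @return a list of `onset_list` objects, one per channel.
#' @export
detect_chewing_cycles <- function(xp, theta_C, w = 100L, theta_P = 0.7,
                                  t_interval = 1 / 3) {
  stopifnot(inherits(xp, "preprocessed_emg"))
  out <- lapply(seq_len(ncol(xp$values)), function(ch) {
    I <- compute_index_series(xp$values[, ch], w, theta_C)
    on <- detect_onsets(I, theta_P, t_interval, xp$fs)
    attr(on, "channel") <- xp$channel_ids[ch]
    on
  })
  names(out) <- xp$channel_ids
  out
}
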