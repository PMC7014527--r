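# Bottom-up chewing-segment detection: eating is inferred from the temporal
# density of detected chewing-cycle onsets. A window of w0 seconds is anchored
# at each onset (step = one onset); the onset count in the window is the
# chewing-cycle frequency f[j]. Runs with f >= theta_0 form chewing segments.

onset_freq_all <- function(t, w0) {
  # f[j] = #{onsets in [t_j, t_j + w0]}, closed on both ends
  if (length(t) == 0L) return(integer())
  findInterval(t + w0, t) - seq_along(t) + 1L
}

#' Chewing-cycle frequency at one onset
#'
#' Counts the onsets falling in the closed window `[C[j], C[j] + w0]`
#' anchored at onset `j`. The count always includes the anchor onset itself,
#' so it is at least 1.
#'
#' @param C an `onset_list` (1-based sample indices) or numeric onset sample
#'   indices.
#' @param j onset index (1-based).
#' @param w0 window length in seconds.
#' @param fs sampling rate in Hz.
#' @return integer onset count.
#' @export
onset_frequency <- function(C, j, w0, fs = attr(C, "fs")) {
  t <- (as.numeric(C) - 1) / fs
  if (j < 1L || j > length(t)) stop("onset index out of range")
  sum(t >= t[j] & t <= t[j] + w0)
}

#' Detect chewing segments from onset density
#'
#' A segment starts at the first onset `j` (at the list start or after the
#' previous segment) whose chewing-cycle frequency `f[j] >= theta_0`. It ends
#' at onset `jend + theta_0 - 1` where `f[jend] == theta_0` and
#' `f[jend + theta_0 - 1] == 1` — i.e., the closing onset is the only onset
#' left in its own window. If the onset list ends before the end rule fires,
#' the segment is closed at the last onset. Every returned boundary is the
#' time of an onset in `C`, and every segment contains at least `theta_0`
#' onsets.
#'
#' @param C an `onset_list` or numeric vector of strictly increasing 1-based
#'   onset sample indices.
#' @param w0 window length in seconds.
#' @param theta_0 minimum onset count (integer >= 2).
#' @param fs sampling rate in Hz.
#' @return an interval data.frame of chewing segments (seconds).
#' @export
detect_segments <- function(C, w0, theta_0, fs = attr(C, "fs")) {
  stopifnot(w0 > 0, theta_0 >= 2)
  theta_0 <- as.integer(theta_0)
  C <- as.numeric(C)
  K <- length(C)
  if (K == 0L) return(intervals())
  if (any(diff(C) <= 0)) stop("onsets must be strictly increasing")
  t <- (C - 1) / fs
  f <- onset_freq_all(t, w0)
  starts <- numeric(); ends <- numeric()
  j <- 1L
  while (j <= K) {
    if (f[j] >= theta_0) {
      js <- j
      je <- NA_integer_
      jj <- js
      while (jj + theta_0 - 1L <= K) {
        if (f[jj] == theta_0 && f[jj + theta_0 - 1L] == 1L) {
          je <- jj + theta_0 - 1L
          break
        }
        jj <- jj + 1L
      }
      if (is.na(je)) je <- K          # recording ended mid-segment
      starts <- c(starts, t[js]); ends <- c(ends, t[je])
      j <- je + 1L
    } else {
      j <- j + 1L
    }
  }
  intervals(starts, ends)
}

#' Bottom-up eating-event detection pipeline
#'
#' Runs the full bottom-up pipeline on a raw recording: pre-processing
#' ([preprocess()]), per-channel chewing-cycle onset detection
#' ([detect_chewing_cycles()]), per-channel chewing-segment detection
#' ([detect_segments()]), multi-source fusion ([fuse_sources()]) and gap
#' elimination ([eliminate_gaps()]).
#'
#' `theta_C` should be estimated from non-eating training data
#' ([estimate_burst_threshold()]). If omitted it is estimated from the whole
#' recording, which is acceptable only when eating occupies a small fraction
#' of the recording (a warning is raised).
#'
#' @param rec an [emg_recording()].
#' @param w0 segment window length in seconds (grid-searched; no default).
#' @param theta_0 minimum onset count per window (grid-searched).
#' @param theta_C burst amplitude threshold; see Details.
#' @param w,theta_P,t_interval chewing-cycle detection parameters
#'   (see [detect_chewing_cycles()]).
#' @param t_gap gap-elimination threshold in seconds (default 300).
#' @param fnf,fhpf pre-processing parameters (see [preprocess()]).
#' @return an object of class `eating_detection` with elements `events`
#'   (interval data.frame), `algo`, `params`, `channel_segments`, `onsets`,
#'   `theta_C`, `fs`, `duration`.
#' @export
detect_eating_bottom_up <- function(rec, w0, theta_0, theta_C = NULL,
                                    w = 100L, theta_P = 0.7,
                                    t_interval = 1 / 3, t_gap = 300,
                                    fnf = 50, fhpf = 20) {
  stopifnot(inherits(rec, "emg_recording"))
  xp <- preprocess(rec, fnf = fnf, fhpf = fhpf)
  if (is.null(theta_C)) {
    warning("theta_C not supplied; estimating from the whole recording")
    theta_C <- estimate_burst_threshold(as.numeric(xp$values))
  }
  onsets <- detect_chewing_cycles(xp, theta_C, w = w, theta_P = theta_P,
                                  t_interval = t_interval)
  segs <- lapply(onsets, detect_segments, w0 = w0, theta_0 = theta_0,
                 fs = rec$fs)
  events <- eliminate_gaps(fuse_sources(segs), t_gap)
  new_eating_detection(events, "bottom-up",
                       params = list(w0 = w0, theta_0 = theta_0, w = w,
                                     theta_P = theta_P,
                                     t_interval = t_interval, t_gap = t_gap,
                                     fnf = fnf, fhpf = fhpf),
                       rec = rec, channel_segments = segs, onsets = onsets,
                       theta_C = theta_C)
}
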