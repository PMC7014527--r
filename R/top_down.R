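# Top-down baselines. Both classify fixed windows of the pre-processed
# signal as chewing/non-chewing and share the fusion and gap-elimination
# stages with the bottom-up pipeline.

#' EMG work of a window
#'
#' EMG work is the sum of rectified EMG sample amplitudes within a window —
#' the chewing-intensity feature of the threshold baseline.
#'
#' @param x non-empty numeric vector of rectified samples.
#' @return scalar sum.
#' @export
emg_work <- function(x) {
  if (length(x) == 0L) stop("empty window")
  sum(x)
}

#' Threshold-based top-down chewing-segment detection
#'
#' Slides a window of `w1` samples with step `s1` over each pre-processed
#' channel and computes the EMG work `F`. A segment start is recorded at
#' window position `i` when `F` crosses above `theta_1`
#' (`F_previous < theta_1` and `F_current > theta_1`); a segment end is
#' recorded at `i + s1` when `F` crosses below (`F_current > theta_1` and
#' `F_next < theta_1`). Crossings are paired greedily in temporal order; an
#' end without a preceding start is dropped, and a trailing open start is
#' closed at the last evaluated window.
#'
#' @param xp a `preprocessed_emg`.
#' @param w1 window length in samples.
#' @param s1 step in samples (default 256 = 1 s at 256 Hz); `w1 >= s1 >= 1`.
#' @param theta_1 EMG-work threshold (amplitude x samples, > 0).
#' @return a list of interval data.frames (seconds), one per channel.
#' @export
detect_segments_threshold <- function(xp, w1, s1 = 256L, theta_1) {
  stopifnot(inherits(xp, "preprocessed_emg"))
  w1 <- as.integer(w1); s1 <- as.integer(s1)
  if (!(w1 >= s1 && s1 >= 1L)) stop("need w1 >= s1 >= 1")
  if (theta_1 <= 0) stop("theta_1 must be positive")
  n <- nrow(xp$values)
  if (n < w1 + 2L * s1) stop("signal shorter than w1 + 2*s1")
  fs <- xp$fs
  out <- lapply(seq_len(ncol(xp$values)), function(ch) {
    x <- xp$values[, ch]
    cs <- c(0, cumsum(x))
    wsum <- function(i0) cs[i0 + w1 + 1L] - cs[i0 + 1L]  # window [i0, i0+w1), 0-based
    pos <- seq.int(s1, n - w1 - 1L, by = s1)             # evaluated positions
    if (length(pos) == 0L) return(intervals())
    f_cur <- wsum(pos)
    f_prev <- wsum(pos - s1)
    f_next <- wsum(pos + s1)
    start_t <- pos[f_prev < theta_1 & f_cur > theta_1] / fs
    end_t <- (pos[f_cur > theta_1 & f_next < theta_1] + s1) / fs
    # greedy pairing in temporal order
    ev <- rbind(data.frame(t = start_t, type = rep(1L, length(start_t))),
                data.frame(t = end_t, type = rep(2L, length(end_t))))
    ev <- ev[order(ev$t, ev$type), , drop = FALSE]
    starts <- numeric(); ends <- numeric(); open <- NA_real_
    for (r in seq_len(nrow(ev))) {
      if (ev$type[r] == 1L) {
        if (is.na(open)) open <- ev$t[r]
      } else if (!is.na(open)) {
        starts <- c(starts, open); ends <- c(ends, ev$t[r]); open <- NA_real_
      }                                   # end without start: dropped
    }
    if (!is.na(open)) {                   # close at last evaluated window
      starts <- c(starts, open)
      ends <- c(ends, (pos[length(pos)] + s1) / fs)
    }
    intervals(starts, ends)
  })
  names(out) <- xp$channel_ids
  out
}

#' Threshold-based top-down eating-event detection pipeline
#'
#' @inheritParams detect_eating_bottom_up
#' @param w1,s1,theta_1 see [detect_segments_threshold()].
#' @return an `eating_detection` object.
#' @export
detect_eating_threshold <- function(rec, w1, theta_1, s1 = 256L, t_gap = 300,
                                    fnf = 50, fhpf = 20) {
  stopifnot(inherits(rec, "emg_recording"))
  xp <- preprocess(rec, fnf = fnf, fhpf = fhpf)
  segs <- detect_segments_threshold(xp, w1 = w1, s1 = s1, theta_1 = theta_1)
  events <- eliminate_gaps(fuse_sources(segs), t_gap)
  new_eating_detection(events, "threshold",
                       params = list(w1 = w1, s1 = s1, theta_1 = theta_1,
                                     t_gap = t_gap, fnf = fnf, fhpf = fhpf),
                       rec = rec, channel_segments = segs)
}

# ---- windowed one-class SVM baseline ---------------------------------------

#' Extract per-window features for the one-class SVM
#'
#' Applies a non-overlapping window of `w2` samples to each pre-processed
#' channel and computes an 8-dimensional feature vector per window: mean,
#' standard deviation, maximum, EMG work, fraction of samples above
#' `theta_C`, spectral centroid (Hz), and relative band power in 20–60 Hz
#' and 60–120 Hz. Feature standardisation happens at training time with
#' training-set statistics (see [train_ocsvm()]).
#'
#' @param xp a `preprocessed_emg`.
#' @param w2 window length in samples (>= 4).
#' @param theta_C burst amplitude threshold used by the above-threshold-rate
#'   feature.
#' @return a list with `features` (windows x 8 matrix, channels stacked),
#'   `channel` (channel index per row), `start` (0-based start sample per
#'   window), `w2`, `fs`.
#' @export
extract_window_features <- function(xp, w2, theta_C) {
  stopifnot(inherits(xp, "preprocessed_emg"))
  w2 <- as.integer(w2)
  if (w2 < 4L) stop("w2 must be >= 4 samples")
  n <- nrow(xp$values)
  nw <- n %/% w2
  if (nw < 1L) stop("signal shorter than one window")
  fs <- xp$fs
  freqs <- (seq_len(w2 %/% 2L)) * fs / w2          # positive FFT bins
  b1 <- freqs >= 20 & freqs < 60
  b2 <- freqs >= 60 & freqs <= 120
  feat_one <- function(x) {
    p <- Mod(fft(x - mean(x))[2L:(w2 %/% 2L + 1L)])^2
    ptot <- sum(p)
    c(mean = mean(x),
      sd = sd(x),
      max = max(x),
      work = sum(x),
      above_rate = mean(x > theta_C),
      centroid = if (ptot > 0) sum(freqs * p) / ptot else 0,
      bp_20_60 = if (ptot > 0) sum(p[b1]) / ptot else 0,
      bp_60_120 = if (ptot > 0) sum(p[b2]) / ptot else 0)
  }
  rows <- list(); chan <- integer(); start <- integer()
  for (ch in seq_len(ncol(xp$values))) {
    x <- xp$values[, ch]
    m <- matrix(x[seq_len(nw * w2)], nrow = w2)
    fm <- t(apply(m, 2, feat_one))
    rows[[ch]] <- fm
    chan <- c(chan, rep.int(ch, nw))
    start <- c(start, (seq_len(nw) - 1L) * w2)
  }
  feats <- do.call(rbind, rows)
  if (any(!is.finite(feats))) stop("non-finite window feature")
  list(features = feats, channel = chan, start = start, w2 = w2, fs = fs)
}

#' Train a one-class SVM on eating-labelled windows
#'
#' Fits an RBF-kernel one-class SVM (novelty detector) on window features
#' from eating-labelled training windows. Features are standardised with the
#' training-set mean and standard deviation; the standardisation is stored in
#' the model and re-applied at prediction time. `nu` upper-bounds the
#' fraction of training windows on the margin-error side.
#'
#' @param features numeric matrix of training window features (rows =
#'   eating-labelled windows), at least 10 rows.
#' @param gamma RBF kernel width (> 0).
#' @param nu margin-error bound in (0, 1].
#' @return an object of class `ocsvm_model`.
#' @export
train_ocsvm <- function(features, gamma, nu) {
  features <- as.matrix(features)
  if (nrow(features) < 10L) stop("need at least 10 training windows")
  if (gamma <= 0) stop("gamma must be positive")
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]")
  center <- colMeans(features)
  scale <- apply(features, 2, sd)
  if (all(scale < 1e-12)) stop("degenerate (constant) training features")
  scale[scale < 1e-12] <- 1
  z <- sweep(sweep(features, 2, center), 2, scale, "/")
  fit <- e1071::svm(z, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = gamma, nu = nu, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale,
                 gamma = gamma, nu = nu), class = "ocsvm_model")
}

#' @export
print.ocsvm_model <- function(x, ...) {
  cat(sprintf("One-class SVM (RBF): gamma=%g, nu=%g, %d support vector(s)\n",
              x$gamma, x$nu, x$fit$tot.nSV))
  invisible(x)
}

#' Predict inlier (eating) windows with a trained one-class SVM
#'
#' @param object an `ocsvm_model`.
#' @param newdata feature matrix as produced by [extract_window_features()].
#' @param ... unused.
#' @return logical vector, `TRUE` = inlier (eating).
#' @export
predict.ocsvm_model <- function(object, newdata, ...) {
  z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  as.logical(predict(object$fit, z))
}

#' One-class-SVM top-down chewing-segment detection
#'
#' Classifies each non-overlapping `w2`-sample window as eating (inlier) or
#' non-eating (outlier) and merges consecutive inlier windows into segments.
#' All segment boundaries are integer multiples of `w2` samples — the
#' structural reason this baseline incurs larger timing errors than the
#' bottom-up detector.
#'
#' @param xp a `preprocessed_emg`.
#' @param model a trained `ocsvm_model`.
#' @param w2 window length in samples (must match the training windows).
#' @param theta_C threshold used by the above-threshold-rate feature.
#' @return a list of interval data.frames (seconds), one per channel.
#' @export
detect_segments_ocsvm <- function(xp, model, w2, theta_C) {
  stopifnot(inherits(model, "ocsvm_model"))
  fe <- extract_window_features(xp, w2, theta_C)
  inlier <- predict(model, fe$features)
  fs <- xp$fs
  out <- lapply(seq_len(ncol(xp$values)), function(ch) {
    sel <- fe$channel == ch
    flag <- inlier[sel]
    st <- fe$start[sel]
    if (!any(flag)) return(intervals())
    r <- rle(flag)
    endi <- cumsum(r$lengths); starti <- endi - r$lengths + 1L
    keep <- r$values
    intervals(st[starti[keep]] / fs,
              (st[endi[keep]] + w2) / fs)
  })
  names(out) <- xp$channel_ids
  out
}

#' One-class-SVM top-down eating-event detection pipeline
#'
#' @inheritParams detect_eating_bottom_up
#' @param model a trained `ocsvm_model` (see [train_ocsvm()]).
#' @param w2 window length in samples.
#' @param theta_C threshold for the above-threshold-rate feature; if `NULL`,
#'   estimated from the whole recording.
#' @return an `eating_detection` object.
#' @export
detect_eating_ocsvm <- function(rec, model, w2, theta_C = NULL, t_gap = 300,
                                fnf = 50, fhpf = 20) {
  stopifnot(inherits(rec, "emg_recording"))
  xp <- preprocess(rec, fnf = fnf, fhpf = fhpf)
  if (is.null(theta_C))
    theta_C <- estimate_burst_threshold(as.numeric(xp$values))
  segs <- detect_segments_ocsvm(xp, model, w2, theta_C)
  events <- eliminate_gaps(fuse_sources(segs), t_gap)
  new_eating_detection(events, "ocsvm",
                       params = list(w2 = w2, gamma = model$gamma,
                                     nu = model$nu, t_gap = t_gap,
                                     fnf = fnf, fhpf = fhpf),
                       rec = rec, channel_segments = segs, theta_C = theta_C)
}
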