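# The eating_detection result object and its methods, plus the algorithm
# dispatch wrapper.

new_eating_detection <- function(events, algo, params, rec,
                                 channel_segments = NULL, onsets = NULL,
                                 theta_C = NULL) {
  structure(list(events = events, algo = algo, params = params,
                 channel_segments = channel_segments, onsets = onsets,
                 theta_C = theta_C, fs = rec$fs,
                 duration = recording_duration(rec)),
            class = "eating_detection")
}

#' Detect eating events in an EMG recording
#'
#' Dispatches to one of the three detection pipelines: `"bottom-up"`
#' (chewing-cycle density, [detect_eating_bottom_up()]), `"threshold"`
#' (EMG-work sliding window, [detect_eating_threshold()]) or `"ocsvm"`
#' (windowed one-class SVM, [detect_eating_ocsvm()]).
#'
#' @param rec an [emg_recording()].
#' @param algo algorithm id.
#' @param ... parameters passed to the selected pipeline.
#' @return an `eating_detection` object.
#' @export
detect_eating <- function(rec, algo = c("bottom-up", "threshold", "ocsvm"),
                          ...) {
  algo <- match.arg(algo)
  switch(algo,
         "bottom-up" = detect_eating_bottom_up(rec, ...),
         "threshold" = detect_eating_threshold(rec, ...),
         "ocsvm"     = detect_eating_ocsvm(rec, ...))
}

#' @export
print.eating_detection <- function(x, ...) {
  cat(sprintf("Eating-event detection (%s): %d event(s) in %.1f s of data\n",
              x$algo, nrow(x$events), x$duration))
  if (nrow(x$events)) {
    df <- x$events
    df$duration <- df$end - df$start
    print.data.frame(round(df, 2), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.eating_detection <- function(object, ...) {
  ev <- object$events
  cat(sprintf("Algorithm: %s\n", object$algo))
  cat(sprintf("Recording: %.1f s @ %g Hz\n", object$duration, object$fs))
  cat(sprintf("Detected events: %d (%.1f s eating, %.2f%% of recording)\n",
              nrow(ev), covered_time(ev),
              100 * covered_time(ev) / object$duration))
  if (!is.null(object$onsets)) {
    n_on <- vapply(object$onsets, length, integer(1))
    cat(sprintf("Chewing-cycle onsets per channel: %s\n",
                paste(sprintf("%s=%d", names(n_on), n_on), collapse = ", ")))
  }
  if (!is.null(object$theta_C))
    cat(sprintf("Burst threshold theta_C: %.4g\n", object$theta_C))
  cat("Parameters: ",
      paste(sprintf("%s=%s", names(object$params),
                    vapply(object$params, function(p)
                      format(p, digits = 4), "")), collapse = ", "), "\n")
  invisible(object)
}

#' Plot detected eating events along the recording timeline
#'
#' Draws detected events as shaded bands and, when supplied, reference events
#' as outlined bands above, giving a quick visual of retrieval and timing
#' agreement.
#'
#' @param x an `eating_detection` object.
#' @param reference optional [event_reference()] to overlay.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.eating_detection <- function(x, reference = NULL, ...) {
  plot(NA, xlim = c(0, x$duration), ylim = c(0, 2.4), yaxt = "n",
       xlab = "time [s]", ylab = "",
       main = sprintf("Eating events (%s)", x$algo), ...)
  axis(2, at = c(0.5, 1.7), labels = c("detected", "reference"), las = 1)
  if (nrow(x$events))
    rect(x$events$start, 0.1, x$events$end, 0.9, col = "steelblue",
         border = NA)
  if (!is.null(reference) && nrow(reference))
    rect(reference$start, 1.3, reference$end, 2.1, col = "grey80",
         border = "grey40")
  invisible(x)
}
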