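# Recording / annotation I-O and the shared time conventions.
#
# Sample index i (1-based) <-> time (i - 1) / fs seconds. All event times are
# seconds relative to recording start; intervals are half-open [start, end).

#' Construct a multi-channel EMG recording
#'
#' @param samples numeric matrix (samples x channels) or a list/data.frame of
#'   equal-length numeric channel vectors.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_ids optional character labels, one per channel.
#' @param t0 recording start time in seconds (default 0); all package times
#'   are relative to recording start, `t0` is metadata only.
#' @return an object of class `emg_recording` with elements `samples`
#'   (matrix), `fs`, `channel_ids`, `t0`.
#' @export
emg_recording <- function(samples, fs, channel_ids = NULL, t0 = 0) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (is.list(samples)) {
    len <- vapply(samples, length, integer(1))
    if (length(unique(len)) > 1L)
      stop("all channels must have the same length")
    samples <- do.call(cbind, lapply(samples, as.numeric))
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number")
  if (ncol(samples) < 1L) stop("recording needs at least one channel")
  if (is.null(channel_ids)) {
    channel_ids <- colnames(samples)
    if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_ids) != ncol(samples))
    stop("channel_ids must match the number of channels")
  colnames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs,
                 channel_ids = as.character(channel_ids), t0 = t0),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d channel(s) [%s], %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), paste(x$channel_ids, collapse = ", "),
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `emg_recording`.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Read a multi-channel recording from CSV or EDF
#'
#' The CSV dialect is one column per channel with an optional header and an
#' optional time column (named `time`, `t` or `time_s`, dropped on read); the
#' sampling rate must then be supplied via `fs`. EDF files carry their own
#' sampling rate and channel labels.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guesses from the file extension.
#' @param fs sampling rate in Hz, required for CSV input.
#' @return an [emg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(read_edf(path))
  if (is.null(fs)) stop("fs must be supplied for CSV recordings (config error)")
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-+0-9.eE, \t]*$", first)
  df <- read.csv(path, header = has_header, fill = TRUE)
  tcol <- tolower(names(df)) %in% c("time", "t", "time_s")
  if (has_header && any(tcol)) df <- df[, !tcol, drop = FALSE]
  if (!all(vapply(df, is.numeric, logical(1))) || anyNA(df))
    stop("format error: recording CSV has non-numeric or ragged columns")
  emg_recording(df, fs = fs,
                channel_ids = if (has_header) names(df) else NULL)
}

#' Construct an eating-event reference
#'
#' @param start,end event start/end times in seconds. Events must be
#'   non-overlapping; they are sorted by start.
#' @return an object of class `event_reference`: an interval data.frame with
#'   attribute `P` (event count).
#' @export
event_reference <- function(start = numeric(), end = numeric()) {
  x <- intervals(start, end)
  if (nrow(x) > 1L && any(x$start[-1L] < x$end[-nrow(x)]))
    stop("validation error: reference events overlap")
  class(x) <- c("event_reference", "data.frame")
  x
}

#' @export
print.event_reference <- function(x, ...) {
  cat(sprintf("Eating-event reference: %d event(s), %.1f s total\n",
              nrow(x), sum(x$end - x$start)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read an eating-event annotation table
#'
#' Expects a CSV with header columns `start_s,end_s` (seconds). Events are
#' validated (start <= end, no overlap) and sorted.
#'
#' @param path file path.
#' @return an [event_reference()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df)))
    stop("annotation CSV must have columns start_s,end_s")
  event_reference(df$start_s, df$end_s)
}

#' Write detected events to an annotation CSV
#'
#' Writes `start_s,end_s` rows that round-trip losslessly through
#' [read_annotations()] at 1/fs resolution.
#'
#' @param events an interval data.frame (e.g., detected eating events).
#' @param path output file path.
#' @export
write_events <- function(events, path) {
  ev <- intervals(events$start, events$end)
  df <- data.frame(start_s = format(ev$start, digits = 15, trim = TRUE),
                   end_s = format(ev$end, digits = 15, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detector/pipeline configuration from YAML
#'
#' Keys mirror the parameter names used throughout the package (`fnf`,
#' `fhpf`, `w`, `theta_C`, `theta_P`, `t_interval`, `w0`, `theta_0`, `t_gap`,
#' `w1`, `s1`, `theta_1`, `w2`, `gamma`, `nu`, `fs`). Missing keys fall back
#' to [default_params()]; grid-searched parameters (`w0`, `theta_0`, `w1`,
#' `theta_1`, `w2`, `gamma`, `nu`) have no defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a named list of parameters.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_params()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

#' Default pipeline parameters
#'
#' Fixed parameters of the detection pipelines: notch at 50 Hz, high-pass at
#' 20 Hz, onset window `w` = 100 samples (0.4 s at 256 Hz), peak threshold
#' `theta_P` = 0.7, onset refractory interval 1/3 s, top-down step `s1` = 256
#' samples, gap-elimination threshold 300 s. Parameters normally chosen by
#' grid search (`w0`, `theta_0`, `w1`, `theta_1`, `w2`, `gamma`, `nu`) are
#' deliberately absent.
#'
#' @return a named list.
#' @export
default_params <- function() {
  list(fs = 256, fnf = 50, fhpf = 20,
       w = 100L, theta_P = 0.7, t_interval = 1 / 3, theta_C = NULL,
       t_gap = 300, s1 = 256L)
}
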