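# Minimal EDF (European Data Format) support: continuous 16-bit recordings
# with one common sampling rate, which covers wearable EMG exports. Reading
# is the supported surface; the writer exists for round-trip testing and
# simple exports.

edf_ascii <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  trimws(raw)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  edf_ascii(con, 8)                       # version
  edf_ascii(con, 80); edf_ascii(con, 80)  # patient / recording id
  edf_ascii(con, 8); edf_ascii(con, 8)    # start date / time
  edf_ascii(con, 8)                       # header byte count
  edf_ascii(con, 44)                      # reserved
  n_rec <- as.integer(edf_ascii(con, 8))
  rec_dur <- as.numeric(edf_ascii(con, 8))
  ns <- as.integer(edf_ascii(con, 4))
  if (is.na(ns) || ns < 1L) stop("format error: invalid EDF header")
  fld <- function(width) vapply(seq_len(ns), function(i) edf_ascii(con, width), "")
  labels <- fld(16)
  fld(80); fld(8)                          # transducer, physical dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                  # prefiltering
  spr <- as.integer(fld(8))                # samples per record
  fld(32)                                  # reserved
  if (length(unique(spr)) != 1L)
    stop("format error: channels with differing sampling rates")
  if (rec_dur <= 0) stop("format error: non-positive record duration")
  fs <- spr[1L] / rec_dur
  dat <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dat) != n_rec * sum(spr))
    stop("format error: truncated EDF data section")
  out <- matrix(0, nrow = n_rec * spr[1L], ncol = ns)
  idx <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- dat[(idx + 1L):(idx + spr[s])]
      out[((r - 1L) * spr[s] + 1L):(r * spr[s]), s] <-
        (seg - dig_min[s]) * (phys_max[s] - phys_min[s]) /
          (dig_max[s] - dig_min[s]) + phys_min[s]
      idx <- idx + spr[s]
    }
  }
  emg_recording(out, fs = fs, channel_ids = labels)
}

edf_field <- function(x, width) {
  x <- as.character(x)
  vapply(x, function(s) {
    s <- substr(s, 1L, width)
    formatC(s, width = width, flag = "-")
  }, "", USE.NAMES = FALSE)
}

# Internal EDF writer (continuous, int16, record duration 1 s). fs must be a
# positive integer and the recording is truncated to whole seconds.
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- as.integer(round(rec$fs))
  if (fs <= 0 || abs(fs - rec$fs) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  ns <- ncol(rec$samples)
  n_rec <- nrow(rec$samples) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record")
  x <- rec$samples[seq_len(n_rec * fs), , drop = FALSE]
  phys_min <- apply(x, 2, min); phys_max <- apply(x, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(paste(edf_field(s, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("chewdet export", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(as.character(256L * (1L + ns)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  wr(rec$channel_ids, 16)
  wr(rep("", ns), 80); wr(rep("uV", ns), 8)
  wr(formatC(phys_min, digits = 6, format = "g"), 8)
  wr(formatC(phys_max, digits = 6, format = "g"), 8)
  wr(rep(as.character(dig_min), ns), 8); wr(rep(as.character(dig_max), ns), 8)
  wr(rep("", ns), 80); wr(rep(as.character(fs), ns), 8); wr(rep("", ns), 32)
  dig <- matrix(0L, nrow = nrow(x), ncol = ns)
  for (s in seq_len(ns)) {
    dig[, s] <- as.integer(round((x[, s] - phys_min[s]) /
      (phys_max[s] - phys_min[s]) * (dig_max - dig_min) + dig_min))
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns))
      writeBin(dig[rows, s], con, size = 2L, endian = "little")
  }
  invisible(path)
}
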