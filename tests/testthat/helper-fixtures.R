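# Small in-code fixtures shared across test files.

# noisy band-limited burst train on a quiet baseline: bursts of `burst_dur`
# seconds at `rate` Hz, amplitude `amp`, baseline sigma `sigma`
burst_train <- function(duration, rate, fs = 256, amp = 8, sigma = 1,
                        burst_dur = 0.28, seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  starts <- seq(0.5, duration - burst_dur - 0.5, by = 1 / rate)
  L <- round(burst_dur * fs)
  win <- chewdet:::tukey_window(L, 0.3)
  env <- numeric(n)
  for (t0 in starts) {
    i0 <- round(t0 * fs) + 1L
    env[i0:(i0 + L - 1L)] <- amp * win
  }
  bp <- signal::butter(2, c(20, 120) / (fs / 2), type = "pass")
  band <- as.numeric(signal::filter(bp, rnorm(n)))
  band <- band / sd(band)
  list(x = sigma * rnorm(n) + env * band, starts = starts, fs = fs, env = env)
}

# small fast synthetic configuration for unit tests (short recording, close
# events allowed, no grinding unless asked)
quick_cfg <- function(duration = 900, n_events = 2, seed = 7, ...) {
  synth_config(duration = duration, n_events = n_events,
               event_duration_range = c(40, 80), min_event_gap = 120,
               grind_rate = 0, seed = seed, ...)
}

ref_of <- function(sim) sim$truth$reference
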