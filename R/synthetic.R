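# Synthetic two-channel temporalis-EMG generator with chew-accurate ground
# truth. Emulates the structure of free-living chewing EMG: Gaussian baseline
# noise, short band-limited chewing bursts recurring quasi-periodically
# within eating events, 50 Hz power-line hum, slow baseline wander, and
# short aperiodic low-amplitude teeth-grinding confounders in non-eating
# time. It does not attempt physiologically detailed motor-unit simulation.

#' Synthetic-recording configuration
#'
#' Default values describe the study conditions the generator emulates: a
#' 2-hour, two-channel 256 Hz recording with 3 eating events whose chewing
#' rates are drawn from 0.94–2.17 Hz, eating occupying roughly 6% of the
#' recording, plus 50 Hz hum, baseline wander and occasional teeth-grinding
#' activations (at most a handful of consecutive, lower-amplitude bursts) in
#' non-eating time.
#'
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param n_channels number of EMG channels (bilateral recording: 2).
#' @param n_events number of eating events.
#' @param event_duration_range event duration range in seconds.
#' @param chew_rate_range chewing-cycle rate range in Hz.
#' @param burst_duration chewing-burst duration in seconds.
#' @param burst_band chewing-burst frequency band in Hz.
#' @param burst_snr ratio of burst envelope amplitude to baseline sigma.
#' @param baseline_sigma standard deviation of baseline Gaussian noise
#'   (arbitrary amplitude units).
#' @param hum_amplitude 50 Hz power-line interference amplitude.
#' @param drift_amplitude baseline-wander amplitude.
#' @param pause_prob probability that an event contains a chewing pause
#'   (conversation-style interrupt).
#' @param pause_duration_range pause duration range in seconds (shorter than
#'   the 300 s gap-elimination threshold, so pauses stay within one event).
#' @param grind_rate teeth-grinding episodes per hour of non-eating time.
#' @param grind_max_act maximum consecutive grinding activations (< 5).
#' @param grind_amp_frac grinding amplitude as a fraction of chew amplitude.
#' @param chew_cv coefficient of variation of inter-chew intervals within an
#'   event (quasi-periodicity).
#' @param channel_jitter maximum inter-channel burst-time jitter in seconds
#'   (< 30 ms; bilateral channels see the same chew slightly offset).
#' @param annotation_jitter journal-annotation jitter in seconds (emulating
#'   1-min-resolution self-report diaries).
#' @param min_event_gap minimum non-eating gap between events in seconds
#'   (> 300 s so events remain distinct after gap elimination).
#' @param seed RNG seed (integer) or `NULL`.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(fs = 256, duration = 7200, n_channels = 2,
                         n_events = 3, event_duration_range = c(54, 240),
                         chew_rate_range = c(0.94, 2.17),
                         burst_duration = 0.28, burst_band = c(20, 120),
                         burst_snr = 8, baseline_sigma = 1,
                         hum_amplitude = 1, drift_amplitude = 1.5,
                         pause_prob = 0.3, pause_duration_range = c(20, 90),
                         grind_rate = 4, grind_max_act = 4,
                         grind_amp_frac = 0.5, chew_cv = 0.06,
                         channel_jitter = 0.010, annotation_jitter = 60,
                         min_event_gap = 360, seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(fs > 0, duration > 0, n_channels >= 1, n_events >= 0,
            event_duration_range[1] <= event_duration_range[2],
            chew_rate_range[1] <= chew_rate_range[2],
            burst_duration > 0, burst_snr >= 0, baseline_sigma > 0,
            grind_max_act < 5, channel_jitter < 0.03)
  class(cfg) <- "synth_config"
  cfg
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed %% (2^31 - 1)))
  }
  expr
}

#' Generate the ground-truth schedule (events, chew times, confounders)
#'
#' Places non-overlapping eating events separated by at least
#' `min_event_gap`, fills each with chew times at a per-event rate drawn from
#' `chew_rate_range` (inter-chew intervals jittered with coefficient of
#' variation `chew_cv`), optionally inserts a within-event chewing pause, and
#' scatters teeth-grinding episodes in non-eating time well clear of any
#' event. Also produces coarse journal-style annotations by jittering the
#' chew-accurate event boundaries by up to `annotation_jitter`.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `ground_truth`: list with `reference`
#'   ([event_reference()], chew-accurate), `onsets` (per-channel true chew
#'   times in seconds), `chews_by_event`, `grinds` (list of activation-time
#'   vectors per channel), `journal` (data.frame `start_s`, `end_s`),
#'   `rates`, `pauses`, `cfg`.
#' @export
generate_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_events
    if (n > 0L) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        durs <- runif(n, cfg$event_duration_range[1], cfg$event_duration_range[2])
        free <- cfg$duration - sum(durs) - (n + 1) * cfg$min_event_gap
        if (free >= 0) { ok <- TRUE; break }
      }
      if (!ok) stop("infeasible packing: events do not fit in the recording")
      extras <- free * diff(c(0, sort(runif(n)), 1))
      starts <- numeric(n)
      cur <- 0
      for (i in seq_len(n)) {
        starts[i] <- cur + cfg$min_event_gap + extras[i]
        cur <- starts[i] + durs[i]
      }
    } else {
      durs <- numeric(); starts <- numeric()
    }
    rates <- if (n > 0L)
      runif(n, cfg$chew_rate_range[1], cfg$chew_rate_range[2]) else numeric()
    chews_by_event <- vector("list", n)
    pauses <- vector("list", n)
    for (i in seq_len(n)) {
      s <- starts[i]; e <- starts[i] + durs[i]
      gap0 <- 1 / rates[i]
      t <- s; ch <- s
      repeat {
        g <- gap0 * (1 + cfg$chew_cv * rnorm(1))
        g <- min(max(g, 0.35), 1.8 * gap0)
        t <- t + g
        if (t >= e - cfg$burst_duration) break
        ch <- c(ch, t)
      }
      p <- NULL
      if (runif(1) < cfg$pause_prob && durs[i] > 4 * cfg$pause_duration_range[1]) {
        pd <- runif(1, cfg$pause_duration_range[1],
                    min(cfg$pause_duration_range[2], durs[i] / 3))
        ps <- runif(1, s + 0.2 * durs[i], e - 0.2 * durs[i] - pd)
        keep <- ch < ps | ch >= ps + pd
        # never drop the boundary chews that define the reference
        keep[c(1L, length(ch))] <- TRUE
        ch <- ch[keep]
        p <- c(start = ps, end = ps + pd)
      }
      chews_by_event[[i]] <- ch
      pauses[[i]] <- p
    }
    ref_start <- vapply(chews_by_event, function(x) x[1L], numeric(1))
    ref_end <- vapply(chews_by_event, function(x)
      x[length(x)] + cfg$burst_duration, numeric(1))
    reference <- event_reference(ref_start, ref_end)
    chews <- unlist(chews_by_event)
    if (is.null(chews)) chews <- numeric()

    # teeth-grinding episodes, clear of events by > t_gap so a stray false
    # segment cannot be merged into a true event
    margin <- 360 + cfg$burst_duration
    blocked <- if (n > 0L)
      interval_union(data.frame(start = pmax(0, ref_start - margin),
                                end = pmin(cfg$duration, ref_end + margin)))
    else intervals()
    allow_s <- c(0, blocked$end); allow_e <- c(blocked$start, cfg$duration)
    keep <- allow_e - allow_s > 30
    allow_s <- allow_s[keep]; allow_e <- allow_e[keep]
    grind_times <- numeric()
    if (length(allow_s) && cfg$grind_rate > 0) {
      free_time <- sum(allow_e - allow_s)
      n_g <- round(cfg$grind_rate * free_time / 3600)
      for (g in seq_len(n_g)) {
        reg <- sample.int(length(allow_s), 1L,
                          prob = allow_e - allow_s)
        t0 <- runif(1, allow_s[reg] + 5, allow_e[reg] - 10)
        n_act <- sample(2:cfg$grind_max_act, 1L)
        grind_times <- c(grind_times, t0 + cumsum(c(0, runif(n_act - 1L,
                                                             0.5, 1.6))))
      }
    }

    jit <- function(x) x + runif(length(x), -cfg$annotation_jitter,
                                 cfg$annotation_jitter)
    journal <- data.frame(start_s = pmax(0, jit(ref_start)),
                          end_s = pmin(cfg$duration, jit(ref_end)))
    if (n > 0L) journal$end_s <- pmax(journal$end_s, journal$start_s + 1)

    chan_jit <- function(x, ch) {
      if (ch == 1L || length(x) == 0L) x
      else pmax(0, x + runif(length(x), -cfg$channel_jitter,
                             cfg$channel_jitter))
    }
    onsets <- lapply(seq_len(cfg$n_channels), function(ch) chan_jit(chews, ch))
    grinds <- lapply(seq_len(cfg$n_channels), function(ch)
      chan_jit(grind_times, ch))
    names(onsets) <- names(grinds) <- paste0("ch", seq_len(cfg$n_channels))

    structure(list(reference = reference, onsets = onsets,
                   chews_by_event = chews_by_event, grinds = grinds,
                   journal = journal, rates = rates, pauses = pauses,
                   cfg = cfg),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d event(s), %d chew(s), %.1f%% eating\n",
              nrow(x$reference), length(x$onsets[[1L]]),
              100 * sum(x$reference$end - x$reference$start) / x$cfg$duration))
  invisible(x)
}

tukey_window <- function(L, alpha = 0.3) {
  if (L == 1L) return(1)
  t <- seq(0, 1, length.out = L)
  w <- rep(1, L)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Render a ground-truth schedule into a raw EMG recording
#'
#' Per channel: Gaussian baseline noise, plus band-limited (20–120 Hz)
#' Tukey-enveloped noise bursts at the channel's chew and grind times, plus
#' 50 Hz hum and slow baseline wander. Channels share chew times up to the
#' (< 30 ms) inter-channel jitter already present in the schedule and have
#' independent noise.
#'
#' @param gt a `ground_truth` from [generate_schedule()].
#' @param cfg the [synth_config()] used for the schedule.
#' @return an [emg_recording()].
#' @export
render_signal <- function(gt, cfg = gt$cfg) {
  stopifnot(inherits(gt, "ground_truth"))
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  L <- max(2L, round(cfg$burst_duration * fs))
  win <- tukey_window(L, 0.3)
  amp <- cfg$burst_snr * cfg$baseline_sigma
  bp <- signal::butter(2, cfg$burst_band / (fs / 2), type = "pass")
  tt <- (seq_len(n) - 1) / fs
  seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 1000003
  with_seed(seed, {
    chans <- lapply(seq_len(cfg$n_channels), function(ch) {
      env <- numeric(n)
      place <- function(times, a) {
        for (t0 in times) {
          i0 <- round(t0 * fs) + 1L
          i1 <- min(n, i0 + L - 1L)
          if (i0 <= n)
            env[i0:i1] <<- pmax(env[i0:i1], a * win[seq_len(i1 - i0 + 1L)])
        }
      }
      place(gt$onsets[[ch]], amp)
      place(gt$grinds[[ch]], amp * cfg$grind_amp_frac)
      band <- as.numeric(signal::filter(bp, rnorm(n)))
      bsd <- sd(band)
      if (bsd > 0) band <- band / bsd
      ph <- runif(2, 0, 2 * pi)
      cfg$baseline_sigma * rnorm(n) +
        env * band +
        cfg$hum_amplitude * sin(2 * pi * 50 * tt + ph[1L]) +
        cfg$drift_amplitude * (0.7 * sin(2 * pi * 0.2 * tt + ph[2L]) + 0.3)
    })
    emg_recording(chans, fs = fs,
                  channel_ids = paste0("ch", seq_len(cfg$n_channels)))
  })
}

#' Generate one synthetic recording with ground truth
#'
#' @param cfg a [synth_config()].
#' @return list with `recording` ([emg_recording()]) and `truth`
#'   (`ground_truth`).
#' @export
generate_recording <- function(cfg = synth_config()) {
  gt <- generate_schedule(cfg)
  list(recording = render_signal(gt, cfg), truth = gt)
}

#' Generate a multi-participant synthetic dataset
#'
#' Derives one seed per participant from `master_seed` and generates an
#' independent recording + ground truth for each.
#'
#' @param n_participants number of participants (>= 1).
#' @param cfg template [synth_config()] applied to every participant.
#' @param master_seed integer master seed.
#' @param render if `FALSE`, only schedules (ground truth) are generated —
#'   useful for fast corpus-statistics checks.
#' @return list of participants, each a list with `recording` (when
#'   rendered), `reference`, `truth`, `id`, `seed`.
#' @export
generate_dataset <- function(n_participants, cfg = synth_config(),
                             master_seed = 1L, render = TRUE) {
  stopifnot(n_participants >= 1)
  seeds <- with_seed(master_seed,
                     sample.int(2^31 - 2, n_participants))
  lapply(seq_len(n_participants), function(i) {
    ci <- cfg
    ci$seed <- seeds[i]
    gt <- generate_schedule(ci)
    out <- list(reference = gt$reference, truth = gt,
                id = sprintf("P%02d", i), seed = seeds[i])
    if (render) out$recording <- render_signal(gt, ci)
    out
  })
}
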