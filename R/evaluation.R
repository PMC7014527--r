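# Event-based evaluation: time-overlap retrieval metrics (precision, recall,
# F1 over summed durations), start/end timing errors, parameter grid search
# with the PX/PS/PE performance points, and leave-one-participant-out
# cross-validation.

#' Summed reference, retrieved and overlap durations
#'
#' `Tgt` is the summed duration of all reference eating events, `Tret` the
#' summed duration of all detected events, and `Ttp` the summed pairwise
#' overlap between reference and detected events (only pairs with positive
#' overlap contribute).
#'
#' @param ref an [event_reference()] (or interval data.frame).
#' @param det detected events: interval data.frame or `eating_detection`.
#' @return list with `Tgt`, `Tret`, `Ttp` (seconds).
#' @export
overlap_durations <- function(ref, det) {
  if (inherits(det, "eating_detection")) det <- det$events
  Tgt <- sum(ref$end - ref$start)
  Tret <- sum(det$end - det$start)
  Ttp <- 0
  if (nrow(ref) && nrow(det)) {
    ov <- pmin(outer(ref$end, det$end, pmin) - outer(ref$start, det$start, pmax),
               Inf)
    Ttp <- sum(ov[ov > 0])
  }
  list(Tgt = Tgt, Tret = Tret, Ttp = Ttp)
}

#' Time-overlap retrieval metrics
#'
#' Precision = `Ttp / Tret`, recall = `Ttp / Tgt`, F1 = harmonic mean of the
#' two (see [overlap_durations()]). Zero-denominator cases yield 0 and are
#' flagged.
#'
#' @inheritParams overlap_durations
#' @return an object of class `retrieval_metrics`: list with `Tgt`, `Tret`,
#'   `Ttp`, `precision`, `recall`, `f1` and logical flags `zero_ret`,
#'   `zero_gt`.
#' @export
retrieval_metrics <- function(ref, det) {
  d <- overlap_durations(ref, det)
  precision <- if (d$Tret > 0) d$Ttp / d$Tret else 0
  recall <- if (d$Tgt > 0) d$Ttp / d$Tgt else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(c(d, list(precision = precision, recall = recall, f1 = f1,
                      zero_ret = d$Tret == 0, zero_gt = d$Tgt == 0)),
            class = "retrieval_metrics")
}

#' @export
print.retrieval_metrics <- function(x, ...) {
  cat(sprintf("Retrieval: precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  Tgt %.1f s, Tret %.1f s, Ttp %.1f s\n", x$Tgt, x$Tret, x$Ttp))
  invisible(x)
}

#' Start/end timing errors of detected events
#'
#' For every detected event the start error is the minimum absolute
#' difference between its start and any reference start (analogously for
#' ends). Means over detected events are the average start/end timing
#' errors; sample standard deviations across events are reported alongside.
#' With no detected events the result is flagged undefined.
#'
#' @inheritParams overlap_durations
#' @return an object of class `timing_errors`: list with `per_event`
#'   (data.frame of per-event `start_error`, `end_error`),
#'   `mean_start_error`, `mean_end_error`, `sd_start`, `sd_end`, `n_events`,
#'   `undefined`.
#' @export
timing_errors <- function(ref, det) {
  if (inherits(det, "eating_detection")) det <- det$events
  Q <- nrow(det)
  if (Q == 0L || nrow(ref) == 0L) {
    return(structure(list(per_event = data.frame(start_error = numeric(),
                                                 end_error = numeric()),
                          mean_start_error = NA_real_,
                          mean_end_error = NA_real_,
                          sd_start = NA_real_, sd_end = NA_real_,
                          n_events = Q, undefined = TRUE),
                     class = "timing_errors"))
  }
  se <- vapply(det$start, function(s) min(abs(s - ref$start)), numeric(1))
  ee <- vapply(det$end, function(e) min(abs(e - ref$end)), numeric(1))
  structure(list(per_event = data.frame(start_error = se, end_error = ee),
                 mean_start_error = mean(se), mean_end_error = mean(ee),
                 sd_start = if (Q > 1L) sd(se) else 0,
                 sd_end = if (Q > 1L) sd(ee) else 0,
                 n_events = Q, undefined = FALSE),
            class = "timing_errors")
}

#' @export
print.timing_errors <- function(x, ...) {
  if (x$undefined) {
    cat("Timing errors: undefined (no detected events)\n")
  } else {
    cat(sprintf("Timing errors over %d event(s): start %.2f +/- %.2f s, end %.2f +/- %.2f s\n",
                x$n_events, x$mean_start_error, x$sd_start,
                x$mean_end_error, x$sd_end))
  }
  invisible(x)
}

#' Full evaluation report for one detection run
#'
#' @inheritParams overlap_durations
#' @return an object of class `eval_report` bundling [retrieval_metrics()]
#'   and [timing_errors()].
#' @export
eval_detection <- function(ref, det) {
  structure(list(retrieval = retrieval_metrics(ref, det),
                 timing = timing_errors(ref, det)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$retrieval); print(x$timing)
  invisible(x)
}

# pooled metrics over several (ref, det) pairs: durations are summed, timing
# errors pooled across events
pooled_metrics <- function(refs, dets) {
  Tgt <- 0; Tret <- 0; Ttp <- 0
  se <- numeric(); ee <- numeric()
  for (i in seq_along(refs)) {
    d <- overlap_durations(refs[[i]], dets[[i]])
    Tgt <- Tgt + d$Tgt; Tret <- Tret + d$Tret; Ttp <- Ttp + d$Ttp
    te <- timing_errors(refs[[i]], dets[[i]])
    if (!te$undefined) {
      se <- c(se, te$per_event$start_error)
      ee <- c(ee, te$per_event$end_error)
    }
  }
  precision <- if (Tret > 0) Ttp / Tret else 0
  recall <- if (Tgt > 0) Ttp / Tgt else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       mean_start_error = if (length(se)) mean(se) else NA_real_,
       mean_end_error = if (length(ee)) mean(ee) else NA_real_,
       sd_start = if (length(se) > 1L) sd(se) else 0,
       sd_end = if (length(ee) > 1L) sd(ee) else 0,
       n_events = length(se))
}

# ---- grid search -----------------------------------------------------------

eating_mask_samples <- function(ref, n, fs) {
  mask <- logical(n)
  for (p in seq_len(nrow(ref))) {
    i0 <- min(n, floor(ref$start[p] * fs) + 1)
    i1 <- min(n, ceiling(ref$end[p] * fs))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

baseline_moments <- function(xp, ref) {
  n <- nrow(xp$values)
  keep <- !eating_mask_samples(ref, n, xp$fs)
  v <- as.numeric(xp$values[keep, ])
  c(n = length(v), s1 = sum(v), s2 = sum(v^2))
}

# eating label per window: >= 50% overlap with reference events
window_eating_labels <- function(fe, ref) {
  ws <- fe$start / fe$fs
  we <- (fe$start + fe$w2) / fe$fs
  ov <- numeric(length(ws))
  if (nrow(ref)) {
    # overlap of [ws, we) with each ref event
    o <- pmin(outer(we, ref$end, pmin) - outer(ws, ref$start, pmax), we - ws)
    o[o < 0] <- 0
    ov <- apply(o, 1, max)
  }
  ov >= (fe$w2 / fe$fs) / 2
}

run_bottom_up_on_xp <- function(xp, onsets, w0, theta_0, t_gap) {
  segs <- lapply(onsets, detect_segments, w0 = w0, theta_0 = theta_0,
                 fs = xp$fs)
  eliminate_gaps(fuse_sources(segs), t_gap)
}

#' Grid search over detector parameters
#'
#' Evaluates every parameter combination in `grid` on a set of labelled
#' recordings (metrics pooled across recordings) and extracts the three
#' performance points: `PX` (maximal F1), `PS` (minimal mean start timing
#' error) and `PE` (minimal mean end timing error). Ties are broken by the
#' first row in grid order, which makes the search deterministic.
#'
#' Grid columns by algorithm: bottom-up `w0` (s), `theta_0`; threshold `w1`
#' (samples), `theta_1`; ocSVM `gamma`, `nu` (window `w2` is passed in
#' `fixed`). Fixed pipeline parameters (`w`, `theta_P`, `t_interval`,
#' `t_gap`, `fnf`, `fhpf`, `s1`, `w2`, `theta_C`) can be overridden through
#' `fixed`; `theta_C` is otherwise estimated from pooled non-eating samples
#' of the supplied recordings.
#'
#' @param recordings list of [emg_recording()] objects (training data).
#' @param references list of [event_reference()] objects, same length.
#' @param grid data.frame of parameter combinations (non-empty).
#' @param algo `"bottom-up"`, `"threshold"` or `"ocsvm"`.
#' @param fixed named list of fixed-parameter overrides.
#' @return an object of class `grid_result`: list with `table` (grid plus
#'   metrics per row), `px`, `ps`, `pe` (row indices), `px_params`,
#'   `ps_params`, `pe_params` (named lists), `theta_C`, `algo`, `fixed`.
#' @export
grid_search <- function(recordings, references, grid,
                        algo = c("bottom-up", "threshold", "ocsvm"),
                        fixed = list()) {
  algo <- match.arg(algo)
  stopifnot(length(recordings) == length(references))
  fx <- default_params()
  fx[names(fixed)] <- fixed
  xps <- lapply(recordings, preprocess, fnf = fx$fnf, fhpf = fx$fhpf)
  grid_search_impl(xps, references, grid, algo, fx)
}

grid_search_impl <- function(xps, references, grid, algo, fx) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) stop("empty grid")
  theta_C <- fx$theta_C
  if (is.null(theta_C)) {
    mom <- rowSums(vapply(seq_along(xps), function(i)
      baseline_moments(xps[[i]], references[[i]]), numeric(3)))
    theta_C <- threshold_from_moments(mom["n"], mom["s1"], mom["s2"])
  }
  dets_for_row <- switch(algo,
    "bottom-up" = {
      onsets <- lapply(xps, detect_chewing_cycles, theta_C = theta_C,
                       w = fx$w, theta_P = fx$theta_P,
                       t_interval = fx$t_interval)
      function(row) lapply(seq_along(xps), function(i)
        run_bottom_up_on_xp(xps[[i]], onsets[[i]],
                            w0 = row$w0, theta_0 = row$theta_0,
                            t_gap = fx$t_gap))
    },
    "threshold" = function(row) lapply(xps, function(xp) {
      segs <- detect_segments_threshold(xp, w1 = row$w1, s1 = fx$s1,
                                        theta_1 = row$theta_1)
      eliminate_gaps(fuse_sources(segs), fx$t_gap)
    }),
    "ocsvm" = {
      if (is.null(fx$w2)) stop("ocsvm grid search requires fixed$w2")
      fes <- lapply(xps, extract_window_features, w2 = fx$w2,
                    theta_C = theta_C)
      labels <- lapply(seq_along(fes), function(i)
        window_eating_labels(fes[[i]], references[[i]]))
      train_feats <- do.call(rbind, lapply(seq_along(fes), function(i)
        fes[[i]]$features[labels[[i]], , drop = FALSE]))
      if (nrow(train_feats) < 10L)
        stop("fewer than 10 eating-labelled training windows")
      function(row) {
        model <- train_ocsvm(train_feats, gamma = row$gamma, nu = row$nu)
        lapply(xps, function(xp) {
          segs <- detect_segments_ocsvm(xp, model, fx$w2, theta_C)
          eliminate_gaps(fuse_sources(segs), fx$t_gap)
        })
      }
    })
  res <- lapply(seq_len(nrow(grid)), function(r) {
    dets <- dets_for_row(grid[r, , drop = FALSE])
    pooled_metrics(references, dets)
  })
  tab <- cbind(grid, do.call(rbind, lapply(res, function(m)
    data.frame(precision = m$precision, recall = m$recall, f1 = m$f1,
               mean_start_error = m$mean_start_error,
               mean_end_error = m$mean_end_error,
               sd_start = m$sd_start, sd_end = m$sd_end,
               n_events = m$n_events))))
  na_inf <- function(v) ifelse(is.na(v), Inf, v)
  px <- which.max(tab$f1)
  ps <- which.min(na_inf(tab$mean_start_error))
  pe <- which.min(na_inf(tab$mean_end_error))
  params_of <- function(r) as.list(grid[r, , drop = FALSE])
  structure(list(table = tab, px = px, ps = ps, pe = pe,
                 px_params = params_of(px), ps_params = params_of(ps),
                 pe_params = params_of(pe), theta_C = theta_C,
                 algo = algo, fixed = fx),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("Grid search (%s): %d combination(s)\n", x$algo, nrow(x$table)))
  pts <- c(PX = x$px, PS = x$ps, PE = x$pe)
  for (nm in names(pts)) {
    r <- x$table[pts[[nm]], ]
    cat(sprintf("  %s: %s | F1 %.3f, start err %.2f s, end err %.2f s\n", nm,
                paste(sprintf("%s=%g", names(x$table)[seq_len(ncol(x$table) - 8L)],
                              unlist(r[seq_len(ncol(x$table) - 8L)])),
                      collapse = ", "),
                r$f1, r$mean_start_error, r$mean_end_error))
  }
  invisible(x)
}

# ---- LOPO cross-validation -------------------------------------------------

apply_params <- function(xp_test, params, algo, fx, theta_C, train_ctx) {
  if (algo == "bottom-up") {
    onsets <- detect_chewing_cycles(xp_test, theta_C, w = fx$w,
                                    theta_P = fx$theta_P,
                                    t_interval = fx$t_interval)
    run_bottom_up_on_xp(xp_test, onsets, params$w0, params$theta_0, fx$t_gap)
  } else if (algo == "threshold") {
    segs <- detect_segments_threshold(xp_test, w1 = params$w1, s1 = fx$s1,
                                      theta_1 = params$theta_1)
    eliminate_gaps(fuse_sources(segs), fx$t_gap)
  } else {
    model <- train_ocsvm(train_ctx$train_feats, gamma = params$gamma,
                         nu = params$nu)
    segs <- detect_segments_ocsvm(xp_test, model, fx$w2, theta_C)
    eliminate_gaps(fuse_sources(segs), fx$t_gap)
  }
}

#' Leave-one-participant-out evaluation
#'
#' For every participant: run [grid_search()] on the remaining participants,
#' take the `PX`/`PS`/`PE` parameter combinations, apply each to the held-out
#' participant, and average the resulting test metrics over folds.
#'
#' A fold whose training union contains no eating events cannot supply
#' eating-labelled training windows (or a meaningful grid); it is flagged and
#' excluded from the averages.
#'
#' @param dataset list of participants, each a list with elements
#'   `recording` ([emg_recording()]) and `reference` ([event_reference()]).
#' @param algo detector id (see [grid_search()]).
#' @param grid parameter grid (see [grid_search()]).
#' @param fixed fixed-parameter overrides (see [grid_search()]).
#' @return an object of class `lopo_result`: list with `folds` (per-fold
#'   point metrics), `summary` (data.frame: one row per performance point
#'   with fold-averaged metrics and across-fold standard deviations),
#'   `n_folds`, `algo`.
#' @export
lopo_evaluate <- function(dataset, algo = c("bottom-up", "threshold", "ocsvm"),
                          grid, fixed = list()) {
  algo <- match.arg(algo)
  n <- length(dataset)
  if (n < 2L) stop("LOPO needs at least 2 participants")
  fx <- default_params()
  fx[names(fixed)] <- fixed
  xps <- lapply(dataset, function(d) preprocess(d$recording, fnf = fx$fnf,
                                                fhpf = fx$fhpf))
  refs <- lapply(dataset, `[[`, "reference")
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (sum(vapply(refs[tr], nrow, integer(1))) == 0L) {
      folds[[i]] <- list(flagged = TRUE)
      next
    }
    gs <- grid_search_impl(xps[tr], refs[tr], grid, algo, fx)
    train_ctx <- NULL
    if (algo == "ocsvm") {
      fes <- lapply(xps[tr], extract_window_features, w2 = fx$w2,
                    theta_C = gs$theta_C)
      train_feats <- do.call(rbind, lapply(seq_along(fes), function(k)
        fes[[k]]$features[window_eating_labels(fes[[k]], refs[tr][[k]]), ,
                          drop = FALSE]))
      train_ctx <- list(train_feats = train_feats)
    }
    pts <- list(PX = gs$px_params, PS = gs$ps_params, PE = gs$pe_params)
    fold <- lapply(pts, function(p) {
      det <- apply_params(xps[[i]], p, algo, fx, gs$theta_C, train_ctx)
      m <- pooled_metrics(refs[i], list(det))
      c(m, list(params = p))
    })
    fold$flagged <- FALSE
    folds[[i]] <- fold
  }
  ok <- !vapply(folds, `[[`, logical(1), "flagged")
  summarise_point <- function(pt) {
    g <- function(field) vapply(folds[ok], function(f) {
      v <- f[[pt]][[field]]
      if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
    }, numeric(1))
    data.frame(point = pt,
               f1 = mean(g("f1")), f1_sd = sd(g("f1")),
               precision = mean(g("precision")), recall = mean(g("recall")),
               mean_start_error = mean(g("mean_start_error"), na.rm = TRUE),
               start_error_sd = sd(g("mean_start_error"), na.rm = TRUE),
               mean_end_error = mean(g("mean_end_error"), na.rm = TRUE),
               end_error_sd = sd(g("mean_end_error"), na.rm = TRUE))
  }
  summary <- do.call(rbind, lapply(c("PX", "PS", "PE"), summarise_point))
  structure(list(folds = folds, summary = summary, n_folds = n,
                 n_flagged = sum(!ok), algo = algo),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("LOPO evaluation (%s): %d fold(s)%s\n", x$algo, x$n_folds,
              if (x$n_flagged) sprintf(", %d flagged", x$n_flagged) else ""))
  df <- x$summary
  df[-1L] <- lapply(df[-1L], round, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
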