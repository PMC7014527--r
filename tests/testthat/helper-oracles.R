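# Independent brute-force oracles. These deliberately avoid the package's
# incremental / vectorised code paths: everything is recomputed from the
# definitions with plain loops.

# per-window recount of the conditional-count index
oracle_index_series <- function(x, w, theta_C) {
  half <- w %/% 2L
  npos <- length(x) - w + 1L
  vapply(seq_len(npos), function(i0) {
    first <- x[i0:(i0 + half - 1L)]
    second <- x[(i0 + half):(i0 + w - 1L)]
    sum(first < theta_C) + sum(second > theta_C)
  }, numeric(1))
}

# direct evaluation of the chewing-segment start/end predicates on the
# onset-count function f(j) = #{onsets in [t_j, t_j + w0]}
oracle_segments <- function(C, w0, theta_0, fs) {
  t <- (as.numeric(C) - 1) / fs
  K <- length(t)
  if (K == 0L) return(data.frame(start = numeric(), end = numeric()))
  f <- rep(0L, K)
  for (j in seq_len(K)) {
    for (k in seq_len(K)) if (t[k] >= t[j] && t[k] <= t[j] + w0)
      f[j] <- f[j] + 1L
  }
  starts <- numeric(); ends <- numeric()
  j <- 1L
  repeat {
    if (j > K) break
    if (f[j] < theta_0) { j <- j + 1L; next }
    js <- j
    je <- NA_integer_
    for (jj in js:K) {
      if (jj + theta_0 - 1L > K) break
      if (f[jj] == theta_0 && f[jj + theta_0 - 1L] == 1L) {
        je <- jj + theta_0 - 1L
        break
      }
    }
    if (is.na(je)) je <- K
    starts <- c(starts, t[js]); ends <- c(ends, t[je])
    j <- je + 1L
  }
  data.frame(start = starts, end = ends)
}

# sample-grid label intersection for the overlap duration
oracle_ttp_grid <- function(ref, det, fs) {
  n <- round(max(c(ref$end, det$end, 1)) * fs) + 1L
  mask_of <- function(iv) {
    m <- logical(n)
    for (r in seq_len(nrow(iv))) {
      i0 <- round(iv$start[r] * fs) + 1L
      i1 <- min(round(iv$end[r] * fs), n)
      if (i1 >= i0) m[i0:i1] <- TRUE
    }
    m
  }
  sum(mask_of(ref) & mask_of(det)) / fs
}

# all-pairs minima for the timing errors
oracle_timing <- function(ref, det) {
  se <- numeric(nrow(det)); ee <- numeric(nrow(det))
  for (q in seq_len(nrow(det))) {
    best_s <- Inf; best_e <- Inf
    for (p in seq_len(nrow(ref))) {
      best_s <- min(best_s, abs(det$start[q] - ref$start[p]))
      best_e <- min(best_e, abs(det$end[q] - ref$end[p]))
    }
    se[q] <- best_s; ee[q] <- best_e
  }
  list(mean_start = mean(se), mean_end = mean(ee), se = se, ee = ee)
}

# random strictly-increasing onset lists with dense clusters and stragglers
random_onset_list <- function(fs = 256) {
  n_clusters <- sample(0:3, 1)
  t <- numeric()
  cur <- runif(1, 0, 5)
  for (k in seq_len(n_clusters)) {
    nk <- sample(3:20, 1)
    gaps <- runif(nk, 0.3, 1.2)
    t <- c(t, cur + cumsum(gaps))
    cur <- max(t) + runif(1, 2, 40)
  }
  n_sparse <- sample(0:6, 1)
  t <- sort(c(t, runif(n_sparse, 0, max(cur, 60))))
  samp <- unique(as.integer(round(t * fs)) + 1L)
  sort(samp)
}

random_interval_set <- function(n_max = 6, span = 1000, fs = NULL) {
  n <- sample(0:n_max, 1)
  if (n == 0L) return(data.frame(start = numeric(), end = numeric()))
  s <- runif(n, 0, span)
  e <- s + runif(n, 0.5, span / 4)
  if (!is.null(fs)) { s <- round(s * fs) / fs; e <- round(e * fs) / fs }
  data.frame(start = s, end = e)
}
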