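test_that("EMG work sums rectified samples", {
  expect_equal(emg_work(rep(0, 100)), 0)
  expect_equal(emg_work(rep(1, 100)), 100)
  expect_equal(emg_work(c(1, 2, 3)), 6)
  expect_error(emg_work(numeric()), "empty")
})

mk_xp <- function(x, fs = 256) {
  structure(list(values = as.matrix(x), fs = fs,
                 channel_ids = paste0("ch", seq_len(ncol(as.matrix(x)))) ),
            class = "preprocessed_emg")
}

test_that("threshold detector finds nothing in silence and one segment per burst", {
  fs <- 256
  xp <- mk_xp(rep(0, 20 * fs))
  expect_equal(nrow(detect_segments_threshold(xp, w1 = 512, s1 = 256,
                                              theta_1 = 10)[[1]]), 0L)
  # one rectangular burst of 3*w1 samples, work far above threshold
  x <- rep(0, 30 * fs)
  x[(10 * fs):(10 * fs + 3 * 512)] <- 1
  seg <- detect_segments_threshold(mk_xp(x), w1 = 512, s1 = 256,
                                   theta_1 = 50)[[1]]
  expect_equal(nrow(seg), 1L)
  expect_lt(abs(seg$start - 10), 512 / fs + 1 / fs)
  expect_lt(abs(seg$end - (10 + 3 * 512 / fs)), 2 * 512 / fs)
})

test_that("threshold detector equals brute-force window recomputation", {
  fs <- 256
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(4000:9000, 1)
    x <- abs(rnorm(n)) + 2 * rbinom(n, 1, 0.05)
    w1 <- sample(c(300L, 512L, 768L), 1); s1 <- 256L
    th1 <- quantile(abs(x), 0.8) * w1
    seg <- detect_segments_threshold(mk_xp(x), w1, s1, th1)[[1]]
    # brute force straight from the sliding-window definition
    pos <- seq.int(s1, n - w1 - 1L, by = s1)
    f <- vapply(pos, function(i) sum(x[(i + 1):(i + w1)]), numeric(1))
    fp <- vapply(pos - s1, function(i) sum(x[(i + 1):(i + w1)]), numeric(1))
    fn <- vapply(pos + s1, function(i) sum(x[(i + 1):(i + w1)]), numeric(1))
    st <- pos[fp < th1 & f > th1] / fs
    en <- (pos[f > th1 & fn < th1] + s1) / fs
    ev <- rbind(data.frame(t = st, k = rep(1L, length(st))),
                data.frame(t = en, k = rep(2L, length(en))))
    ev <- ev[order(ev$t, ev$k), ]
    ss <- c(); ee <- c(); open <- NA
    for (r in seq_len(nrow(ev))) {
      if (ev$k[r] == 1L) { if (is.na(open)) open <- ev$t[r] }
      else if (!is.na(open)) { ss <- c(ss, open); ee <- c(ee, ev$t[r]); open <- NA }
    }
    if (!is.na(open)) { ss <- c(ss, open); ee <- c(ee, (pos[length(pos)] + s1) / fs) }
    expect_equal(seg$start, as.numeric(ss))
    expect_equal(seg$end, as.numeric(ee))
  }
})

test_that("window features behave on constant and identical windows", {
  fs <- 256
  fe0 <- extract_window_features(mk_xp(rep(0, 1024)), w2 = 256, theta_C = 1)
  expect_equal(unname(fe0$features[1, "mean"]), 0)
  expect_equal(unname(fe0$features[1, "work"]), 0)
  fe2 <- extract_window_features(mk_xp(rep(2, 1024)), w2 = 256, theta_C = 1)
  expect_equal(unname(fe2$features[1, "mean"]), 2)
  expect_equal(unname(fe2$features[1, "sd"]), 0)
  expect_equal(unname(fe2$features[1, "above_rate"]), 1)
  # identical windows -> identical rows
  set.seed(2); xw <- abs(rnorm(256))
  fe <- extract_window_features(mk_xp(rep(xw, 4)), w2 = 256, theta_C = 1)
  expect_true(all(apply(fe$features, 2, function(c) max(abs(c - c[1]))) < 1e-12))
})

test_that("one-class SVM respects the nu bound and is deterministic", {
  set.seed(31)
  feats <- matrix(rnorm(1000 * 8), ncol = 8)
  m <- train_ocsvm(feats, gamma = 0.2, nu = 0.1)
  train_out <- mean(!predict(m, feats))
  expect_lte(train_out, 0.13)
  m2 <- train_ocsvm(feats, gamma = 0.2, nu = 0.1)
  expect_identical(predict(m, feats), predict(m2, feats))
  expect_error(train_ocsvm(matrix(1, 50, 8), 0.2, 0.1), "degenerate")
  expect_error(train_ocsvm(feats[1:5, ], 0.2, 0.1), "10")
})

test_that("ocSVM trained on one channel's eating windows accepts the other's", {
  cfg <- synth_config(duration = 1800, n_events = 2,
                      event_duration_range = c(120, 180),
                      min_event_gap = 150, grind_rate = 0, seed = 55)
  sim <- generate_recording(cfg)
  xp <- preprocess(sim$recording)
  thc <- estimate_burst_threshold(as.numeric(xp$values))
  fe <- extract_window_features(xp, w2 = 1280, theta_C = thc)
  lab <- chewdet:::window_eating_labels(fe, ref_of(sim))
  tr <- lab & fe$channel == 1L
  te <- lab & fe$channel == 2L
  m <- train_ocsvm(fe$features[tr, , drop = FALSE], gamma = 0.05, nu = 0.1)
  expect_gt(mean(predict(m, fe$features[te, , drop = FALSE])), 0.5)
})

test_that("ocSVM segments align to window boundaries and merge runs", {
  fs <- 256; w2 <- 512L
  cfg <- quick_cfg(duration = 600, n_events = 1, seed = 66)
  sim <- generate_recording(cfg)
  xp <- preprocess(sim$recording)
  thc <- estimate_burst_threshold(as.numeric(xp$values))
  fe <- extract_window_features(xp, w2, thc)
  lab <- chewdet:::window_eating_labels(fe, ref_of(sim))
  m <- train_ocsvm(fe$features[lab, , drop = FALSE], gamma = 0.1, nu = 0.1)
  segs <- detect_segments_ocsvm(xp, m, w2, thc)
  for (s in segs) {
    if (!nrow(s)) next
    expect_true(all(abs((s$start * fs) %% w2) < 1e-6))
    expect_true(all(abs((s$end * fs) %% w2) < 1e-6))
    expect_true(all(diff(c(rbind(s$start, s$end))) >= 0))
  }
})

test_that("ocSVM segment merging handles alternating and empty predictions", {
  fs <- 256; w2 <- 256L
  set.seed(9)
  # alternating loud/quiet windows; model trained on loud ones
  loud <- function() abs(rnorm(w2, sd = 5)); quiet <- function() abs(rnorm(w2, sd = 0.1))
  x <- unlist(lapply(1:10, function(i) c(loud(), quiet())))
  xp <- mk_xp(x)
  fe <- extract_window_features(xp, w2, theta_C = 1)
  odd <- seq(1, 20, by = 2)
  m <- train_ocsvm(fe$features[odd, ], gamma = 0.05, nu = 0.05)
  seg <- detect_segments_ocsvm(xp, m, w2, theta_C = 1)[[1]]
  # loud windows alternate with quiet ones, so accepted windows stay isolated
  expect_gte(nrow(seg), 5L)
  expect_lte(nrow(seg), 10L)
  expect_true(all(abs(seg$end - seg$start - w2 / fs) < 1e-9))
  # a signal nothing like the training windows yields no segments
  seg0 <- detect_segments_ocsvm(mk_xp(rep(0.05, 20 * w2)), m, w2, 1)[[1]]
  expect_equal(nrow(seg0), 0L)
})
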