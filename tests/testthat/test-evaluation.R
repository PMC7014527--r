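test_that("retrieval metrics follow the overlap-duration definitions", {
  ref <- event_reference(c(0, 200), c(100, 300))
  m <- retrieval_metrics(ref, ref)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))

  m2 <- retrieval_metrics(event_reference(0, 100), intervals(50, 150))
  expect_equal(m2$Ttp, 50)
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(0.5, 0.5, 0.5))

  # one detection spanning two reference events
  m3 <- retrieval_metrics(event_reference(c(0, 20), c(10, 30)),
                          intervals(0, 30))
  expect_equal(m3$Ttp, 20)
  expect_equal(m3$Tret, 30)
  expect_equal(m3$precision, 2 / 3)
  expect_equal(m3$recall, 1)

  m4 <- retrieval_metrics(ref, intervals())
  expect_equal(m4$f1, 0)
  expect_true(m4$zero_ret)
})

test_that("overlap durations match a sample-grid computation", {
  fs <- 256
  ref <- event_reference(c(0, 50), c(20, 80))
  full <- intervals(0, 100)
  d <- overlap_durations(ref, full)
  expect_equal(d$Ttp, d$Tgt)
  expect_equal(overlap_durations(ref, intervals())$Ttp, 0)

  set.seed(23)
  for (rep in 1:30) {
    ref <- interval_union(random_interval_set(5, 500, fs = fs))
    det <- interval_union(random_interval_set(5, 500, fs = fs))
    d <- overlap_durations(ref, det)
    grid <- oracle_ttp_grid(ref, det, fs = fs)
    expect_lt(abs(d$Ttp - grid), (nrow(ref) * nrow(det) + 1) / fs)
    expect_lte(d$Ttp, min(d$Tgt, d$Tret) + 1e-9)
  }
})

test_that("timing errors are all-pairs minima averaged over detections", {
  ref <- event_reference(c(10, 100), c(50, 150))
  te0 <- timing_errors(ref, ref)
  expect_equal(te0$mean_start_error, 0)
  expect_equal(te0$mean_end_error, 0)

  te1 <- timing_errors(ref, intervals(12, 60))
  expect_equal(te1$mean_start_error, 2)    # min(|12-10|, |12-100|)
  expect_equal(te1$mean_end_error, 10)

  expect_true(timing_errors(ref, intervals())$undefined)

  set.seed(44)
  for (rep in 1:25) {
    ref <- event_reference(c(0, 300, 600), c(100, 400, 700))
    det <- random_interval_set(6, 800)
    if (nrow(det) == 0) next
    te <- timing_errors(ref, det)
    br <- oracle_timing(ref, det)
    expect_equal(te$mean_start_error, br$mean_start)
    expect_equal(te$mean_end_error, br$mean_end)
    expect_equal(te$per_event$start_error, br$se)
  }
})

test_that("timing errors are order-invariant and 1-Lipschitz under shifts", {
  set.seed(61)
  ref <- event_reference(c(0, 300, 600), c(100, 400, 700))
  det <- intervals(c(10, 310, 590), c(105, 395, 712))
  te <- timing_errors(ref, det)
  perm <- det[c(3, 1, 2), ]
  expect_equal(timing_errors(ref, perm)$mean_start_error, te$mean_start_error)
  for (delta in c(-3, 1, 5)) {
    sh <- intervals(det$start + delta, det$end + delta)
    expect_lte(abs(timing_errors(ref, sh)$mean_start_error -
                     te$mean_start_error), abs(delta) + 1e-9)
  }
})

test_that("retrieval metric invariants hold on random inputs", {
  set.seed(3)
  for (rep in 1:40) {
    ref <- tryCatch(event_reference(sort(runif(3, 0, 900)),
                                    sort(runif(3, 0, 900))),
                    error = function(e) NULL)
    if (is.null(ref)) next
    det <- interval_union(random_interval_set(5, 1000))
    m <- retrieval_metrics(ref, det)
    expect_true(all(c(m$precision, m$recall, m$f1) >= 0))
    expect_true(all(c(m$precision, m$recall, m$f1) <= 1))
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("grid search extracts PX/PS/PE deterministically", {
  cfg <- quick_cfg(duration = 900, n_events = 2, seed = 13)
  sim <- generate_recording(cfg)
  g1 <- grid_search(list(sim$recording), list(ref_of(sim)),
                    grid = data.frame(w0 = 5, theta_0 = 6), algo = "bottom-up")
  expect_equal(g1$px, 1L); expect_equal(g1$ps, 1L); expect_equal(g1$pe, 1L)
  expect_equal(g1$px_params$w0, 5)

  g2 <- grid_search(list(sim$recording), list(ref_of(sim)),
                    grid = expand.grid(w0 = c(3, 5), theta_0 = c(2, 6)),
                    algo = "bottom-up")
  expect_equal(g2$px, which.max(g2$table$f1))
  expect_equal(g2$table$mean_start_error[g2$ps],
               min(g2$table$mean_start_error, na.rm = TRUE))
  expect_equal(g2$table$mean_end_error[g2$pe],
               min(g2$table$mean_end_error, na.rm = TRUE))
  # deterministic tie-break: first row in grid order wins
  expect_equal(g2$ps, which.min(ifelse(is.na(g2$table$mean_start_error), Inf,
                                       g2$table$mean_start_error)))
  expect_error(grid_search(list(sim$recording), list(ref_of(sim)),
                           grid = data.frame(), algo = "bottom-up"), "empty")
})

test_that("LOPO has one fold per participant; identical twins agree", {
  cfg <- quick_cfg(duration = 900, n_events = 2, seed = 29)
  sim <- generate_recording(cfg)
  ds <- list(list(recording = sim$recording, reference = ref_of(sim)),
             list(recording = sim$recording, reference = ref_of(sim)))
  res <- lopo_evaluate(ds, "bottom-up", grid = data.frame(w0 = 5, theta_0 = 6))
  expect_equal(res$n_folds, 2L)
  expect_length(res$folds, 2L)
  # train and test participant are identical recordings
  gs <- grid_search(list(sim$recording), list(ref_of(sim)),
                    grid = data.frame(w0 = 5, theta_0 = 6), algo = "bottom-up")
  expect_equal(res$folds[[1]]$PX$f1, gs$table$f1[1])
  expect_equal(res$summary$f1[res$summary$point == "PX"], gs$table$f1[1])
})
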