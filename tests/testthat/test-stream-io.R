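make_stream <- function(n = 100, rate = 10, jitter = 0, channels = 1,
                        name = "S", seed = 1) {
  set.seed(seed)
  ts <- (seq_len(n) - 1) / rate
  if (jitter > 0) ts <- sort(ts + stats::rnorm(n, sd = jitter))
  stream_series(name, rate, ts, matrix(stats::rnorm(n * channels), n, channels))
}

test_that("recordings round-trip losslessly through the container", {
  sim <- memo("io_session", function() short_session(seed = 11))
  dir <- withr::local_tempdir()
  write_recording(sim$recording, dir)
  back <- read_recording(dir, dejitter = FALSE)
  for (m in names(sim$recording$streams)) {
    s0 <- sim$recording$streams[[m]]
    s1 <- back$streams[[m]]
    expect_identical(s1$timestamps, s0$timestamps)   # bit-exact doubles
    expect_identical(s1$samples, unname(s0$samples))
    expect_identical(s1$channel_labels, s0$channel_labels)
    expect_identical(s1$nominal_rate, s0$nominal_rate)
  }
  expect_equal(back$markers$timestamp, sim$recording$markers$timestamp)
  expect_identical(back$markers$action_id, sim$recording$markers$action_id)
  # 54-channel fNIRS order is preserved
  expect_identical(back$streams$fNIRS$channel_labels[1:4],
                   c("CH01_O2Hb", "CH01_HHb", "CH02_O2Hb", "CH02_HHb"))
})

test_that("empty-marker recordings and missing containers behave", {
  rec <- session_recording(list(S = make_stream()), empty_markers())
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_identical(nrow(back$markers), 0L)
  expect_error(read_recording(file.path(dir, "nope")), class = "mwlfuse_io_error")
  file.remove(file.path(dir, "markers.csv"))
  expect_error(read_recording(dir), class = "mwlfuse_io_error",
               regexp = "marker")
})

test_that("rate check accepts small offsets but de-jitters noisy clocks", {
  # uniform grid at 255.9 Hz declared as 256 Hz: within 1%, left untouched
  n <- 512
  ts <- (seq_len(n) - 1) / 255.9
  s <- stream_series("GSR", 256, ts, matrix(0, n, 1))
  rec <- session_recording(list(GSR = s))
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_false(back$metadata$rate_checks$GSR$dejittered)
  expect_identical(back$streams$GSR$timestamps, ts)
  expect_equal(back$metadata$rate_checks$GSR$realized, 255.9, tolerance = 1e-9)

  # 2 ms jitter on a 100 Hz stream: de-jittered onto the least-squares grid
  j <- make_stream(n = 400, rate = 100, jitter = 0.002, seed = 4)
  dir2 <- withr::local_tempdir()
  write_recording(session_recording(list(S = j)), dir2)
  back2 <- read_recording(dir2)
  expect_true(back2$metadata$rate_checks$S$dejittered)
  out_ts <- back2$streams$S$timestamps
  expect_equal(diff(out_ts), rep(diff(out_ts)[1], 399), tolerance = 1e-9)
  # the recovered grid deviates from the raw timestamps by < 1 sample period
  expect_lt(max(abs(out_ts - j$timestamps)), 1 / 100)
  # sample values are untouched
  expect_identical(back2$streams$S$samples, unname(j$samples))
})

test_that("de-jitter fits the least-squares grid and is idempotent", {
  s <- stream_series("S", 10, c(0, 0.11, 0.19, 0.30), matrix(1:4, 4, 1))
  d1 <- dejitter_timestamps(s)
  # closed-form least-squares line fit as the oracle
  k <- 0:3
  fit <- stats::lm(c(0, 0.11, 0.19, 0.30) ~ k)
  expect_equal(d1$timestamps, unname(fit$fitted.values))
  delta <- diff(d1$timestamps)[1]
  expect_equal(delta, unname(stats::coef(fit)["k"]))
  expect_lt(abs(delta - 0.1) / 0.1, 0.05)
  d2 <- dejitter_timestamps(d1)
  expect_equal(d2$timestamps, d1$timestamps, tolerance = 1e-12)
  expect_identical(d2$samples, d1$samples)
  # already-uniform grids are fixed points
  u <- make_stream(n = 50, rate = 20)
  expect_equal(dejitter_timestamps(u)$timestamps, u$timestamps,
               tolerance = 1e-12)
  irregular <- stream_series("M", 0, c(0, 1, 5), matrix(0, 3, 1))
  expect_error(dejitter_timestamps(irregular),
               class = "mwlfuse_invalid_argument")
})

test_that("effective rate is intervals over realized span", {
  ts <- seq(0, 8, length.out = 2048)
  s <- stream_series("S", 256, ts, matrix(0, 2048, 1))
  expect_equal(effective_rate(s), 2047 / 8)
  u <- make_stream(n = 240, rate = 120)
  expect_equal(effective_rate(u), 120, tolerance = 1e-9)
  j <- make_stream(n = 1000, rate = 100, jitter = 0.001, seed = 2)
  expect_lt(abs(effective_rate(j) - 100), 0.5)
  one <- stream_series("S", 10, 0, matrix(0, 1, 1))
  expect_error(effective_rate(one), class = "mwlfuse_invalid_argument")
})

test_that("drift report recovers injected clock drift", {
  perfect <- make_stream(n = 500, rate = 50)
  expect_identical(drift_report(session_recording(list(A = perfect)))$per_stream$drift_ms,
                   0)
  # stretch timestamps so the realized span exceeds nominal by 0.5 s
  n <- 1000; rate <- 50
  span <- (n - 1) / rate
  ts <- ((seq_len(n) - 1) / rate) * (1 + 0.5 / span)
  drifted <- stream_series("B", rate, ts, matrix(0, n, 1))
  rep <- drift_report(session_recording(list(A = perfect, B = drifted)))
  b <- rep$per_stream$drift_ms[rep$per_stream$stream == "B"]
  expect_lt(abs(b - 500), 1000 / rate)
  expect_equal(rep$mean_ms, mean(rep$per_stream$drift_ms))
  expect_equal(rep$sd_ms, stats::sd(rep$per_stream$drift_ms))
})

test_that("markers outside the stream time range are flagged, not dropped", {
  s <- make_stream(n = 100, rate = 10)       # spans ~10 s
  mk <- data.frame(timestamp = c(5, 42), participant_id = "P",
                   action_type = "select_answer", action_id = c("a1", "a2"),
                   status = "correct")
  rec <- session_recording(list(S = s), mk)
  expect_identical(nrow(rec$markers), 2L)
  expect_identical(rec$metadata$flagged_markers, 2L)
})
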