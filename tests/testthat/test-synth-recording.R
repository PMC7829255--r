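test_that("canonical HRF starts at zero, peaks in 5-8 s and is linear in gain", {
  t <- seq(0, 30, by = 0.05)
  h <- canonical_hrf(t)
  expect_identical(h[1], 0)
  peak_t <- t[which.max(h)]
  expect_gte(peak_t, 5); expect_lte(peak_t, 8)
  # single positive peak followed by a shallow undershoot
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.5 * max(h))
  expect_equal(canonical_hrf(t, gain = 2.5), 2.5 * h)
  expect_error(canonical_hrf(c(1, 0.5)), class = "mwlfuse_invalid_argument")
})

test_that("HRF convolution is additive over impulses (discrete-convolution oracle)", {
  dt <- 0.1
  n <- 300
  imp1 <- numeric(n); imp1[11] <- 1            # impulse at 1 s
  imp2 <- numeric(n); imp2[41] <- 1            # impulse at 4 s (3 s later)
  both <- imp1 + imp2
  expect_equal(hrf_convolve(both, dt),
               hrf_convolve(imp1, dt) + hrf_convolve(imp2, dt),
               tolerance = 1e-10)
  # oracle: direct O(n^2) convolution sum
  kernel <- canonical_hrf(seq(0, 30, by = dt)) * dt
  direct <- vapply(seq_len(n), function(i) {
    j <- seq_len(min(i, length(kernel)))
    sum(both[i - j + 1] * kernel[j])
  }, numeric(1))
  expect_equal(hrf_convolve(both, dt), direct, tolerance = 1e-8)
})

test_that("simulated modalities have declared shapes, rates and sample counts", {
  prof <- participant_profile()
  flat <- data.frame(start = 0, end = 8, difficulty = 3)
  for (m in c("GSR", "PPG", "ET", "fNIRS")) {
    empty <- simulate_modality(m, 0, flat, prof, seed = 1)
    expect_identical(length(empty$timestamps), 0L)
    expect_identical(ncol(empty$samples),
                     c(GSR = 1L, PPG = 1L, ET = 4L, fNIRS = 54L)[[m]])
  }
  gsr <- simulate_modality("GSR", 8, flat, prof, rate = 256, seed = 1)
  expect_identical(nrow(gsr$samples), 2048L)
  # exact grid when no jitter/drift is applied
  expect_equal(diff(gsr$timestamps), rep(1 / 256, 2047), tolerance = 1e-12)
  fn <- simulate_modality("fNIRS", 8, flat, prof, rate = 10, seed = 1)
  expect_identical(dim(fn$samples), c(80L, 54L))
  expect_error(simulate_modality("EEG", 1, flat, prof, rate = 10),
               class = "mwlfuse_invalid_argument")
})

test_that("paired HHb channels are anti-correlated with O2Hb under activity", {
  box <- data.frame(start = c(10, 60), end = c(40, 90), difficulty = c(3, 5))
  fn <- simulate_modality("fNIRS", 120, box, participant_profile(),
                          rate = 10, seed = 3)
  cors <- vapply(1:27, function(ci) {
    stats::cor(fn$samples[, 2 * ci - 1], fn$samples[, 2 * ci])
  }, numeric(1))
  expect_lt(mean(cors), -0.3)
})

test_that("workload-sensitive statistics increase with difficulty over seeds", {
  prof <- participant_profile()
  stat_at <- function(d, seed) {
    flat <- data.frame(start = 0, end = 60, difficulty = d)
    gsr <- simulate_modality("GSR", 60, flat, prof, rate = 64, seed = seed)
    ppg <- simulate_modality("PPG", 60, flat, prof, rate = 64, seed = seed)
    et <- simulate_modality("ET", 60, flat, prof, rate = 30, seed = seed)
    fnirs <- simulate_modality("fNIRS", 60, flat, prof, rate = 10, seed = seed)
    c(scr = length(attr(gsr, "scr_times")),
      hr = attr(ppg, "hr_mean"),
      fix = length(attr(et, "fixation_times")),
      o2hb = max(fnirs$samples[, 1]))
  }
  lo <- rowMeans(vapply(1:50, function(s) stat_at(1, s), numeric(4)))
  hi <- rowMeans(vapply(1:50, function(s) stat_at(5, s), numeric(4)))
  expect_gt(hi[["scr"]], lo[["scr"]])
  expect_gt(hi[["hr"]], lo[["hr"]])
  expect_gt(hi[["fix"]], lo[["fix"]])
  expect_gt(hi[["o2hb"]], lo[["o2hb"]])
})

test_that("marker generation respects the schedule and logs its own count", {
  sched <- data.frame(start = c(10, 60), end = c(50, 100),
                      puzzle_id = c("puzzle1", "puzzle2"),
                      difficulty = c(2, 4))
  mk <- generate_markers(sched, seed = 5)
  expect_identical(nrow(mk), attr(mk, "action_count"))
  expect_true(all(c("timestamp", "participant_id", "action_type",
                    "action_id", "status") %in% names(mk)))
  expect_false(is.unsorted(mk$timestamp))
  pz <- marker_puzzles(mk)
  expect_identical(pz, attr(mk, "puzzle_id"))
  for (i in seq_len(nrow(mk))) {
    row <- sched[sched$puzzle_id == pz[i], ]
    expect_gte(mk$timestamp[i], row$start)
    expect_lte(mk$timestamp[i], row$end)
  }
  empty <- generate_markers(sched[0, ], seed = 1)
  expect_identical(nrow(empty), 0L)
  overlap <- data.frame(start = c(0, 5), end = c(10, 15),
                        puzzle_id = c("a", "b"), difficulty = c(1, 1))
  expect_error(generate_markers(overlap), class = "mwlfuse_invalid_argument")
})

test_that("simulate_session is deterministic and ratings stay in 1..7", {
  cfg <- sim_config(n_puzzles = 2L, puzzle_difficulties = c(2, 5),
                    puzzle_duration = 20, rest_duration = 5, seed = 42)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  full <- short_session(seed = 3)
  expect_true(all(full$truth$puzzles$rating >= 1 &
                    full$truth$puzzles$rating <= 7))
  # a default session yields a realistic per-participant marker count
  n_markers <- nrow(simulate_session(sim_config(seed = 8))$recording$markers)
  expect_gte(n_markers, 100); expect_lte(n_markers, 300)
})

test_that("injected drift and gaps are recovered by the stream audit", {
  cfg <- sim_config(n_puzzles = 2L, puzzle_difficulties = c(2, 4),
                    puzzle_duration = 30, rest_duration = 5,
                    clock_drift = c(ET = 0.5),
                    missing_gaps = list(list(start = 20, duration = 1.5,
                                             stream = "GSR")),
                    seed = 9)
  sim <- simulate_session(cfg)
  rep <- drift_report(sim$recording)
  et_drift <- rep$per_stream$drift_ms[rep$per_stream$stream == "ET"]
  expect_lt(abs(et_drift - 500), 1000 / 120)   # within one ET sample period
  gaps <- gap_report(sim$recording$streams$GSR)
  expect_identical(nrow(gaps), 1L)
  expect_lt(abs(gaps$duration - 1.5), 1 / 256) # within one sample period
  # report mean is the arithmetic mean of the per-stream drifts
  expect_equal(rep$mean_ms, mean(rep$per_stream$drift_ms))
})
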