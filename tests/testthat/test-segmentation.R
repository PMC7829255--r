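test_that("nearest index minimizes distance with lower-index ties", {
  expect_identical(nearest_index(c(0, 0.1, 0.2), 0.14), 2L)
  expect_identical(nearest_index(c(0, 0.1, 0.2), 0.1), 2L)
  expect_identical(nearest_index(c(0, 0.1), 0.05), 1L)   # midpoint tie: lower
  expect_identical(nearest_index(c(0, 0.1, 0.2), -3), 1L)
  expect_identical(nearest_index(c(0, 0.1, 0.2), 99), 3L)
  expect_error(nearest_index(numeric(), 1), class = "mwlfuse_invalid_argument")
  # linear-scan oracle over random grids and queries
  set.seed(21)
  for (rep in 1:20) {
    ts <- sort(stats::runif(30))
    q <- stats::runif(10, -0.2, 1.2)
    oracle <- vapply(q, function(tt) {
      best <- 1L
      for (i in seq_along(ts)) {
        if (abs(ts[i] - tt) < abs(ts[best] - tt)) best <- i
      }
      best
    }, integer(1))
    expect_identical(nearest_index(ts, q), oracle)
  }
})

test_that("marker selection removes collisions, short histories and gap windows", {
  sim <- memo("seg_session", function() short_session(seed = 13))
  rec <- sim$recording
  mask <- select_markers(rec)
  expect_identical(length(mask), nrow(rec$markers))

  # hand-built recording: 10 Hz stream, markers 1 ms apart share an index
  ts <- (0:299) / 10
  s10 <- stream_series("fNIRS", 10, ts, matrix(0, 300, 54))
  mk <- data.frame(timestamp = c(12, 20, 20.001, 25, 3),
                   participant_id = "P", action_type = "select_answer",
                   action_id = paste0("puzzle1_a", 1:5), status = "correct")
  rec2 <- session_recording(list(fNIRS = s10), mk)
  m2 <- select_markers(rec2, segmentation_config(window_length = 8))
  # markers sorted by time: 3 s (too early), 12, 20, 20.001 (collide), 25
  expect_identical(m2, c(FALSE, TRUE, FALSE, FALSE, TRUE))

  # two markers 5 s apart with ample data both survive
  mk3 <- mk[c(1, 4), ]
  rec3 <- session_recording(list(fNIRS = s10), mk3)
  expect_identical(select_markers(rec3), c(TRUE, TRUE))
})

test_that("selection agrees with a brute-force all-pairs oracle on small sessions", {
  set.seed(31)
  for (rep in 1:5) {
    n_mark <- sample(5:20, 1)
    streams <- list(
      A = stream_series("A", 32, (0:2047) / 32,
                        matrix(0, 2048, 1)),              # 64 s at 32 Hz
      B = stream_series("B", 5, (0:319) / 5, matrix(0, 320, 2))
    )
    mk <- data.frame(timestamp = sort(stats::runif(n_mark, 0, 64)),
                     participant_id = "P", action_type = "x",
                     action_id = paste0("puzzle1_a", seq_len(n_mark)),
                     status = "checked")
    # force occasional collisions on the slow stream
    if (n_mark > 3) mk$timestamp[2] <- mk$timestamp[3] + 0.01
    mk <- mk[order(mk$timestamp), ]
    rec <- session_recording(streams, mk)
    cfg <- segmentation_config(window_length = 8)
    got <- select_markers(rec, cfg)
    oracle <- rep(TRUE, n_mark)
    for (s in streams) {
      ni <- vapply(rec$markers$timestamp, function(tt) {
        which.min(abs(s$timestamps - tt))
      }, integer(1))
      for (i in seq_len(n_mark)) {
        if (sum(ni == ni[i]) > 1) oracle[i] <- FALSE
        n_win <- round(8 * s$nominal_rate)
        i_end <- max(which(s$timestamps <= rec$markers$timestamp[i]), 0L)
        if (i_end < n_win) oracle[i] <- FALSE
      }
    }
    expect_identical(got, oracle)
  }
})

test_that("adding a marker never turns a masked-out marker back on", {
  sim <- memo("seg_session", function() short_session(seed = 13))
  rec <- sim$recording
  base_mask <- select_markers(rec)
  extra <- rec$markers[7, ]
  extra$timestamp <- extra$timestamp + 1e-4   # collides with marker 7
  extra$action_id <- "puzzle1_a999"
  mk2 <- rbind(rec$markers, extra)
  rec2 <- session_recording(rec$streams, mk2, rec$metadata)
  ord <- order(mk2$timestamp)
  new_mask <- select_markers(rec2)
  # map old markers to their rows in the enlarged recording
  old_rows <- match(rec$markers$action_id, rec2$markers$action_id)
  expect_true(all(new_mask[old_rows] <= base_mask))
})

test_that("extracted windows have native-rate row counts and exact contents", {
  sim <- memo("seg_session", function() short_session(seed = 13))
  rec <- sim$recording
  mask <- select_markers(rec)
  mt <- rec$markers$timestamp[which(mask)[1]]
  expect_identical(dim(extract_window(rec$streams$GSR, mt)), c(2048L, 1L))
  expect_identical(dim(extract_window(rec$streams$PPG, mt)), c(2048L, 1L))
  expect_identical(dim(extract_window(rec$streams$ET, mt)), c(960L, 4L))
  expect_identical(dim(extract_window(rec$streams$fNIRS, mt)), c(80L, 54L))
  # contents equal index-arithmetic slicing of the raw matrix
  s <- rec$streams$fNIRS
  i_end <- max(which(s$timestamps <= mt))
  expect_identical(extract_window(s, mt),
                   s$samples[(i_end - 79):i_end, ])
  expect_error(extract_window(s, s$timestamps[10]),
               class = "mwlfuse_window_error")
})

test_that("sample sets carry one sample per selected marker with conserved counts", {
  sim <- memo("seg_session", function() short_session(seed = 13))
  ss <- build_sample_set(sim$recording, ratings_of(sim))
  mask <- select_markers(sim$recording)
  expect_identical(length(ss$samples), sum(mask))
  expect_identical(sum(ss$label_counts), sum(mask))
  labels <- vapply(ss$samples, `[[`, numeric(1), "label")
  expect_true(all(labels >= 0 & labels <= 1))
  # every sample's label matches its puzzle's rating
  for (s in ss$samples[1:5]) {
    r <- sim$truth$puzzles$rating[sim$truth$puzzles$puzzle_id == s$puzzle_id]
    expect_identical(s$label, individual_label(r))
  }
  # missing rating errors with the puzzle named
  bad <- ratings_of(sim)[-1, ]
  expect_error(build_sample_set(sim$recording, bad),
               class = "mwlfuse_missing_rating", regexp = "puzzle1")
  # empty recording gives an empty set
  empty_rec <- session_recording(sim$recording$streams, empty_markers())
  ss0 <- build_sample_set(empty_rec, ratings_of(sim))
  expect_identical(length(ss0$samples), 0L)
})

test_that("sample statistics summarize labels and window quality", {
  sim <- memo("seg_session", function() short_session(seed = 13))
  ss <- build_sample_set(sim$recording, ratings_of(sim))
  st <- sample_stats(ss)
  expect_equal(sum(st$label_table$percent), 100)
  q <- st$quality$GSR
  expect_true(all(q["min", ] <= q["mean", ] & q["mean", ] <= q["max", ]))
  labs <- mwlfuse:::set_labels(ss)
  single <- mwlfuse:::subset_samples(ss, which(labs == labs[1]))
  st1 <- sample_stats(single)
  expect_identical(nrow(st1$label_table), 1L)
  expect_equal(st1$label_table$percent, 100)
  expect_error(sample_stats(mwlfuse:::new_sample_set(list(), "individual")),
               class = "mwlfuse_invalid_argument")
})

test_that("sample sets round-trip through sharded record files", {
  sim <- memo("seg_session", function() short_session(seed = 13))
  ss <- build_sample_set(sim$recording, ratings_of(sim))
  dir <- withr::local_tempdir()
  write_sample_set(ss, dir, shard_size = 7L)
  back <- read_sample_set(dir)
  expect_identical(length(back$samples), length(ss$samples))
  expect_identical(back$labelling_scheme, ss$labelling_scheme)
  expect_identical(back$samples[[3]]$windows$fNIRS, ss$samples[[3]]$windows$fNIRS)
})
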