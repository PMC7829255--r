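# Shared fixtures, generated in code. Heavy objects are memoized per test
# run so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) assign(key, fn(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# A short three-puzzle session: enough markers for segmentation tests while
# staying fast (~0.4 s to simulate).
short_session <- function(seed = 7, ...) {
  cfg <- sim_config(n_puzzles = 3L, puzzle_difficulties = c(1, 3, 5),
                    puzzle_duration = 40, rest_duration = 10,
                    seed = seed, ...)
  simulate_session(cfg)
}

ratings_of <- function(sim) {
  data.frame(puzzle_id = sim$truth$puzzles$puzzle_id,
             rating = sim$truth$puzzles$rating)
}

# Tiny window shapes for fast model tests (a spec's input shapes are free).
tiny_shapes <- list(PPG = c(32L, 1L), GSR = c(32L, 1L),
                    ET = c(16L, 4L), fNIRS = c(8L, 6L))

# Toy multimodal samples whose labels are carried by the window means of
# every modality, so both unimodal and fused models can learn them.
toy_samples <- function(n, shapes = tiny_shapes, seed = 1, signal = 1) {
  set.seed(seed)
  labels <- sample((0:6) / 6, n, replace = TRUE)
  samples <- lapply(seq_len(n), function(i) {
    windows <- lapply(shapes, function(s) {
      matrix(stats::rnorm(s[1] * s[2], mean = signal * labels[i], sd = 0.3),
             s[1], s[2])
    })
    list(windows = windows, label = labels[i], participant_id = "T01",
         puzzle_id = "puzzle1", marker_time = i)
  })
  mwlfuse:::new_sample_set(samples, "individual")
}

# The study-scale synthetic dataset: two simulated participants under the
# default session conditions (~400 samples, individual labels).
study_sample_set <- function() {
  memo("study_set", function() {
    sets <- lapply(1:2, function(p) {
      cfg <- sim_config(participant_id = sprintf("P%02d", p), seed = 100 + p)
      sim <- simulate_session(cfg)
      build_sample_set(sim$recording, ratings_of(sim))
    })
    do.call(combine_sample_sets, sets)
  })
}
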