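#' Participant profile for the session simulator
#'
#' Baseline physiology and workload sensitivities of one simulated
#' participant. All sensitivities are per unit of nominal puzzle difficulty
#' (1--5 scale).
#'
#' @param base_hr Resting heart rate, beats/min.
#' @param hr_sens Heart-rate increase per difficulty unit, beats/min.
#' @param tonic_level Tonic skin conductance level, microsiemens.
#' @param tonic_sens Tonic conductance increase per difficulty unit, uS.
#' @param scr_base Baseline phasic SCR rate, events/min.
#' @param scr_sens SCR-rate increase per difficulty unit, events/min.
#' @param hrf_gain Haemodynamic response gain per difficulty unit (a.u.).
#' @param fix_base Baseline fixation rate, fixations/s.
#' @param fix_sens Fixation-rate increase per difficulty unit, fixations/s.
#' @param rating_bias Additive bias of the simulated 7-point rating.
#' @param rating_noise_sd SD of rating noise, 7-point scale units.
#' @return A list of profile parameters.
#' @export
participant_profile <- function(base_hr = 68, hr_sens = 3,
                                tonic_level = 2, tonic_sens = 0.4,
                                scr_base = 4, scr_sens = 3,
                                hrf_gain = 1,
                                fix_base = 1.5, fix_sens = 0.4,
                                rating_bias = 0, rating_noise_sd = 0.5) {
  if (rating_noise_sd < 0) stop_invalid("rating_noise_sd must be >= 0")
  list(base_hr = base_hr, hr_sens = hr_sens, tonic_level = tonic_level,
       tonic_sens = tonic_sens, scr_base = scr_base, scr_sens = scr_sens,
       hrf_gain = hrf_gain, fix_base = fix_base, fix_sens = fix_sens,
       rating_bias = rating_bias, rating_noise_sd = rating_noise_sd)
}

#' Configuration of one simulated recording session
#'
#' Defines the puzzle schedule, participant, stream rates and clock
#' imperfections of one synthetic session. Defaults give five puzzles of
#' nominal difficulty 1--5, 120 s each with 10 s rest in between, and an
#' action-rate model of `12 + 3 * difficulty` markers per minute, so a
#' default session yields on the order of 150--250 markers.
#'
#' @param n_puzzles Number of puzzles (`>= 0`).
#' @param puzzle_difficulties Ordered nominal difficulties, one per puzzle,
#'   on the 1--5 scale.
#' @param puzzle_duration Seconds per puzzle.
#' @param rest_duration Rest seconds between puzzles (and before the first).
#' @param profile A [participant_profile()].
#' @param stream_rates Named Hz vector for `GSR`, `PPG`, `ET`, `fNIRS`.
#' @param action_rate Function mapping difficulty to actions/min.
#' @param jitter_sd Timestamp jitter SD in seconds (applied per stream).
#' @param clock_drift Named numeric: seconds of clock drift accumulated over
#'   the session per stream (e.g. `c(ET = 0.5)`).
#' @param missing_gaps List of gaps, each `list(start =, duration =,
#'   stream =)`; `stream = NULL` applies the gap to every signal stream.
#' @param participant_id Participant identifier string.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_puzzles = 5L,
                       puzzle_difficulties = seq_len(n_puzzles),
                       puzzle_duration = 120,
                       rest_duration = 10,
                       profile = participant_profile(),
                       stream_rates = DEFAULT_RATES,
                       action_rate = function(difficulty) 12 + 3 * difficulty,
                       jitter_sd = 0,
                       clock_drift = numeric(),
                       missing_gaps = list(),
                       participant_id = "P01",
                       seed = 1L) {
  if (n_puzzles < 0) stop_invalid("n_puzzles must be >= 0")
  if (length(puzzle_difficulties) != n_puzzles) {
    stop_invalid("puzzle_difficulties must have one entry per puzzle")
  }
  if (any(stream_rates <= 0)) stop_invalid("stream rates must be positive")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  structure(
    list(n_puzzles = as.integer(n_puzzles),
         puzzle_difficulties = as.numeric(puzzle_difficulties),
         puzzle_duration = puzzle_duration, rest_duration = rest_duration,
         profile = profile, stream_rates = stream_rates,
         action_rate = action_rate, jitter_sd = jitter_sd,
         clock_drift = clock_drift, missing_gaps = missing_gaps,
         participant_id = participant_id, seed = as.integer(seed)),
    class = "sim_config"
  )
}

puzzle_schedule <- function(config) {
  n <- config$n_puzzles
  if (n == 0L) {
    return(data.frame(start = numeric(), end = numeric(),
                      puzzle_id = character(), difficulty = numeric()))
  }
  start <- config$rest_duration +
    (seq_len(n) - 1) * (config$puzzle_duration + config$rest_duration)
  data.frame(start = start, end = start + config$puzzle_duration,
             puzzle_id = sprintf("puzzle%d", seq_len(n)),
             difficulty = config$puzzle_difficulties,
             stringsAsFactors = FALSE)
}

#' Generate marker events for a puzzle schedule
#'
#' Actions (hint and answer selections) occur as a Poisson process within
#' each puzzle interval at `action_rate(difficulty)` events per minute. Every
#' marker carries the participant id, its timestamp, an action type, an
#' action id that encodes the puzzle it belongs to, and a status.
#'
#' @param schedule Data frame with columns `start`, `end`, `puzzle_id`,
#'   `difficulty`; intervals must not overlap.
#' @param action_rate Function difficulty -> actions/min.
#' @param participant_id Participant identifier.
#' @param seed Integer seed.
#' @return Marker data frame (see [empty_markers()]), ascending in time, with
#'   attributes `puzzle_id` (per-marker puzzle) and `action_count` (the
#'   generator's own event count, usable as a test oracle).
#' @export
generate_markers <- function(schedule, action_rate = function(d) 12 + 3 * d,
                             participant_id = "P01", seed = 1L) {
  if (nrow(schedule) > 1L) {
    s <- schedule[order(schedule$start), ]
    if (any(s$start[-1] < s$end[-nrow(s)])) {
      stop_invalid("puzzle intervals must not overlap")
    }
  }
  set.seed(seed)
  out <- empty_markers()
  puzzle_of <- character()
  types <- c("select_hint", "unselect_hint", "select_answer", "unselect_answer")
  statuses <- c("correct", "incorrect", "checked")
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    lambda <- action_rate(row$difficulty) / 60
    k <- stats::rpois(1, lambda * (row$end - row$start))
    if (k == 0) next
    ts <- sort(stats::runif(k, row$start, row$end))
    out <- rbind(out, data.frame(
      timestamp = ts,
      participant_id = participant_id,
      action_type = sample(types, k, replace = TRUE,
                           prob = c(0.35, 0.1, 0.45, 0.1)),
      action_id = sprintf("%s_a%03d", row$puzzle_id, seq_len(k)),
      status = sample(statuses, k, replace = TRUE, prob = c(0.5, 0.2, 0.3)),
      stringsAsFactors = FALSE))
    puzzle_of <- c(puzzle_of, rep(row$puzzle_id, k))
  }
  rownames(out) <- NULL
  attr(out, "puzzle_id") <- puzzle_of
  attr(out, "action_count") <- nrow(out)
  out
}

#' Extract the puzzle id encoded in marker action ids
#'
#' Action ids take the form `<puzzle_id>_a<number>`; this recovers the
#' puzzle id for each marker.
#'
#' @param markers Marker data frame.
#' @return Character vector of puzzle ids.
#' @export
marker_puzzles <- function(markers) {
  sub("_a[0-9]+$", "", markers$action_id)
}

apply_clock_model <- function(stream, drift_s, jitter_sd, gaps, seed) {
  set.seed(seed)
  ts <- stream$timestamps
  n <- length(ts)
  if (n == 0L) return(stream)
  span <- ts[n] - ts[1]
  if (drift_s != 0 && span > 0) ts <- ts[1] + (ts - ts[1]) * (1 + drift_s / span)
  if (jitter_sd > 0) ts <- sort(ts + stats::rnorm(n, sd = jitter_sd))
  keep <- rep(TRUE, n)
  for (g in gaps) {
    if (is.null(g$stream) || identical(g$stream, stream$name)) {
      keep <- keep & !(ts >= g$start & ts < g$start + g$duration)
    }
  }
  stream_series(stream$name, stream$nominal_rate, ts[keep],
                stream$samples[keep, , drop = FALSE],
                channel_labels = stream$channel_labels)
}

#' Simulate a complete multi-stream session recording
#'
#' Runs the per-modality simulators over the puzzle schedule of `config`,
#' applies the configured clock imperfections (jitter, drift, missing-data
#' gaps), generates the marker stream, and draws the participant's simulated
#' 7-point difficulty ratings: the nominal 1--5 difficulty is mapped linearly
#' onto 1--7, the participant's rating bias and Gaussian noise are added, and
#' the result is rounded and clipped to \[1, 7\].
#'
#' @param config A [sim_config()].
#' @return List with elements `recording` (a [session_recording()]) and
#'   `truth` (list: `puzzles` data frame with `puzzle_id`, `difficulty`,
#'   `rating`; `marker_puzzle` character vector assigning each marker to its
#'   puzzle).
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "sim_config")) stop_invalid("config must be a sim_config")
  schedule <- puzzle_schedule(config)
  duration <- if (nrow(schedule)) max(schedule$end) + config$rest_duration
              else config$rest_duration
  streams <- list()
  for (m in MODALITIES) {
    raw <- simulate_modality(m, duration, schedule, profile = config$profile,
                             rate = config$stream_rates[[m]],
                             seed = config$seed + match(m, MODALITIES))
    drift <- if (m %in% names(config$clock_drift)) config$clock_drift[[m]] else 0
    streams[[m]] <- apply_clock_model(raw, drift, config$jitter_sd,
                                      config$missing_gaps,
                                      seed = config$seed + 100L + match(m, MODALITIES))
  }
  markers <- generate_markers(schedule, config$action_rate,
                              config$participant_id, seed = config$seed + 200L)
  set.seed(config$seed + 300L)
  mapped <- 1 + (schedule$difficulty - 1) * 6 / 4
  rating <- pmin(pmax(round(mapped + config$profile$rating_bias +
                            stats::rnorm(nrow(schedule),
                                         sd = config$profile$rating_noise_sd)),
                      1), 7)
  truth <- list(
    puzzles = data.frame(puzzle_id = schedule$puzzle_id,
                         difficulty = schedule$difficulty,
                         rating = as.integer(rating),
                         stringsAsFactors = FALSE),
    marker_puzzle = attr(markers, "puzzle_id") %||% character()
  )
  recording <- session_recording(
    streams, markers,
    metadata = list(participant_id = config$participant_id,
                    simulated = TRUE, seed = config$seed)
  )
  list(recording = recording, truth = truth)
}

#' Write the simulated ground truth as a sidecar ratings CSV
#'
#' @param truth The `truth` element returned by [simulate_session()].
#' @param participant_id Participant identifier.
#' @param path Output CSV path (`participant_id`, `puzzle_id`, `rating`).
#' @return `path`, invisibly.
#' @export
write_ratings <- function(truth, participant_id, path) {
  df <- data.frame(participant_id = participant_id,
                   puzzle_id = truth$puzzles$puzzle_id,
                   rating = truth$puzzles$rating)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
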