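#' Segmentation configuration
#'
#' @param window_length Pre-marker window length in seconds (default 8; the
#'   haemodynamic response peaks 5--8 s after activity onset, so an 8 s
#'   window captures the response to the contemplation preceding an action).
#' @param gap_factor Multiple of the nominal period treated as a
#'   missing-data gap when screening windows (see [gap_report()]).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(window_length = 8, gap_factor = 2.5) {
  if (window_length <= 0) stop_invalid("window_length must be > 0")
  structure(list(window_length = window_length, gap_factor = gap_factor),
            class = "segmentation_config")
}

#' Index of the timestamp nearest to a query time
#'
#' Returns the index minimizing `|timestamps[i] - t|`; exact midpoint ties
#' are broken toward the lower index.
#'
#' @param timestamps Ascending numeric vector (non-empty).
#' @param t Query time(s) in seconds.
#' @return Integer index (1-based), vectorized over `t`.
#' @export
nearest_index <- function(timestamps, t) {
  if (length(timestamps) == 0L) stop_invalid("timestamps must be non-empty")
  lo <- findInterval(t, timestamps)
  lo_c <- pmin(pmax(lo, 1L), length(timestamps))
  hi_c <- pmin(lo + 1L, length(timestamps))
  d_lo <- abs(t - timestamps[lo_c])
  d_hi <- abs(timestamps[hi_c] - t)
  out <- ifelse(lo < 1L, 1L, ifelse(d_lo <= d_hi, lo_c, hi_c))
  as.integer(out)
}

# Index of last timestamp at or before t (0 when none).
index_at_or_before <- function(timestamps, t) {
  findInterval(t, timestamps)
}

window_rows <- function(window_length, rate) as.integer(round(window_length * rate))

#' Select usable markers via Boolean masks
#'
#' A marker is kept only if, in every signal stream, (a) its nearest sample
#' index is not shared with any other marker (all colliding markers are
#' removed, not just duplicates after the first -- identical indices signal
#' drifting clocks or missing data), (b) a full window of
#' `config$window_length` seconds of data exists before it, and (c) the
#' window does not span a missing-data gap.
#'
#' @param recording A [session_recording()].
#' @param config A [segmentation_config()].
#' @return Logical mask over rows of `recording$markers`.
#' @export
select_markers <- function(recording, config = segmentation_config()) {
  markers <- recording$markers
  n <- nrow(markers)
  if (n == 0L) return(logical())
  mask <- rep(TRUE, n)
  for (s in recording$streams) {
    if (s$nominal_rate <= 0 || n_samples(s) == 0L) next
    ni <- nearest_index(s$timestamps, markers$timestamp)
    dup <- ni %in% ni[duplicated(ni)]
    mask <- mask & !dup
    n_win <- window_rows(config$window_length, s$nominal_rate)
    i_end <- index_at_or_before(s$timestamps, markers$timestamp)
    enough <- i_end >= n_win
    mask <- mask & enough
    # a window spanning a gap covers more wall time than n_win samples should
    ok_span <- enough
    idx <- which(enough)
    if (length(idx)) {
      t_end <- s$timestamps[i_end[idx]]
      t_start <- s$timestamps[i_end[idx] - n_win + 1L]
      expected <- (n_win - 1L) / s$nominal_rate
      ok_span[idx] <- (t_end - t_start) <= expected + config$gap_factor / s$nominal_rate
    }
    mask <- mask & ok_span
  }
  mask
}

#' Extract one pre-marker window from a stream
#'
#' The window ends at the nearest sample at or before `marker_time` and
#' contains `round(window_length * nominal_rate)` rows; channel order is
#' preserved.
#'
#' @param stream A [stream_series()].
#' @param marker_time Marker timestamp in seconds.
#' @param window_length Window length in seconds.
#' @return Numeric matrix (time x channels).
#' @export
extract_window <- function(stream, marker_time, window_length = 8) {
  n_win <- window_rows(window_length, stream$nominal_rate)
  i_end <- index_at_or_before(stream$timestamps, marker_time)
  if (i_end < n_win) {
    stop(errorCondition(
      sprintf("insufficient data before marker at %.3f s in stream '%s' (%d of %d samples)",
              marker_time, stream$name, i_end, n_win),
      class = c("mwlfuse_window_error", "error")))
  }
  stream$samples[(i_end - n_win + 1L):i_end, , drop = FALSE]
}

#' Assemble the labelled multimodal sample set
#'
#' One multimodal sample is created per selected marker: a pre-marker window
#' from every signal stream at its native rate, labelled with the rating or
#' label of the marker's puzzle.
#'
#' @param recording A [session_recording()].
#' @param ratings Data frame with columns `puzzle_id` and either `label`
#'   (already in \[0, 1\]) or `rating` (integer 1--7, mapped through
#'   [individual_label()]).
#' @param config A [segmentation_config()].
#' @param scheme Labelling scheme recorded on the set (`"individual"` or
#'   `"group"`).
#' @return A `sample_set`: list of samples (each with `windows`, `label`,
#'   `participant_id`, `puzzle_id`, `marker_time`), plus the scheme, the
#'   per-label counts and the selection mask.
#' @export
build_sample_set <- function(recording, ratings,
                             config = segmentation_config(),
                             scheme = c("individual", "group")) {
  scheme <- match.arg(scheme)
  mask <- select_markers(recording, config)
  markers <- recording$markers[mask, , drop = FALSE]
  puzzles <- marker_puzzles(markers)
  missing <- setdiff(unique(puzzles), ratings$puzzle_id)
  if (length(missing)) {
    stop(errorCondition(
      paste0("no rating for puzzle(s): ", paste(missing, collapse = ", ")),
      class = c("mwlfuse_missing_rating", "error")))
  }
  if (!is.null(ratings$label)) {
    labels <- ratings$label[match(puzzles, ratings$puzzle_id)]
  } else {
    labels <- individual_label(ratings$rating[match(puzzles, ratings$puzzle_id)])
  }
  signal <- Filter(function(s) s$nominal_rate > 0, recording$streams)
  samples <- vector("list", nrow(markers))
  for (i in seq_len(nrow(markers))) {
    windows <- lapply(signal, extract_window,
                      marker_time = markers$timestamp[i],
                      window_length = config$window_length)
    samples[[i]] <- list(windows = windows, label = labels[i],
                         participant_id = markers$participant_id[i],
                         puzzle_id = puzzles[i],
                         marker_time = markers$timestamp[i])
  }
  new_sample_set(samples, scheme, mask = mask)
}

new_sample_set <- function(samples, scheme, mask = NULL) {
  labels <- vapply(samples, `[[`, numeric(1), "label")
  counts <- if (length(labels)) table(format(labels, digits = 10)) else table(numeric())
  structure(list(samples = samples, labelling_scheme = scheme,
                 label_counts = counts, selection_mask = mask),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set: %d samples, %s labels, %d distinct labels>\n",
              length(x$samples), x$labelling_scheme, length(x$label_counts)))
  invisible(x)
}

#' @export
length.sample_set <- function(x) length(x$samples)

set_labels <- function(set) vapply(set$samples, `[[`, numeric(1), "label")

subset_samples <- function(set, idx) {
  new_sample_set(set$samples[idx], set$labelling_scheme)
}

#' Merge several sample sets (e.g. across participants)
#' @param ... `sample_set` objects with a common labelling scheme.
#' @return A combined `sample_set`.
#' @export
combine_sample_sets <- function(...) {
  sets <- list(...)
  schemes <- unique(vapply(sets, `[[`, character(1), "labelling_scheme"))
  if (length(schemes) != 1L) stop_invalid("sample sets mix labelling schemes")
  new_sample_set(do.call(c, lapply(sets, `[[`, "samples")), schemes)
}

#' Label distribution and per-channel quality statistics of a sample set
#'
#' Quality statistics (mean, variance, max, min per channel over each
#' window) are advisory: noisy samples are reported, never removed, so the
#' network sees realistic data.
#'
#' @param sample_set A non-empty `sample_set`.
#' @return List with `label_table` (label, count, percent of total) and
#'   `quality` (per modality: matrix of per-channel mean/var/max/min averaged
#'   over samples).
#' @export
sample_stats <- function(sample_set) {
  if (length(sample_set$samples) == 0L) stop_invalid("sample set is empty")
  labels <- set_labels(sample_set)
  label_table <- label_distribution(table(labels))
  modalities <- names(sample_set$samples[[1]]$windows)
  quality <- lapply(modalities, function(m) {
    per_sample <- lapply(sample_set$samples, function(s) {
      w <- s$windows[[m]]
      rbind(mean = colMeans(w), var = apply(w, 2, stats::var),
            max = apply(w, 2, max), min = apply(w, 2, min))
    })
    Reduce(`+`, per_sample) / length(per_sample)
  })
  names(quality) <- modalities
  list(label_table = label_table, quality = quality)
}

#' Per-label counts and percentages
#'
#' @param counts Named vector/table of per-label sample counts.
#' @return Data frame with `label`, `count`, `percent` (of total).
#' @export
label_distribution <- function(counts) {
  nm <- names(counts) %||% as.character(seq_along(counts))
  cts <- as.numeric(counts)
  total <- sum(cts)
  if (total == 0) stop_invalid("counts are all zero")
  data.frame(label = nm, count = cts, percent = 100 * cts / total,
             stringsAsFactors = FALSE)
}

#' Write the per-participant CSV of the final marker selection
#'
#' @param recording A [session_recording()].
#' @param mask Logical selection mask from [select_markers()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_selection <- function(recording, mask, path) {
  df <- recording$markers
  df$selected <- mask
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a sample set as sharded record files
#'
#' Samples are written in shards (RDS serialization) so large sets can be
#' shuffled, batched and split without loading everything at once.
#'
#' @param sample_set A `sample_set`.
#' @param dir Output directory.
#' @param shard_size Samples per shard.
#' @return `dir` invisibly (`write_sample_set`); a `sample_set`
#'   (`read_sample_set`).
#' @export
write_sample_set <- function(sample_set, dir, shard_size = 128L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(sample_set$samples)
  shard_of <- if (n) ((seq_len(n) - 1L) %/% shard_size) + 1L else integer()
  for (k in unique(shard_of)) {
    saveRDS(sample_set$samples[shard_of == k],
            file.path(dir, sprintf("shard-%04d.rds", k)))
  }
  jsonlite::write_json(
    list(format = "mwlfuse-samples", n = n,
         labelling_scheme = sample_set$labelling_scheme,
         shards = length(unique(shard_of))),
    file.path(dir, "samples.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(dir) {
  meta_path <- file.path(dir, "samples.json")
  if (!file.exists(meta_path)) stop_io("no sample-set manifest in ", dir)
  meta <- jsonlite::read_json(meta_path)
  files <- sort(list.files(dir, pattern = "^shard-.*\\.rds$", full.names = TRUE))
  samples <- do.call(c, c(lapply(files, readRDS), list()))
  new_sample_set(samples %||% list(), meta$labelling_scheme)
}
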