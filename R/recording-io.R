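#' Assemble a session recording from streams and markers
#'
#' A `session_recording` bundles the signal streams of one participant session
#' (one [stream_series()] per modality) with the marker stream of task-action
#' events. Markers whose timestamps fall outside the union of the stream time
#' ranges are not dropped but flagged in `metadata$flagged_markers`.
#'
#' @param streams Named list of [stream_series()] objects (at least one).
#' @param markers Data frame with columns `timestamp`, `participant_id`,
#'   `action_type`, `action_id`, `status`; may have zero rows.
#' @param metadata List of session metadata (`participant_id`, notes, ...).
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(streams, markers = empty_markers(),
                              metadata = list()) {
  if (!is.list(streams) || length(streams) == 0L ||
      !all(vapply(streams, inherits, logical(1), "stream_series"))) {
    stop_invalid("streams must be a non-empty named list of stream_series")
  }
  if (is.null(names(streams)) || any(names(streams) == "")) {
    stop_invalid("streams must be named by modality")
  }
  markers <- validate_markers(markers)
  if (nrow(markers) > 1L && is.unsorted(markers$timestamp)) {
    markers <- markers[order(markers$timestamp), , drop = FALSE]
    rownames(markers) <- NULL
  }
  rng <- range(unlist(lapply(streams, function(s) {
    if (n_samples(s)) range(s$timestamps) else numeric()
  })))
  flagged <- which(markers$timestamp < rng[1] | markers$timestamp > rng[2])
  metadata$flagged_markers <- flagged
  structure(list(streams = streams, markers = markers, metadata = metadata),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording: %d streams (%s), %d markers>\n",
              length(x$streams), paste(names(x$streams), collapse = ", "),
              nrow(x$markers)))
  invisible(x)
}

#' @rdname session_recording
#' @export
empty_markers <- function() {
  data.frame(timestamp = numeric(), participant_id = character(),
             action_type = character(), action_id = character(),
             status = character(), stringsAsFactors = FALSE)
}

validate_markers <- function(markers) {
  required <- names(empty_markers())
  if (!is.data.frame(markers) || !all(required %in% names(markers))) {
    stop_invalid("markers must be a data frame with columns ",
                 paste(required, collapse = ", "))
  }
  if (any(!is.finite(markers$timestamp))) {
    stop_invalid("marker timestamps must be finite")
  }
  markers[required]
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a session recording to a portable multi-stream container
#'
#' The container is a directory holding a JSON manifest (`recording.json`)
#' plus one CSV per stream and a marker CSV, mirroring the layout of
#' multi-stream XDF recordings: per-stream nominal rate and channel metadata
#' in the manifest, per-sample timestamps alongside the channel columns.
#' Floating point values are written with 17 significant digits, so doubles
#' round-trip bit-exactly.
#'
#' @param recording A [session_recording()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  if (!inherits(recording, "session_recording")) {
    stop_invalid("recording must be a session_recording")
  }
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!ok && !dir.exists(path)) stop_io("cannot create directory ", path)
  manifest <- list(
    format = "mwlfuse-recording",
    version = 1L,
    metadata = recording$metadata[setdiff(names(recording$metadata),
                                          "flagged_markers")],
    streams = lapply(recording$streams, function(s) {
      list(name = s$name, nominal_rate = s$nominal_rate,
           channel_labels = as.list(s$channel_labels),
           file = paste0("stream_", s$name, ".csv"))
    }),
    marker_file = "markers.csv"
  )
  jsonlite::write_json(manifest, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (s in recording$streams) {
    df <- cbind(timestamp = fmt_full(s$timestamps),
                matrix(fmt_full(s$samples), nrow = nrow(s$samples),
                       dimnames = list(NULL, s$channel_labels)))
    utils::write.table(df, file.path(path, paste0("stream_", s$name, ".csv")),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  mk <- recording$markers
  mk$timestamp <- fmt_full(mk$timestamp)
  utils::write.table(mk, file.path(path, "markers.csv"), sep = ",",
                     row.names = FALSE, quote = seq_along(mk)[-1])
  invisible(path)
}

#' Read a session recording, checking rates and de-jittering where necessary
#'
#' Reads the container written by [write_recording()]. For every signal
#' stream the declared (nominal) rate is compared against the realized rate
#' and inter-sample intervals; the outcome is logged in
#' `metadata$rate_checks`. Streams whose realized inter-sample intervals
#' deviate from the nominal period by more than `rate_tolerance` (relative,
#' default 1%) are de-jittered onto a least-squares uniform grid, fitted per
#' contiguous segment so that genuine missing-data gaps are preserved.
#'
#' @param path Container directory.
#' @param rate_tolerance Relative interval deviation above which a stream is
#'   de-jittered (default 0.01).
#' @param dejitter Set `FALSE` to skip de-jittering (raw timestamps kept).
#' @return A [session_recording()] with `metadata$rate_checks` populated.
#' @export
read_recording <- function(path, rate_tolerance = 0.01, dejitter = TRUE) {
  manifest_path <- file.path(path, "recording.json")
  if (!file.exists(manifest_path)) {
    stop_io("no recording manifest at ", manifest_path)
  }
  manifest <- tryCatch(jsonlite::read_json(manifest_path),
                       error = function(e) stop_io("corrupt manifest: ",
                                                   conditionMessage(e)))
  if (!identical(manifest$format, "mwlfuse-recording")) {
    stop_io("not a mwlfuse recording container: ", path)
  }
  streams <- list()
  rate_checks <- list()
  for (ms in manifest$streams) {
    f <- file.path(path, ms$file)
    if (!file.exists(f)) stop_io("missing stream file ", f)
    labels <- as.character(unlist(ms$channel_labels))
    df <- utils::read.csv(f, colClasses = "numeric", check.names = FALSE)
    s <- stream_series(ms$name, ms$nominal_rate, df[[1L]],
                       as.matrix(df[, -1L, drop = FALSE]),
                       channel_labels = labels)
    if (s$nominal_rate > 0 && n_samples(s) >= 2L) {
      realized <- effective_rate(s)
      excess <- jitter_excess(s)
      needs <- excess > rate_tolerance
      rate_checks[[s$name]] <- list(declared = s$nominal_rate,
                                    realized = realized,
                                    interval_excess = excess,
                                    dejittered = needs && dejitter)
      if (needs && dejitter) s <- dejitter_segmentwise(s)
    }
    streams[[ms$name]] <- s
  }
  marker_path <- file.path(path, manifest$marker_file %||% "markers.csv")
  if (!file.exists(marker_path)) {
    stop_io("recording at ", path, " has no marker stream file (expected ",
            manifest$marker_file %||% "markers.csv", ")")
  }
  markers <- utils::read.csv(marker_path, colClasses = c(
    timestamp = "numeric", participant_id = "character",
    action_type = "character", action_id = "character", status = "character"))
  metadata <- manifest$metadata
  metadata$rate_checks <- rate_checks
  session_recording(streams, markers, metadata = metadata)
}

# De-jitter each contiguous segment (between detected gaps) independently.
dejitter_segmentwise <- function(stream, gap_factor = 2.5) {
  period <- 1 / stream$nominal_rate
  dt <- diff(stream$timestamps)
  cut <- which(dt > gap_factor * period)
  bounds <- c(0L, cut, n_samples(stream))
  ts <- stream$timestamps
  for (i in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    if (length(idx) >= 2L) {
      k <- seq_along(idx) - 1
      fit <- stats::lm.fit(cbind(1, k), ts[idx])
      ts[idx] <- fit$coefficients[[1]] + k * fit$coefficients[[2]]
    }
  }
  stream$timestamps <- ts
  stream
}

#' Audit per-stream clock drift of a recording
#'
#' Drift is measured per signal stream as the absolute difference between the
#' realized time span (`t_last - t_first`) and the span implied by the
#' nominal rate and sample count (`(n - 1) / nominal_rate`), in milliseconds.
#' The report also gives the mean and standard deviation across streams.
#'
#' @param recording A [session_recording()].
#' @return List with `per_stream` (data frame: `stream`, `drift_ms`),
#'   `mean_ms`, `sd_ms`.
#' @export
drift_report <- function(recording) {
  signal <- Filter(function(s) s$nominal_rate > 0, recording$streams)
  drift <- vapply(signal, function(s) {
    n <- n_samples(s)
    if (n < 2L) stop_invalid("drift_report needs >= 2 samples per stream")
    realized <- s$timestamps[n] - s$timestamps[1]
    expected <- (n - 1) / s$nominal_rate
    abs(realized - expected) * 1000
  }, numeric(1))
  list(per_stream = data.frame(stream = names(signal), drift_ms = unname(drift)),
       mean_ms = mean(drift),
       sd_ms = if (length(drift) > 1L) stats::sd(drift) else 0)
}
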