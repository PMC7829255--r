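#' Construct a timestamped multichannel signal stream
#'
#' A `stream_series` holds one device stream: a strictly ascending timestamp
#' vector in seconds and a sample matrix with one row per timestamp and one
#' column per channel. A `nominal_rate` of 0 marks an irregular stream (for
#' example a marker stream); signal streams must declare a positive rate.
#'
#' @param name Stream name, e.g. `"GSR"`.
#' @param nominal_rate Declared sampling rate in Hz; 0 for irregular streams.
#' @param timestamps Numeric vector of seconds, strictly ascending.
#' @param samples Numeric matrix, `length(timestamps)` rows.
#' @param channel_labels Optional character vector, one label per column.
#' @return An object of class `stream_series`.
#' @export
stream_series <- function(name, nominal_rate, timestamps, samples,
                          channel_labels = NULL) {
  if (!is.character(name) || length(name) != 1L) {
    stop_invalid("stream name must be a single string")
  }
  assert_scalar_number(nominal_rate, "nominal_rate", lower = 0)
  timestamps <- as.numeric(timestamps)
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL   # channel identity lives in channel_labels
  if (nrow(samples) != length(timestamps)) {
    stop_invalid("samples must have one row per timestamp (",
                 nrow(samples), " rows vs ", length(timestamps), " timestamps)")
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop_invalid("timestamps must be strictly ascending in stream '", name, "'")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (ncol(samples) > 0) paste0("ch", seq_len(ncol(samples))) else character()
  }
  if (length(channel_labels) != ncol(samples)) {
    stop_invalid("channel_labels length must equal the number of channels")
  }
  structure(
    list(name = name, nominal_rate = as.numeric(nominal_rate),
         timestamps = timestamps, samples = samples,
         channel_labels = as.character(channel_labels)),
    class = "stream_series"
  )
}

#' @export
print.stream_series <- function(x, ...) {
  cat(sprintf("<stream_series '%s': %d samples x %d channels, nominal %g Hz>\n",
              x$name, length(x$timestamps), ncol(x$samples), x$nominal_rate))
  invisible(x)
}

n_samples <- function(stream) length(stream$timestamps)

#' Realized sampling rate of a stream
#'
#' Computed as `(n - 1) / (t_last - t_first)`, i.e. the number of
#' inter-sample intervals divided by the realized time span.
#'
#' @param stream A [stream_series()].
#' @return Realized rate in Hz.
#' @export
effective_rate <- function(stream) {
  n <- n_samples(stream)
  if (n < 2L) stop_invalid("effective_rate needs at least 2 samples")
  (n - 1) / (stream$timestamps[n] - stream$timestamps[1])
}

#' Regularize jittered timestamps onto a least-squares uniform grid
#'
#' Replaces the timestamp vector by `t0 + k * delta`, where `(t0, delta)` is
#' the ordinary least-squares line fit of timestamp against sample index.
#' Sample values are untouched. The operation is idempotent: a uniform grid is
#' its own least-squares fit.
#'
#' @param stream A [stream_series()] with positive nominal rate and at least
#'   two samples.
#' @return The stream with regularized timestamps.
#' @export
dejitter_timestamps <- function(stream) {
  if (stream$nominal_rate <= 0) {
    stop_invalid("cannot de-jitter an irregular (rate 0) stream")
  }
  n <- n_samples(stream)
  if (n < 2L) stop_invalid("de-jitter needs at least 2 samples")
  k <- seq_len(n) - 1
  fit <- stats::lm.fit(cbind(1, k), stream$timestamps)
  stream$timestamps <- fit$coefficients[[1]] + k * fit$coefficients[[2]]
  stream
}

#' Detect missing-data gaps in a signal stream
#'
#' An inter-sample interval larger than `factor` nominal periods is reported
#' as a gap. The estimated gap duration is the interval minus one nominal
#' period (the spacing a contiguous recording would have shown).
#'
#' @param stream A [stream_series()] with positive nominal rate.
#' @param factor Multiple of the nominal period above which an interval
#'   counts as a gap (default 2.5).
#' @return A data frame with columns `start`, `end`, `duration` (seconds);
#'   zero rows when no gap is found.
#' @export
gap_report <- function(stream, factor = 2.5) {
  if (stream$nominal_rate <= 0) stop_invalid("gap_report needs a signal stream")
  period <- 1 / stream$nominal_rate
  dt <- diff(stream$timestamps)
  idx <- which(dt > factor * period)
  data.frame(
    start = stream$timestamps[idx],
    end = stream$timestamps[idx + 1L],
    duration = dt[idx] - period
  )
}

# Max relative deviation of realized inter-sample intervals from the nominal
# period, ignoring gap intervals (which are audited separately).
jitter_excess <- function(stream, gap_factor = 2.5) {
  period <- 1 / stream$nominal_rate
  dt <- diff(stream$timestamps)
  dt <- dt[dt <= gap_factor * period]
  if (length(dt) == 0L) return(0)
  max(abs(dt - period)) / period
}
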