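#' Canonical double-gamma haemodynamic response function
#'
#' The haemodynamic response to a brief burst of neural activity: a positive
#' lobe peaking 5--8 s after onset followed by a shallow undershoot, modelled
#' as the difference of two gamma densities. The response is exactly zero at
#' `t = 0` and scales linearly with `gain`.
#'
#' @param time_points Non-negative, ascending times in seconds.
#' @param gain Peak amplitude scale (arbitrary units).
#' @param peak_delay Time-to-peak of the positive lobe in seconds (default 6).
#' @param undershoot_ratio Amplitude of the undershoot relative to the peak
#'   (default 1/6).
#' @return Numeric response values, one per time point, normalized so the
#'   positive lobe peaks at `gain`.
#' @export
canonical_hrf <- function(time_points, gain = 1, peak_delay = 6,
                          undershoot_ratio = 1 / 6) {
  time_points <- as.numeric(time_points)
  if (length(time_points) && (any(time_points < 0) ||
      (length(time_points) > 1L && any(diff(time_points) <= 0)))) {
    stop_invalid("time_points must be non-negative and strictly ascending")
  }
  assert_scalar_number(gain, "gain")
  assert_scalar_number(peak_delay, "peak_delay", lower = 1e-6)
  # gamma shape parameters: peak of t^a * exp(-t/b) sits at a*b
  a1 <- 6; b1 <- peak_delay / a1
  a2 <- 16; b2 <- (peak_delay * 16 / 6) / a2
  lobe <- function(t, a, b) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- exp(a * log(t[pos] / (a * b)) - (t[pos] - a * b) / b)
    out  # normalized to peak 1 at t = a*b
  }
  gain * (lobe(time_points, a1, b1) - undershoot_ratio * lobe(time_points, a2, b2))
}

#' Convolve a neural activity time course with the canonical response
#'
#' Discrete causal convolution of a regularly sampled activity trace with the
#' [canonical_hrf()] kernel, scaled by the sampling step so the result
#' approximates the continuous convolution integral.
#'
#' @param activity Numeric vector sampled every `dt` seconds.
#' @param dt Sampling step in seconds.
#' @param kernel_duration Kernel support in seconds (default 30).
#' @param ... Passed to [canonical_hrf()].
#' @return Numeric vector of the same length as `activity`.
#' @export
hrf_convolve <- function(activity, dt, kernel_duration = 30, ...) {
  assert_scalar_number(dt, "dt", lower = 1e-9)
  n <- length(activity)
  if (n == 0L) return(numeric())
  kt <- seq(0, kernel_duration, by = dt)
  kernel <- canonical_hrf(kt, ...) * dt
  out <- stats::convolve(activity, rev(kernel), type = "open")[seq_len(n)]
  out
}

sample_times <- function(duration, rate) {
  n <- round(duration * rate)
  if (n <= 0) return(numeric())
  (seq_len(n) - 1) / rate
}

# Evaluate a piecewise-constant difficulty profile (data frame with columns
# start, end, difficulty; 0 between intervals) at times t.
profile_at <- function(difficulty_profile, t) {
  d <- numeric(length(t))
  if (is.function(difficulty_profile)) return(difficulty_profile(t))
  for (i in seq_len(nrow(difficulty_profile))) {
    row <- difficulty_profile[i, ]
    d[t >= row$start & t < row$end] <- row$difficulty
  }
  d
}

pink_noise <- function(n, sd = 1) {
  if (n == 0L) return(numeric())
  w <- stats::rnorm(n)
  ar <- as.numeric(stats::filter(w, 0.95, method = "recursive"))
  x <- 0.7 * ar / sqrt(1 / (1 - 0.95^2)) + 0.3 * w
  sd * x
}

#' Simulate one physiological modality under a workload profile
#'
#' Generates a [stream_series()] whose workload-sensitive statistic increases
#' with the difficulty profile:
#'
#' * `GSR` (1 channel, microsiemens): tonic level rising with difficulty plus
#'   Poisson-timed phasic skin-conductance responses (SCRs) with exponential
#'   rise and decay; SCR rate grows with difficulty. Event onsets are kept in
#'   the `scr_times` attribute.
#' * `PPG` (1 channel): periodic blood-volume pulse at an instantaneous heart
#'   rate that rises with difficulty; the realized instantaneous-rate mean is
#'   kept in the `hr_mean` attribute.
#' * `fNIRS` (54 channels = 27 sites x \{O2Hb, HHb\}): difficulty boxcar
#'   convolved with the canonical double-gamma response plus pink noise;
#'   HHb is anti-correlated with its paired O2Hb channel (-0.5 scale).
#' * `ET` (4 channels: left/right eye x/y in normalized screen units):
#'   fixation--saccade alternation with Gaussian fixation scatter; fixation
#'   rate grows with difficulty. Fixation onsets are kept in the
#'   `fixation_times` attribute.
#'
#' @param modality One of `"GSR"`, `"PPG"`, `"fNIRS"`, `"ET"`.
#' @param duration Session length in seconds (`>= 0`).
#' @param difficulty_profile Data frame (`start`, `end`, `difficulty`) or a
#'   function of time; difficulty 0 denotes rest.
#' @param profile Participant profile, see [participant_profile()].
#' @param rate Sampling rate in Hz (`> 0`).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A [stream_series()].
#' @export
simulate_modality <- function(modality, duration, difficulty_profile,
                              profile = participant_profile(),
                              rate = DEFAULT_RATES[[modality]], seed = 1L) {
  if (!modality %in% MODALITIES) {
    stop_invalid("unknown modality '", modality, "'")
  }
  assert_scalar_number(duration, "duration", lower = 0)
  assert_scalar_number(rate, "rate", lower = 1e-9)
  set.seed(seed)
  t <- sample_times(duration, rate)
  d <- profile_at(difficulty_profile, t)
  switch(modality,
    GSR = sim_gsr(t, d, profile, rate),
    PPG = sim_ppg(t, d, profile, rate),
    fNIRS = sim_fnirs(t, d, profile, rate),
    ET = sim_et(t, d, profile, rate)
  )
}

# Smooth zero-mean baseline wander: a sum of slow sinusoids with random
# periods and phases. Real tonic conductance, heart rate and oculomotor
# baselines all wander on the minute scale by amounts comparable to the
# workload effect, which is what keeps any single modality from being fully
# informative about workload on its own.
slow_wander <- function(t, sd, periods = c(45, 90, 180)) {
  if (!length(t)) return(numeric())
  w <- rowSums(vapply(periods, function(p) {
    sin(2 * pi * t / (p * stats::runif(1, 0.7, 1.4)) +
          stats::runif(1, 0, 2 * pi))
  }, numeric(length(t))))
  sd * w / sqrt(length(periods) / 2)
}

sim_gsr <- function(t, d, profile, rate) {
  n <- length(t)
  duration <- if (n) t[n] + 1 / rate else 0
  tonic <- profile$tonic_level + profile$tonic_sens * d +
    slow_wander(t, sd = 0.45)
  x <- tonic + stats::rnorm(n, sd = 0.01)
  # inhomogeneous Poisson SCR onsets via thinning
  scr_times <- numeric()
  if (n) {
    rate_fun <- function(tt) (profile$scr_base +
                              profile$scr_sens * profile_interp(t, d, tt)) / 60
    lambda_max <- (profile$scr_base + profile$scr_sens * max(d, 0)) / 60
    cand <- cumsum(stats::rexp(max(10, ceiling(3 * lambda_max * duration)),
                               rate = max(lambda_max, 1e-9)))
    cand <- cand[cand < duration]
    keep <- stats::runif(length(cand)) < rate_fun(cand) / max(lambda_max, 1e-9)
    scr_times <- cand[keep]
    tau_r <- 0.75; tau_d <- 2.5
    for (t0 in scr_times) {
      amp <- stats::rlnorm(1, meanlog = log(0.3), sdlog = 0.3)
      idx <- which(t >= t0 & t <= t0 + 12)
      if (length(idx)) {
        dt0 <- t[idx] - t0
        shape <- exp(-dt0 / tau_d) - exp(-dt0 / tau_r)
        x[idx] <- x[idx] + amp * shape / max(shape)
      }
    }
  }
  out <- stream_series("GSR", rate, t, matrix(x, ncol = 1),
                       channel_labels = "conductance_uS")
  attr(out, "scr_times") <- scr_times
  out
}

profile_interp <- function(t, d, tt) {
  if (!length(t)) return(numeric(length(tt)))
  d[pmin(pmax(findInterval(tt, t), 1L), length(t))]
}

sim_ppg <- function(t, d, profile, rate) {
  n <- length(t)
  hr <- profile$base_hr + profile$hr_sens * d + slow_wander(t, sd = 4) +
    1.5 * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi))
  phase <- 2 * pi * cumsum(hr / 60) / rate
  x <- 0.6 * sin(phase) + 0.25 * sin(2 * phase - 0.8) +
    0.1 * sin(3 * phase - 1.2) + stats::rnorm(n, sd = 0.02)
  out <- stream_series("PPG", rate, t, matrix(x, ncol = 1),
                       channel_labels = "bvp")
  attr(out, "hr_mean") <- if (n) mean(hr) else NA_real_
  out
}

sim_fnirs <- function(t, d, profile, rate, n_sites = 27L) {
  n <- length(t)
  neural <- 0.12 * d
  bold <- if (n) hrf_convolve(neural, dt = 1 / rate, gain = profile$hrf_gain)
          else numeric()
  gains <- stats::runif(n_sites, 0.5, 1.5)
  # systemic physiological oscillation shared across channels (Mayer-wave
  # range) plus per-channel pink noise; systemic power is deliberately of
  # the same order as the evoked response, as in real scalp fNIRS
  systemic <- slow_wander(t, sd = 0.5, periods = c(8, 25, 60))
  x <- matrix(0, nrow = n, ncol = 2L * n_sites)
  labels <- character(2L * n_sites)
  for (c_i in seq_len(n_sites)) {
    clean <- gains[c_i] * bold
    x[, 2L * c_i - 1L] <- clean + systemic + pink_noise(n, sd = 0.15)
    x[, 2L * c_i] <- -0.5 * (clean + systemic) + pink_noise(n, sd = 0.08)
    labels[2L * c_i - 1L] <- sprintf("CH%02d_O2Hb", c_i)
    labels[2L * c_i] <- sprintf("CH%02d_HHb", c_i)
  }
  stream_series("fNIRS", rate, t, x, channel_labels = labels)
}

sim_et <- function(t, d, profile, rate) {
  n <- length(t)
  duration <- if (n) t[n] + 1 / rate else 0
  gaze <- matrix(0.5, nrow = n, ncol = 2)
  fixation_times <- numeric()
  now <- 0
  target <- stats::runif(2, 0.2, 0.8)
  prev_target <- target
  saccade_dur <- 0.03
  wander_phase <- stats::runif(3, 0, 2 * pi)
  wander_period <- 75 * stats::runif(3, 0.7, 1.4)
  while (now < duration && n) {
    rate_wander <- 0.35 * sum(sin(2 * pi * now / wander_period + wander_phase)) /
      sqrt(1.5)
    fix_rate <- max(0.3, profile$fix_base + rate_wander +
                      profile$fix_sens * profile_interp(t, d, now))
    fix_dur <- stats::rgamma(1, shape = 4, rate = 4 * fix_rate)
    fixation_times <- c(fixation_times, now)
    idx <- which(t >= now & t < now + fix_dur)
    if (length(idx)) {
      gaze[idx, 1] <- target[1] + stats::rnorm(length(idx), sd = 0.004)
      gaze[idx, 2] <- target[2] + stats::rnorm(length(idx), sd = 0.004)
    }
    prev_target <- target
    target <- stats::runif(2, 0.2, 0.8)
    sidx <- which(t >= now + fix_dur & t < now + fix_dur + saccade_dur)
    if (length(sidx)) {
      frac <- (t[sidx] - now - fix_dur) / saccade_dur
      gaze[sidx, 1] <- prev_target[1] + frac * (target[1] - prev_target[1])
      gaze[sidx, 2] <- prev_target[2] + frac * (target[2] - prev_target[2])
    }
    now <- now + fix_dur + saccade_dur
  }
  x <- cbind(gaze[, 1] + stats::rnorm(n, sd = 0.002),
             gaze[, 2] + stats::rnorm(n, sd = 0.002),
             gaze[, 1] + stats::rnorm(n, sd = 0.002),
             gaze[, 2] + stats::rnorm(n, sd = 0.002))
  if (n == 0L) x <- matrix(numeric(), ncol = 4)
  out <- stream_series("ET", rate, t, x,
                       channel_labels = c("Lx", "Ly", "Rx", "Ry"))
  attr(out, "fixation_times") <- fixation_times
  out
}
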