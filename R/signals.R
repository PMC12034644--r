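#' Surface-EMG and kinematic signal conditioning
#'
#' The raw sEMG chain is: zero-phase 2nd-order Butterworth band-pass
#' (20-450 Hz) to remove motion artefact and out-of-band noise, full-wave
#' rectification, zero-phase 4th-order Butterworth low-pass at 6 Hz to form
#' the linear envelope, then division by the MVC envelope peak to give the
#' normalized EMG `u(t)`. All filtering is forward-backward (zero phase),
#' appropriate for offline analysis.
#'
#' @name emg_conditioning
NULL

# zero-phase Butterworth helper
zp_filter <- function(x, flt) {
  as.numeric(signal::filtfilt(flt, x))
}

#' Band-pass stage of the EMG chain
#'
#' @param x Raw EMG trace (numeric vector), mV.
#' @param rate Sampling rate, Hz; must exceed 900 Hz so the 450 Hz corner is
#'   below Nyquist.
#' @param band Pass band corners, Hz.
#' @param order Butterworth order of the band-pass.
#' @return Filtered trace, zero phase.
#' @export
emg_bandpass <- function(x, rate, band = c(20, 450), order = 2) {
  if (rate <= 2 * max(band)) {
    abort_invalid(sprintf(
      "EMG sampling rate %.0f Hz is too low for a %.0f Hz band edge", rate,
      max(band)))
  }
  zp_filter(x, signal::butter(order, band / (rate / 2), type = "pass"))
}

#' Linear envelope of a raw EMG trace
#'
#' Band-pass, rectify, low-pass (see [emg_conditioning]). The output is
#' clamped at zero: the low-pass stage can undershoot slightly around sharp
#' onsets and a linear envelope is nonnegative by definition.
#'
#' @inheritParams emg_bandpass
#' @param lowpass Envelope low-pass corner, Hz.
#' @return Nonnegative envelope trace at the input rate.
#' @export
emg_envelope <- function(x, rate, band = c(20, 450), lowpass = 6) {
  y <- abs(emg_bandpass(x, rate, band))
  lp <- signal::butter(4, lowpass / (rate / 2), type = "low")
  pmax(zp_filter(y, lp), 0)
}

#' Envelope all EMG channels of a record
#'
#' Applies [emg_envelope()] to every `emg_*` column of a raw record.
#'
#' @param data Data frame with a `time_s` column and `emg_<muscle>` channels.
#' @param rate Sampling rate, Hz; inferred from `time_s` when `NULL`.
#' @inheritParams emg_envelope
#' @return Tibble with `time_s` and `env_<muscle>` columns.
#' @export
emg_envelope_record <- function(data, rate = NULL, band = c(20, 450),
                                lowpass = 6) {
  data <- tibble::as_tibble(data)
  chans <- grep("^emg_", names(data), value = TRUE)
  if (length(chans) == 0) abort_schema("no emg_* channels found")
  if (is.null(rate)) rate <- 1 / mean(diff(data$time_s))
  out <- tibble::tibble(time_s = data$time_s)
  for (ch in chans) {
    out[[sub("^emg_", "env_", ch)]] <- emg_envelope(data[[ch]], rate, band,
                                                    lowpass)
  }
  out
}

#' MVC normalization
#'
#' Divides an envelope by the subject's maximum-voluntary-contraction
#' envelope peak and clips to \[0, 1\]. Values above the MVC peak occur in
#' practice (dynamic contractions can exceed the isometric MVC envelope);
#' they are clipped and counted.
#'
#' @param envelope Nonnegative envelope trace.
#' @param mvc_peak MVC envelope peak, same units as `envelope` (positive).
#' @return Normalized EMG `u` in \[0, 1\].
#' @export
mvc_normalize <- function(envelope, mvc_peak) {
  if (!is.finite(mvc_peak) || mvc_peak <= 0) {
    abort_invalid("MVC peak must be a positive number")
  }
  u <- envelope / mvc_peak
  n_clip <- sum(u > 1 | u < 0)
  if (n_clip > 0) {
    inform_log(sprintf("mvc_normalize: clipped %d sample(s) to [0, 1]", n_clip))
  }
  clip01(u)
}

#' MVC envelope peak from an MVC trial
#'
#' The normalization constant is taken from the envelope of the MVC trial
#' rather than its raw amplitude, which makes it robust to single-sample
#' spikes.
#'
#' @param x Raw MVC-trial EMG trace.
#' @param rate Sampling rate, Hz.
#' @return The envelope maximum (positive scalar).
#' @export
mvc_peak <- function(x, rate) {
  max(emg_envelope(x, rate))
}

#' Resample two sensor streams onto a common analysis grid
#'
#' EMG (nominally 2000 Hz) and motion-capture-derived streams (nominally
#' 200 Hz) are linearly interpolated onto one uniform grid at
#' `analysis_rate`, cropped to their overlapping time span.
#'
#' @param a,b Data frames with a `time_s` column and arbitrary numeric
#'   channels; channel names must not collide.
#' @param analysis_rate Target rate, Hz (default 100).
#' @return A tibble on the shared grid containing `time_s` and all channels
#'   of both inputs.
#' @export
synchronize <- function(a, b, analysis_rate = 100) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  t0 <- max(min(a$time_s), min(b$time_s))
  t1 <- min(max(a$time_s), max(b$time_s))
  if (t1 <= t0) abort_invalid("streams have no overlapping time span")
  grid <- seq(t0, t1, by = 1 / analysis_rate)
  out <- tibble::tibble(time_s = grid)
  resample_into <- function(out, d) {
    for (ch in setdiff(names(d), "time_s")) {
      if (ch %in% names(out)) abort_schema(paste("duplicate channel:", ch))
      out[[ch]] <- stats::approx(d$time_s, d[[ch]], xout = grid, rule = 2)$y
    }
    out
  }
  resample_into(resample_into(out, a), b)
}

# smoothed numerical time derivative: central differences (one-sided at the
# ends), then zero-phase 4th-order low-pass at `lowpass` Hz when the series
# is long enough for stable filtering.
deriv_series <- function(x, rate, lowpass = 6, smooth = TRUE) {
  n <- length(x)
  if (n < 3) abort_invalid("need at least 3 samples to differentiate")
  dt <- 1 / rate
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  if (smooth && n > 30 && lowpass < rate / 2) {
    v <- zp_filter(v, signal::butter(4, lowpass / (rate / 2), type = "low"))
  }
  v
}

#' Fiber-velocity estimate from a fiber-length series
#'
#' Central differences (one-sided at the ends) followed by a zero-phase
#' 4th-order Butterworth low-pass at 6 Hz. Shortening gives negative
#' velocity.
#'
#' @param l_m Fiber-length series, m, uniformly sampled.
#' @param rate Sampling rate, Hz.
#' @param smooth Apply the low-pass stage (skipped automatically for series
#'   too short to filter stably).
#' @return Velocity series, m/s.
#' @export
fiber_velocity <- function(l_m, rate, smooth = TRUE) {
  deriv_series(l_m, rate, lowpass = 6, smooth = smooth)
}
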