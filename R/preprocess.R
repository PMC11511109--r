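# Preprocessing: raw reflectance channel -> negated, band-limited pulse series.
#
# The chain is negate -> baseline high-pass -> Savitzky-Golay smoothing.
# Every stage is linear and zero-phase, so pulse fiducial timing is preserved
# and the whole chain commutes with sign flips (prepare(-x) == -prepare(x)).

#' Negate a raw PPG channel
#'
#' Reflectance PPG intensity falls during systole, so the raw pulse is a dip.
#' Negating the channel makes a normal pulse point upward like an arterial
#' blood pressure wave; an inverted pulse then points downward.
#'
#' @param x Numeric vector of intensity samples. Must be finite.
#' @return The sample-wise negation of `x` (same length).
#' @examples
#' negate_signal(c(1, -2, 0))
#' @export
negate_signal <- function(x) {
  check_finite_vector(x, "x")
  -x
}

# Minimum-order Butterworth-magnitude design for the zero-phase baseline
# high-pass: returns list(order_2m, cutoff_hz) meeting
#   gain(stopband) <= 10^(-atten_db/20)  and  gain(passband) within ripple_db.
design_highpass <- function(passband_hz, stopband_hz, atten_db, ripple_db = 0.5) {
  ks <- 10^(atten_db / 20) - 1          # (fc/fstop)^(2m) >= ks
  kp <- 10^(ripple_db / 20) - 1         # (fc/fpass)^(2m) <= kp
  two_m <- 2 * ceiling(log(ks / kp) / log(passband_hz / stopband_hz) / 2)
  cutoff <- stopband_hz * (1.001 * ks)^(1 / two_m)  # margin keeps the bound strict
  list(two_m = two_m, cutoff_hz = cutoff)
}

#' Remove baseline drift with a zero-phase high-pass filter
#'
#' Suppresses the quasi-static ("DC") level and slow baseline wander below the
#' passband while leaving cardiac frequencies untouched. The filter is a
#' zero-phase Butterworth-magnitude gain applied in the frequency domain on an
#' odd-reflection-padded copy of the signal, so it introduces no phase
#' distortion and no startup transient inside the series. The minimum filter
#' order and cutoff are derived from the stopband attenuation (default 60 dB
#' at and below `stopband_hz`) and the passband ripple bound (0.5 dB at and
#' above `passband_hz`).
#'
#' @param x Numeric vector of intensity samples.
#' @param sampling_rate Sampling rate in Hz (>= 1).
#' @param passband_hz Passband edge in Hz; gain is within 0.5 dB of unity at
#'   and above this frequency. Default 0.1 Hz.
#' @param stopband_hz Stopband edge in Hz; attenuation is at least `atten_db`
#'   at and below this frequency. Default 0.05 Hz.
#' @param atten_db Minimum stopband attenuation in dB. Default 60.
#' @return Filtered vector, same length as `x`.
#' @export
highpass_baseline <- function(x, sampling_rate, passband_hz = 0.1,
                              stopband_hz = 0.05, atten_db = 60) {
  check_finite_vector(x, "x")
  check_scalar_in(sampling_rate, 1, Inf, "sampling_rate")
  check_scalar_in(passband_hz, 0, sampling_rate / 2, "passband_hz", open = TRUE)
  check_scalar_in(stopband_hz, 0, passband_hz, "stopband_hz", open = TRUE)
  des <- design_highpass(passband_hz, stopband_hz, atten_db)
  nx <- length(x)
  if (nx <= 3L * des$two_m) {
    abort(sprintf("series too short for the baseline filter: %d samples (need > %d).",
                  nx, 3L * des$two_m),
          class = "ppginv_too_short")
  }
  # odd reflection about both endpoints keeps the padded signal continuous,
  # which controls spectral leakage into the deep stopband
  pad <- min(nx - 1L, as.integer(round(60 * sampling_rate)))
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[nx] - x[(nx - 1L):(nx - pad)])
  np <- length(xp)
  f <- c(0:(np %/% 2L), -rev(seq_len(np - np %/% 2L - 1L))) * sampling_rate / np
  gain <- ifelse(f == 0, 0, 1 / (1 + (des$cutoff_hz / abs(f))^des$two_m))
  y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / np
  y[(pad + 1L):(pad + nx)]
}

# Cache of Savitzky-Golay projection kernels keyed by "order:frame".
.sg_cache <- new.env(parent = emptyenv())

# Savitzky-Golay smoothing weights: orthonormal column basis Q of the local
# polynomial design matrix on abscissae scaled to [-1, 1] (QR keeps the
# degree-20 fit numerically sound). Row i of Q %*% t(Q) gives the weights
# evaluating the local fit at position i of the frame.
sg_kernel <- function(order, frame) {
  key <- paste0(order, ":", frame)
  hit <- .sg_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- (frame - 1L) / 2L
  xs <- seq(-half, half) / half
  q <- qr.Q(qr(outer(xs, 0:order, "^")))
  out <- list(
    center = as.vector(q %*% q[half + 1L, ]),  # interior convolution weights
    head   = q[seq_len(half), , drop = FALSE] %*% t(q),  # first `half` samples
    tail   = q[(half + 2L):frame, , drop = FALSE] %*% t(q)
  )
  .sg_cache[[key]] <- out
  out
}

#' Savitzky-Golay low-pass smoothing
#'
#' Least-squares local-polynomial smoothing with polynomial order 20 and frame
#' length 999 by default. Interior samples are produced by convolution with
#' the central projection row; the first and last half-frames are produced by
#' evaluating the local fit of the first/last full frame at the off-center
#' positions, so no samples are discarded. Polynomials up to the filter order
#' are reproduced exactly (to floating point).
#'
#' @param x Numeric vector, length at least `frame`.
#' @param order Polynomial order (default 20).
#' @param frame Odd frame length (default 999).
#' @return Smoothed vector, same length as `x`.
#' @export
sgolay_smooth <- function(x, order = 20L, frame = 999L) {
  check_finite_vector(x, "x")
  order <- as.integer(order); frame <- as.integer(frame)
  if (frame %% 2L != 1L || frame <= order) {
    abort("`frame` must be odd and greater than `order`.",
          class = "ppginv_invalid_input")
  }
  n <- length(x)
  if (n < frame) {
    abort(sprintf("series too short for Savitzky-Golay frame: %d samples (need >= %d).",
                  n, frame),
          class = "ppginv_too_short")
  }
  k <- sg_kernel(order, frame)
  half <- (frame - 1L) / 2L
  y <- as.numeric(stats::filter(x, k$center, sides = 2))
  y[seq_len(half)] <- as.vector(k$head %*% x[seq_len(frame)])
  y[(n - half + 1L):n] <- as.vector(k$tail %*% x[(n - frame + 1L):n])
  y
}

#' Prepare a raw recording channel for pulse analysis
#'
#' Applies the full preprocessing chain (negation, baseline high-pass,
#' Savitzky-Golay smoothing) to one LED channel and wraps the result as a
#' pulse series tibble carrying its sampling rate and provenance.
#'
#' @param recording A `ppg_recording`, e.g. from [simulate_recording()] or
#'   [read_recording()].
#' @param channel LED channel name: one of `"ir"`, `"red"`, `"green"`, `"blue"`.
#' @param passband_hz,stopband_hz,atten_db High-pass parameters, see
#'   [highpass_baseline()].
#' @param sg_order,sg_frame Savitzky-Golay parameters, see [sgolay_smooth()].
#' @return A `ppg_pulse_series`: a tibble with columns `sample` (1-based) and
#'   `value`, with attributes `sampling_rate`, `channel` and `source_id`.
#' @export
prepare_channel <- function(recording, channel,
                            passband_hz = 0.1, stopband_hz = 0.05, atten_db = 60,
                            sg_order = 20L, sg_frame = 999L) {
  stopifnot(inherits(recording, "ppg_recording"))
  if (!channel %in% names(recording$signals)) {
    abort(sprintf("channel \"%s\" not present in recording.", channel),
          class = "ppginv_missing_channel")
  }
  x <- recording$signals[[channel]]
  v <- negate_signal(x)
  v <- highpass_baseline(v, recording$sampling_rate, passband_hz, stopband_hz, atten_db)
  v <- sgolay_smooth(v, sg_order, sg_frame)
  new_pulse_series(v, recording$sampling_rate, channel,
                   source_id = recording$metadata$source_id %||% NA_character_)
}

new_pulse_series <- function(values, sampling_rate, channel = NA_character_,
                             source_id = NA_character_) {
  check_finite_vector(values, "values")
  if (length(values) < 480L) {
    abort(sprintf("pulse series too short to analyze: %d samples (need >= 480).",
                  length(values)),
          class = "ppginv_too_short")
  }
  check_scalar_in(sampling_rate, 1e-12, Inf, "sampling_rate")
  out <- tibble(sample = seq_along(values), value = as.numeric(values))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "channel") <- channel
  attr(out, "source_id") <- source_id
  class(out) <- c("ppg_pulse_series", class(out))
  out
}

#' Construct a pulse series from a plain numeric vector
#'
#' Convenience constructor for analysing signals that did not come from a
#' `ppg_recording` (already negated, filtered data for example).
#'
#' @param values Numeric samples, negated convention (normal pulses point up).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel,source_id Optional provenance labels.
#' @return A `ppg_pulse_series` tibble.
#' @export
pulse_series <- function(values, sampling_rate = 800, channel = NA_character_,
                         source_id = NA_character_) {
  new_pulse_series(values, sampling_rate, channel, source_id)
}
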