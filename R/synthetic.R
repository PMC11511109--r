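# Synthetic multi-wavelength PPG generator with per-beat polarity ground
# truth. The generator emits RAW sensor-convention signals: a normal beat
# DIPS at systole (reflected intensity falls), an inverted beat rises, so the
# preprocessing negation step is exercised by every downstream test.

#' Pulse shape template
#'
#' Parameters of one synthetic beat in arterial-blood-pressure-like shape:
#' a steep systolic upstroke followed by a slower, exponential-like diastolic
#' decay carrying an optional dicrotic (secondary) wave.
#'
#' @param systolic_rise_fraction Fraction of the beat period occupied by the
#'   upstroke; must be below 0.5 so the upstroke is steeper than the decay.
#'   Default 0.15.
#' @param dicrotic_amplitude Relative height of the secondary wave, in
#'   `[0, 0.5]`. Default 0.2.
#' @param dicrotic_delay_fraction Position of the secondary wave within the
#'   beat, as a fraction of the period. Default 0.45.
#' @param dicrotic_width_fraction Gaussian width of the secondary wave as a
#'   fraction of the period. Default 0.04.
#' @param decay_rate Dimensionless exponential decay rate of the diastolic
#'   limb. Default 3.
#' @param amplitude AC magnitude in arbitrary ADC-like units. Default 1000.
#' @return A list of class `ppg_pulse_template`.
#' @export
pulse_template <- function(systolic_rise_fraction = 0.15,
                           dicrotic_amplitude = 0.2,
                           dicrotic_delay_fraction = 0.45,
                           dicrotic_width_fraction = 0.04,
                           decay_rate = 3,
                           amplitude = 1000) {
  check_scalar_in(systolic_rise_fraction, 0, 0.5, "systolic_rise_fraction", open = TRUE)
  check_scalar_in(dicrotic_amplitude, 0, 0.5, "dicrotic_amplitude")
  check_scalar_in(dicrotic_delay_fraction, systolic_rise_fraction, 1,
                  "dicrotic_delay_fraction", open = TRUE)
  check_scalar_in(dicrotic_width_fraction, 0, 0.25, "dicrotic_width_fraction", open = TRUE)
  check_scalar_in(decay_rate, 0, Inf, "decay_rate", open = TRUE)
  check_scalar_in(amplitude, 0, Inf, "amplitude", open = TRUE)
  structure(list(systolic_rise_fraction = systolic_rise_fraction,
                 dicrotic_amplitude = dicrotic_amplitude,
                 dicrotic_delay_fraction = dicrotic_delay_fraction,
                 dicrotic_width_fraction = dicrotic_width_fraction,
                 decay_rate = decay_rate,
                 amplitude = amplitude),
            class = "ppg_pulse_template")
}

#' Render one synthetic beat
#'
#' Returns one beat of `period_samples` samples in raw sensor convention:
#' a `"normal"` beat dips at systole, an `"inverted"` beat is its exact
#' sample-for-sample negation. The beat starts and ends at baseline 0; the
#' global extremum sits at `systolic_rise_fraction * period_samples` (within
#' one sample).
#'
#' @param template [pulse_template()].
#' @param period_samples Beat length in samples (>= 16).
#' @param polarity `"normal"` or `"inverted"`.
#' @return Numeric vector of `period_samples` intensity samples.
#' @export
render_pulse <- function(template, period_samples, polarity = c("normal", "inverted")) {
  stopifnot(inherits(template, "ppg_pulse_template"))
  polarity <- match.arg(polarity)
  period_samples <- as.integer(period_samples)
  if (period_samples < 16L) {
    abort("`period_samples` must be at least 16.", class = "ppginv_invalid_input")
  }
  n_rise <- max(2L, as.integer(round(template$systolic_rise_fraction * period_samples)))
  i <- seq_len(period_samples) - 1L
  shape <- numeric(period_samples)
  # half-cosine upstroke from exactly 0 to the systolic summit
  up <- i < n_rise
  shape[up] <- 0.5 * (1 - cos(pi * i[up] / n_rise))
  # exponential-like decay reaching exactly 0 at the last sample
  v <- (i[!up] - n_rise) / (period_samples - 1L - n_rise)
  k <- template$decay_rate
  shape[!up] <- (exp(-k * v) - exp(-k)) / (1 - exp(-k))
  # dicrotic wave on the diastolic limb
  u <- i / period_samples
  shape <- shape + template$dicrotic_amplitude *
    exp(-0.5 * ((u - template$dicrotic_delay_fraction) / template$dicrotic_width_fraction)^2)
  shape[1L] <- 0
  beat <- -template$amplitude * shape   # raw convention: systole is a dip
  if (polarity == "inverted") -beat else beat
}

#' Simulation plan for one recording
#'
#' Collects every knob of the synthetic recording generator. Defaults match
#' the acquisition protocol the generator emulates: 90 s recordings at
#' 800 Hz, four LED channels.
#'
#' @param duration_s Recording length in seconds. Default 90.
#' @param sampling_rate Hz. Default 800.
#' @param heart_rate_bpm Mean beat rate. Default 60.
#' @param hr_jitter Per-beat period standard deviation as a fraction of the
#'   period. Default 0.03.
#' @param fraction_inverted Fraction of inverted beats in `[0, 1]`; either a
#'   single value for all channels or a named vector over
#'   `ir, red, green, blue`. Default 0.
#' @param inversion_pattern `"block"` (one contiguous inverted segment with a
#'   deterministic beat count) or `"random"` (independent per-beat
#'   Bernoulli). Default `"block"`.
#' @param noise_sd Additive white-noise SD relative to the template
#'   amplitude. Default 0.02.
#' @param drift_amplitude Sinusoidal baseline-wander amplitude relative to
#'   the template amplitude. Default 0.5.
#' @param drift_period_s Baseline-wander period in seconds. Default 30.
#' @param artifact_rate Transient motion spikes per minute. Default 0.
#' @param led_gains Named per-LED amplitude multipliers. Defaults emulate
#'   decreasing pulsatile amplitude from IR to blue.
#' @return A list of class `ppg_sim_plan`.
#' @export
sim_plan <- function(duration_s = 90, sampling_rate = 800, heart_rate_bpm = 60,
                     hr_jitter = 0.03, fraction_inverted = 0,
                     inversion_pattern = c("block", "random"),
                     noise_sd = 0.02, drift_amplitude = 0.5, drift_period_s = 30,
                     artifact_rate = 0,
                     led_gains = c(ir = 1, red = 0.8, green = 0.6, blue = 0.5)) {
  inversion_pattern <- match.arg(inversion_pattern)
  check_scalar_in(duration_s, 1e-9, Inf, "duration_s")
  check_scalar_in(sampling_rate, 1, Inf, "sampling_rate")
  check_scalar_in(heart_rate_bpm, 1, 400, "heart_rate_bpm")
  check_scalar_in(hr_jitter, 0, 0.5, "hr_jitter")
  check_scalar_in(noise_sd, 0, Inf, "noise_sd")
  check_scalar_in(drift_amplitude, 0, Inf, "drift_amplitude")
  check_scalar_in(drift_period_s, 1e-9, Inf, "drift_period_s")
  check_scalar_in(artifact_rate, 0, Inf, "artifact_rate")
  if (is.null(names(fraction_inverted))) {
    if (length(fraction_inverted) != 1L) {
      abort("`fraction_inverted` must be a single value or named over the LED channels.",
            class = "ppginv_invalid_input")
    }
    fraction_inverted <- setNames(rep(fraction_inverted, 4L), LED_CHANNELS)
  } else {
    if (!setequal(names(fraction_inverted), LED_CHANNELS)) {
      abort("named `fraction_inverted` must cover exactly ir, red, green, blue.",
            class = "ppginv_invalid_input")
    }
    fraction_inverted <- fraction_inverted[LED_CHANNELS]
  }
  if (any(fraction_inverted < 0 | fraction_inverted > 1)) {
    abort("`fraction_inverted` values must lie in [0, 1].", class = "ppginv_invalid_input")
  }
  if (!setequal(names(led_gains), LED_CHANNELS) || any(led_gains <= 0)) {
    abort("`led_gains` must be positive and named over ir, red, green, blue.",
          class = "ppginv_invalid_input")
  }
  structure(list(duration_s = duration_s, sampling_rate = sampling_rate,
                 heart_rate_bpm = heart_rate_bpm, hr_jitter = hr_jitter,
                 fraction_inverted = fraction_inverted,
                 inversion_pattern = inversion_pattern,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s, artifact_rate = artifact_rate,
                 led_gains = led_gains[LED_CHANNELS]),
            class = "ppg_sim_plan")
}

# polarity sequence for one channel: TRUE = inverted beat
draw_polarity <- function(n_beats, fraction, pattern) {
  if (fraction == 0) return(rep(FALSE, n_beats))
  if (fraction == 1) return(rep(TRUE, n_beats))
  if (pattern == "block") {
    n_inv <- as.integer(round(fraction * n_beats))
    if (n_inv == 0L) return(rep(FALSE, n_beats))
    start <- sample.int(n_beats - n_inv + 1L, 1L)
    out <- rep(FALSE, n_beats)
    out[start:(start + n_inv - 1L)] <- TRUE
    out
  } else {
    runif(n_beats) < fraction
  }
}

#' Generate one synthetic multi-wavelength recording
#'
#' Concatenates beats with jittered periods, applies per-beat polarity
#' according to the plan, adds sinusoidal baseline wander, white noise and
#' optional motion artifacts, scales each LED channel by its gain, and
#' returns the four-channel recording together with the per-beat ground
#' truth. Identical seeds reproduce identical output.
#'
#' @param plan [sim_plan()].
#' @param template [pulse_template()].
#' @param seed Integer seed; mandatory because beat timing, polarity
#'   placement and noise are all stochastic.
#' @param metadata Optional named list merged into the recording metadata
#'   (participant, position_mm, pressure, ...).
#' @return A `ppg_recording`: list with `signals` (tibble `sample`, `ir`,
#'   `red`, `green`, `blue`), `sampling_rate`, `metadata` (one-row tibble)
#'   and `ground_truth` (tibble `channel`, `beat`, `onset_sample`,
#'   `n_samples`, `inverted`).
#' @export
simulate_recording <- function(plan = sim_plan(), template = pulse_template(),
                               seed, metadata = list()) {
  stopifnot(inherits(plan, "ppg_sim_plan"), inherits(template, "ppg_pulse_template"))
  if (missing(seed)) {
    abort("`seed` is mandatory: the generator is stochastic.",
          class = "ppginv_invalid_input")
  }
  with_seed(seed, {
    fs <- plan$sampling_rate
    n_total <- as.integer(round(plan$duration_s * fs))
    base_period <- fs * 60 / plan$heart_rate_bpm

    periods <- integer(0)
    while (sum(periods) < n_total) {
      p <- max(16L, as.integer(round(base_period * (1 + rnorm(1L, 0, plan$hr_jitter)))))
      periods <- c(periods, p)
    }
    n_beats <- length(periods)
    onsets <- c(0L, cumsum(periods))[seq_len(n_beats)] + 1L  # 1-based

    amp <- template$amplitude
    t <- (seq_len(n_total) - 1L) / fs
    drift <- plan$drift_amplitude * amp *
      sin(2 * pi * t / plan$drift_period_s + runif(1L, 0, 2 * pi))

    artifacts <- numeric(n_total)
    n_art <- rpois(1L, plan$artifact_rate * plan$duration_s / 60)
    if (n_art > 0L) {
      centers <- runif(n_art, 0, plan$duration_s)
      widths <- runif(n_art, 0.05, 0.2)
      heights <- runif(n_art, 2, 5) * amp * sample(c(-1, 1), n_art, replace = TRUE)
      for (a in seq_len(n_art)) {
        artifacts <- artifacts + heights[a] * exp(-0.5 * ((t - centers[a]) / widths[a])^2)
      }
    }

    beats_normal <- lapply(periods, function(p) render_pulse(template, p, "normal"))

    channels <- list()
    truth <- list()
    for (ch in LED_CHANNELS) {
      inv <- draw_polarity(n_beats, plan$fraction_inverted[[ch]],
                           plan$inversion_pattern)
      pulse <- unlist(lapply(seq_len(n_beats), function(b) {
        if (inv[b]) -beats_normal[[b]] else beats_normal[[b]]
      }), use.names = FALSE)[seq_len(n_total)]
      noise <- rnorm(n_total, 0, plan$noise_sd * amp)
      channels[[ch]] <- plan$led_gains[[ch]] * pulse + drift + artifacts + noise
      truth[[ch]] <- tibble(channel = ch, beat = seq_len(n_beats),
                            onset_sample = onsets, n_samples = periods,
                            inverted = inv)
    }

    meta_defaults <- list(source_id = sprintf("sim-%d", as.integer(seed)),
                          participant = NA_character_, position_mm = NA_integer_,
                          pressure = NA_character_,
                          contact_force_mmhg = NA_real_, skin_temp_c = NA_real_,
                          room_temp_c = NA_real_,
                          duration_s = plan$duration_s)
    meta <- modifyList(meta_defaults, metadata)
    new_recording(
      signals = tibble(sample = seq_len(n_total), ir = channels$ir,
                       red = channels$red, green = channels$green,
                       blue = channels$blue),
      sampling_rate = fs,
      metadata = as_tibble(meta),
      ground_truth = dplyr::bind_rows(truth))
  })
}

new_recording <- function(signals, sampling_rate, metadata, ground_truth = NULL) {
  stopifnot(is.data.frame(signals),
            all(c("sample", LED_CHANNELS) %in% names(signals)))
  structure(list(signals = as_tibble(signals), sampling_rate = sampling_rate,
                 metadata = as_tibble(metadata), ground_truth = ground_truth),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> %s: %d samples x 4 LEDs @ %g Hz (%.1f s)\n",
              x$metadata$source_id %||% "?", nrow(x$signals), x$sampling_rate,
              nrow(x$signals) / x$sampling_rate))
  meta <- x$metadata
  if (!is.na(meta$participant %||% NA)) {
    cat(sprintf("  participant %s, position %s mm, pressure %s\n",
                meta$participant, meta$position_mm, meta$pressure))
  }
  if (!is.null(x$ground_truth)) {
    inv <- dplyr::summarise(dplyr::group_by(x$ground_truth, .data$channel),
                            f = mean(.data$inverted))
    cat("  ground truth inverted fraction:",
        paste(sprintf("%s %.2f", inv$channel, inv$f), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate the study measurement protocol
#'
#' One row per channel-recording of the default measurement grid:
#' participants x positions x pressure levels x LED channels
#' (12 x 11 x 3 x 4 = 1584 by default).
#'
#' @param participants Number of participants or a character vector of ids.
#' @param positions Integer sensor positions in mm relative to the artery
#'   central line (positive = medial). Default `-5:5`.
#' @param pressures Pressure levels. Default low/medium/high.
#' @param leds LED channels. Default all four.
#' @return Tibble with columns `participant`, `position_mm`, `pressure`,
#'   `led`.
#' @export
study_protocol <- function(participants = 12, positions = -5:5,
                           pressures = PRESSURE_LEVELS, leds = LED_CHANNELS) {
  if (is.numeric(participants) && length(participants) == 1L) {
    participants <- sprintf("S%d", seq_len(participants))
  }
  tidyr::expand_grid(participant = participants,
                     position_mm = as.integer(positions),
                     pressure = pressures, led = leds)
}

# Observed ranges of the study conditions table, used to draw plausible
# sensor metadata for synthetic participants.
FORCE_RANGES <- list(high = c(34.0, 55.0), medium = c(14.0, 38.0), low = c(3.2, 24.5))
SKIN_TEMP_RANGE <- c(28.9, 36.2)
ROOM_TEMP_RANGE <- c(21.2, 24.6)

#' Generate a full synthetic study
#'
#' Emits one multi-wavelength recording per (participant, position, pressure)
#' cell of the protocol, with per-LED inverted-beat fractions supplied by
#' `inversion_map` and plausible contact-force / temperature metadata drawn
#' within the observed study ranges. Deterministic under `seed`.
#'
#' @param base_plan [sim_plan()] used for every recording; its
#'   `fraction_inverted` is overridden per cell by `inversion_map`.
#' @param template [pulse_template()].
#' @param inversion_map `NULL` (no inversion anywhere) or a function
#'   `(participant, position_mm, pressure, led) -> fraction in [0, 1]`.
#' @param participants,positions,pressures Protocol grid, see
#'   [study_protocol()].
#' @param seed Integer master seed; per-recording seeds are derived from it.
#' @param handler Optional function applied to each `ppg_recording` as it is
#'   generated; when supplied, the list of handler results is returned
#'   instead of the recordings (keeps full-size studies out of memory).
#' @return List of `ppg_recording` objects (or handler results), one per
#'   (participant, position, pressure).
#' @export
generate_study <- function(base_plan = sim_plan(), template = pulse_template(),
                           inversion_map = NULL, participants = 12,
                           positions = -5:5, pressures = PRESSURE_LEVELS,
                           seed, handler = NULL) {
  if (missing(seed)) {
    abort("`seed` is mandatory: the generator is stochastic.",
          class = "ppginv_invalid_input")
  }
  cells <- study_protocol(participants, positions, pressures, leds = "ir") |>
    dplyr::select(-"led")
  if (is.numeric(participants) && length(participants) == 1L) {
    participants <- sprintf("S%d", seq_len(participants))
  }
  with_seed(seed, {
    # participant-level conditions, stable across their recordings
    skin <- setNames(runif(length(participants), SKIN_TEMP_RANGE[1], SKIN_TEMP_RANGE[2]),
                     participants)
    room <- setNames(runif(length(participants), ROOM_TEMP_RANGE[1], ROOM_TEMP_RANGE[2]),
                     participants)
    force <- list()
    for (p in participants) {
      force[[p]] <- vapply(PRESSURE_LEVELS,
                           function(pr) runif(1, FORCE_RANGES[[pr]][1], FORCE_RANGES[[pr]][2]),
                           numeric(1))
    }
    rec_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
    out <- vector("list", nrow(cells))
    for (j in seq_len(nrow(cells))) {
      cell <- cells[j, ]
      frac <- if (is.null(inversion_map)) {
        setNames(rep(0, 4L), LED_CHANNELS)
      } else {
        vapply(LED_CHANNELS, function(led) {
          inversion_map(cell$participant, cell$position_mm, cell$pressure, led)
        }, numeric(1))
      }
      plan_j <- base_plan
      plan_j$fraction_inverted <- frac
      rec <- simulate_recording(
        plan_j, template, seed = rec_seeds[j],
        metadata = list(
          source_id = sprintf("%s_pos%+d_%s", cell$participant,
                              cell$position_mm, cell$pressure),
          participant = cell$participant,
          position_mm = cell$position_mm,
          pressure = cell$pressure,
          contact_force_mmhg = unname(force[[cell$participant]][[cell$pressure]]),
          skin_temp_c = unname(skin[[cell$participant]]),
          room_temp_c = unname(room[[cell$participant]])))
      out[[j]] <- if (is.null(handler)) rec else handler(rec)
    }
    out
  })
}

#' Study contact-force and temperature conditions
#'
#' Per-participant mean contact force at each pressure level (mmHg) and
#' skin/room temperatures (deg C) of the measurement campaign the synthetic
#' generator emulates, read from the package's plain-text data.
#'
#' @return Tibble with columns `participant`, `f_max_mmhg`, `f_med_mmhg`,
#'   `f_min_mmhg`, `skin_temp_c`, `room_temp_c`.
#' @export
study_conditions <- function() {
  path <- system.file("extdata", "contact_force_temperature.csv", package = "ppginv")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(participant = readr::col_character(),
                                          .default = readr::col_double()))
}
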