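# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy the per-candidate diagnostics of a pulse analysis
#'
#' @param x A `ppg_inversion` from [analyze_pulses()].
#' @param ... Unused.
#' @return Tibble with one row per pulse candidate: `index`, `kind`,
#'   `plateau`, `verified`, `symmetry_pass`, `label`, `cos_theta`.
#' @method tidy ppg_inversion
#' @export
tidy.ppg_inversion <- function(x, ...) {
  x$candidates
}

#' One-row summary of a pulse analysis
#'
#' @param x A `ppg_inversion`.
#' @param ... Unused.
#' @return The recording-channel estimate row (see [estimate_inversion()])
#'   with `source_id` and `channel` prepended.
#' @method glance ppg_inversion
#' @export
glance.ppg_inversion <- function(x, ...) {
  dplyr::bind_cols(tibble(source_id = x$source_id, channel = x$channel),
                   x$estimate)
}

#' Tidy an OOI grid
#'
#' @param x A `ppg_ooi_grid` from [aggregate_grid()].
#' @param ... Unused.
#' @return The full position x pressure x LED cell tibble.
#' @method tidy ppg_ooi_grid
#' @export
tidy.ppg_ooi_grid <- function(x, ...) {
  x$grid
}

#' One-row summary of an OOI grid
#'
#' @param x A `ppg_ooi_grid`.
#' @param ... Unused.
#' @return Tibble with the number of analyzable recording-channels, cell
#'   count, and overall mean OOI.
#' @method glance ppg_ooi_grid
#' @export
glance.ppg_ooi_grid <- function(x, ...) {
  tibble(n_recordings = x$n_usable, n_cells = nrow(x$grid),
         mean_ooi = if (nrow(x$grid) > 0L) mean(x$grid$ooi) else NA_real_)
}

#' Plot a multi-wavelength recording
#'
#' Raw channels stacked by LED. Long recordings are thinned for display.
#'
#' @param object A `ppg_recording`.
#' @param window_s Optional length-2 time window in seconds.
#' @param max_points Display thinning cap per channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_recording
#' @export
autoplot.ppg_recording <- function(object, window_s = NULL, max_points = 20000, ...) {
  df <- object$signals |>
    tidyr::pivot_longer(dplyr::all_of(LED_CHANNELS),
                        names_to = "led", values_to = "intensity") |>
    dplyr::mutate(time_s = (.data$sample - 1) / object$sampling_rate,
                  led = factor(.data$led, levels = LED_CHANNELS))
  if (!is.null(window_s)) {
    df <- dplyr::filter(df, .data$time_s >= window_s[1], .data$time_s <= window_s[2])
  }
  thin <- max(1L, nrow(df) %/% (max_points * 4L))
  df <- df[seq(1L, nrow(df), by = thin), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~led, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "raw intensity [a.u.]",
                  title = object$metadata$source_id %||% NULL)
}

#' Plot a pulse analysis with its classified candidates
#'
#' Preprocessed series with symmetry-passing peaks and troughs marked.
#'
#' @param object A `ppg_inversion`.
#' @param series The `ppg_pulse_series` the analysis was run on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_inversion
#' @export
autoplot.ppg_inversion <- function(object, series, ...) {
  fs <- attr(series, "sampling_rate") %||% 1
  df <- tibble(time_s = (series$sample - 1) / fs, value = series$value)
  cand <- object$candidates |>
    dplyr::filter(.data$symmetry_pass) |>
    dplyr::mutate(time_s = (.data$index - 1) / fs,
                  value = series$value[.data$index])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::geom_point(data = cand,
                        ggplot2::aes(colour = .data$kind), size = 1.6) +
    ggplot2::scale_colour_manual(values = c(peak = "#2166ac", trough = "#b2182b")) +
    ggplot2::labs(x = "time [s]", y = "negated intensity [a.u.]",
                  colour = "pulse label",
                  subtitle = sprintf("DOI = %.3f over %d pulses",
                                     object$estimate$doi, object$estimate$n_pulses))
}

#' Plot an OOI grid
#'
#' Occurrence of inversion versus sensor position, as one of the standard
#' panels: the full per-LED-and-pressure grid, the per-LED or per-pressure
#' marginal, the per-subject occurrence, or the grand mean/median.
#'
#' @param object A `ppg_ooi_grid`.
#' @param panel One of `"grid"`, `"led"`, `"pressure"`, `"subject"`,
#'   `"position"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_ooi_grid
#' @export
autoplot.ppg_ooi_grid <- function(object,
                                  panel = c("grid", "led", "pressure",
                                            "subject", "position"), ...) {
  panel <- match.arg(panel)
  pct <- ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v))
  base <- ggplot2::labs(x = "position relative to artery [mm] (+ medial)",
                        y = "occurrence of inversion")
  switch(panel,
    grid = ggplot2::ggplot(object$grid,
                           ggplot2::aes(x = .data$position_mm, y = .data$ooi,
                                        colour = .data$pressure)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::facet_wrap(~led) + pct + base,
    led = ggplot2::ggplot(object$by_led,
                          ggplot2::aes(x = .data$position_mm, y = .data$ooi,
                                       colour = .data$led)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) + pct + base,
    pressure = ggplot2::ggplot(object$by_pressure,
                               ggplot2::aes(x = .data$position_mm, y = .data$ooi,
                                            colour = .data$pressure)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) + pct + base,
    subject = ggplot2::ggplot(object$by_subject,
                              ggplot2::aes(x = .data$position_mm,
                                           y = .data$occurrence,
                                           colour = .data$participant)) +
      ggplot2::geom_line(show.legend = FALSE) + pct + base,
    position = ggplot2::ggplot(object$by_position,
                               ggplot2::aes(x = .data$position_mm)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_ooi)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$median_occurrence),
                         colour = "grey60") +
      pct + base)
}
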