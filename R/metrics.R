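# Recording-level inversion statistics and grid aggregation.
#
# mu    = mean of per-pulse labels a_i in {+1 non-inverted, -1 inverted}
# DOI   = (1 - mu) / 2, the degree of inversion in [0, 1]
# OOI   = fraction of analyzable recordings in a configuration cell with
#         DOI above the binary threshold (default 0.25)

#' Metric thresholds
#'
#' @param doi_threshold Binary inversion cutoff on DOI; a recording is
#'   classified inverted iff DOI is strictly above it. Default 0.25.
#' @param noise_mu_threshold Noise screen: a recording is flagged when the
#'   absolute mean label falls below this value, since inconsistent or
#'   noise-corrupted signals drive the mean label toward zero. Default 0.3.
#' @return A list of class `ppg_metric_params`.
#' @export
metric_params <- function(doi_threshold = 0.25, noise_mu_threshold = 0.3) {
  check_scalar_in(doi_threshold, 0, 1, "doi_threshold", open = TRUE)
  check_scalar_in(noise_mu_threshold, 0, 1, "noise_mu_threshold", open = TRUE)
  structure(list(doi_threshold = doi_threshold,
                 noise_mu_threshold = noise_mu_threshold),
            class = "ppg_metric_params")
}

#' Mean pulse label
#'
#' Averages the per-pulse labels of a recording. A mean close to +1 indicates
#' a consistently non-inverted signal, close to -1 a consistently inverted
#' one, and values near zero either mixed polarity or noise.
#'
#' @param labels Numeric vector of +1/-1 pulse labels.
#' @return The mean label, in `[-1, 1]`.
#' @export
mu_inversion <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) {
    abort("no labelled pulses: the inversion estimate is undefined and the recording must be excluded.",
          class = "ppginv_no_pulses")
  }
  if (!all(labels %in% c(-1, 1))) {
    abort("labels must be +1 or -1.", class = "ppginv_invalid_input")
  }
  mean(labels)
}

#' Degree of inversion
#'
#' Maps the mean pulse label to the unit interval: `DOI = (1 - mu) / 2`.
#' A DOI of 0 is completely non-inverted; a DOI of 1 is fully inverted.
#'
#' @param mu Mean pulse label in `[-1, 1]`.
#' @return DOI in `[0, 1]`.
#' @export
degree_of_inversion <- function(mu) {
  if (any(!is.finite(mu) | mu < -1 | mu > 1)) {
    abort("`mu` must lie in [-1, 1].", class = "ppginv_invalid_input")
  }
  (1 - mu) / 2
}

#' Binary inversion classification
#'
#' @param doi Degree of inversion in `[0, 1]` (vectorised).
#' @param params [metric_params()].
#' @return Integer 0/1: 1 iff `doi` is strictly above the threshold.
#' @export
classify_inverted <- function(doi, params = metric_params()) {
  if (any(!is.finite(doi) | doi < 0 | doi > 1)) {
    abort("`doi` must lie in [0, 1].", class = "ppginv_invalid_input")
  }
  as.integer(doi > params$doi_threshold)
}

#' Occurrence of inversion in a configuration cell
#'
#' Fraction of analyzable recordings whose DOI is strictly above the binary
#' threshold.
#'
#' @param dois Numeric vector of per-recording DOI values (one per
#'   analyzable recording in the cell).
#' @param params [metric_params()].
#' @return OOI as a fraction in `[0, 1]`.
#' @export
occurrence_of_inversion <- function(dois, params = metric_params()) {
  if (length(dois) == 0L) {
    abort("empty cell: OOI is undefined and the cell must be reported as missing.",
          class = "ppginv_empty_cell")
  }
  mean(classify_inverted(dois, params))
}

#' Recording-level inversion estimate from classified candidates
#'
#' Computes the mean pulse label over symmetry-passing candidates, the DOI,
#' the phase according to each classifier layer, and the noise and
#' disagreement flags. Flags never alter the estimate; they surface
#' recordings for an exclusion decision. A recording with no
#' symmetry-passing pulses is marked `excluded` with undefined estimates.
#'
#' @param candidates Candidate tibble with `kind`, `symmetry_pass`, `label`
#'   and `cos_theta` columns (see [analyze_pulses()]).
#' @param params [metric_params()].
#' @return One-row tibble: `n_pulses`, `mu`, `doi`, `inverted` (0/1),
#'   `symmetry_phase`, `triangulation_phase`, `noise_flag`,
#'   `disagreement_flag`, `excluded`.
#' @export
estimate_inversion <- function(candidates, params = metric_params()) {
  labels <- candidates$label[!is.na(candidates$label) & candidates$symmetry_pass]
  tri_phase <- phase_by_triangulation(candidates)
  if (length(labels) == 0L) {
    return(tibble(
      n_pulses = 0L, mu = NA_real_, doi = NA_real_, inverted = NA_integer_,
      symmetry_phase = "indeterminate", triangulation_phase = tri_phase,
      noise_flag = TRUE, disagreement_flag = FALSE, excluded = TRUE))
  }
  mu <- mu_inversion(labels)
  doi <- degree_of_inversion(mu)
  sym_phase <- if (mu > 0) "non-inverted" else if (mu < 0) "inverted" else "indeterminate"
  defined <- c("inverted", "non-inverted")
  tibble(
    n_pulses = length(labels),
    mu = mu,
    doi = doi,
    inverted = classify_inverted(doi, params),
    symmetry_phase = sym_phase,
    triangulation_phase = tri_phase,
    noise_flag = abs(mu) < params$noise_mu_threshold,
    disagreement_flag = sym_phase %in% defined && tri_phase %in% defined &&
      sym_phase != tri_phase,
    excluded = FALSE)
}

#' Aggregate per-recording estimates into the OOI grid and its marginals
#'
#' Groups analyzable recordings by measurement configuration (position,
#' pressure, LED) and computes the occurrence of inversion per cell, plus the
#' marginal summaries: per-LED OOI vs position (averaged over pressures),
#' per-pressure OOI vs position (averaged over LEDs), per-subject occurrence
#' vs position (averaged over pressures and LEDs), and the grand mean/median
#' per position. Excluded recordings are removed from every denominator;
#' cells with no analyzable recording are absent, never imputed as zero.
#'
#' @param estimates Tibble with one row per recording-channel:
#'   `participant`, `position_mm`, `pressure`, `led`, `doi`, `excluded`.
#'   Typically the output of [run_analyze()].
#' @param params [metric_params()].
#' @return A `ppg_ooi_grid` object: list of tibbles `grid`, `by_led`,
#'   `by_pressure`, `by_subject`, `by_position`. OOI values are fractions;
#'   rendering as percentages is left to reports.
#' @export
aggregate_grid <- function(estimates, params = metric_params()) {
  required <- c("participant", "position_mm", "pressure", "led", "doi", "excluded")
  missing_cols <- setdiff(required, names(estimates))
  if (length(missing_cols) > 0L) {
    abort(sprintf("estimates are missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "ppginv_schema")
  }
  dup <- estimates |>
    dplyr::count(.data$participant, .data$position_mm, .data$pressure, .data$led) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate measurement key(s), e.g. participant %s at %s mm, %s pressure, %s LED.",
                  dup$participant[1L], dup$position_mm[1L], dup$pressure[1L], dup$led[1L]),
          class = "ppginv_duplicate_measurement")
  }
  usable <- dplyr::filter(estimates, !.data$excluded, !is.na(.data$doi))
  if (nrow(usable) == 0L) {
    warn("all recordings excluded: the OOI grid is empty.")
  }
  usable <- dplyr::mutate(usable, b = classify_inverted(.data$doi, params))
  grid <- usable |>
    dplyr::group_by(.data$position_mm, .data$pressure, .data$led) |>
    dplyr::summarise(n_recordings = dplyr::n(),
                     n_inverted = sum(.data$b),
                     ooi = mean(.data$b), .groups = "drop")
  by_led <- grid |>
    dplyr::group_by(.data$led, .data$position_mm) |>
    dplyr::summarise(ooi = mean(.data$ooi), .groups = "drop")
  by_pressure <- grid |>
    dplyr::group_by(.data$pressure, .data$position_mm) |>
    dplyr::summarise(ooi = mean(.data$ooi), .groups = "drop")
  by_subject <- usable |>
    dplyr::group_by(.data$participant, .data$position_mm) |>
    dplyr::summarise(occurrence = mean(.data$b), .groups = "drop")
  by_position <- grid |>
    dplyr::group_by(.data$position_mm) |>
    dplyr::summarise(mean_ooi = mean(.data$ooi), .groups = "drop") |>
    dplyr::left_join(
      by_subject |>
        dplyr::group_by(.data$position_mm) |>
        dplyr::summarise(median_occurrence = median(.data$occurrence),
                         .groups = "drop"),
      by = "position_mm")
  structure(list(grid = grid, by_led = by_led, by_pressure = by_pressure,
                 by_subject = by_subject, by_position = by_position,
                 params = params,
                 n_input = nrow(estimates), n_usable = nrow(usable)),
            class = "ppg_ooi_grid")
}

#' @export
print.ppg_ooi_grid <- function(x, ...) {
  cat("<ppg_ooi_grid>\n")
  cat(sprintf("  %d analyzable of %d recording-channels, %d cells\n",
              x$n_usable, x$n_input, nrow(x$grid)))
  if (nrow(x$grid) > 0L) {
    cat(sprintf("  overall OOI: %.2f%%\n", 100 * mean(x$grid$ooi)))
  }
  invisible(x)
}
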