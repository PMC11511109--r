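# Two-layer inversion classifier.
#
# Layer 1 (symmetry): every dominance-verified extremum is tested for the
# systole/diastole asymmetry of a real pulse -- the mean absolute first
# difference over the window before the reference point must exceed the one
# after it. Passing peaks are labelled +1 (non-inverted), passing troughs -1
# (inverted).
#
# Layer 2 (triangulation): each verified extremum is triangulated with its
# nearest non-candidate extrema of the same kind on either side; the cosine
# of the vertex angle (law of cosines, time in samples, intensity z-scored)
# measures sharpness. Sharper troughs than peaks indicate an inverted signal.

#' Analysis window parameters
#'
#' @param verify_window Samples on each side used by the dominance check
#'   (default 150).
#' @param symmetry_window Samples on each side of the reference point used by
#'   the symmetry criterion (default 240, about 0.3 s at 800 Hz).
#' @return A list of class `ppg_analysis_params`.
#' @export
analysis_params <- function(verify_window = 150L, symmetry_window = 240L) {
  verify_window <- as.integer(verify_window)
  symmetry_window <- as.integer(symmetry_window)
  if (verify_window < 1L || symmetry_window < 1L) {
    abort("analysis windows must be positive integers.",
          class = "ppginv_invalid_input")
  }
  structure(list(verify_window = verify_window, symmetry_window = symmetry_window),
            class = "ppg_analysis_params")
}

# All strict local extrema of x, with plateaus contributing one extremum at
# the plateau midpoint. Boundary runs are never extrema.
# Returns tibble(index, kind, plateau).
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) {
    abort("series must have at least 3 samples to carry extrema.",
          class = "ppginv_too_short")
  }
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) {
    return(tibble(index = integer(), kind = character(), plateau = logical()))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- (starts + ends) %/% 2L
  dp <- c(NA, diff(r$values))
  dn <- c(diff(r$values), NA)
  is_max <- !is.na(dp) & !is.na(dn) & dp > 0 & dn < 0
  is_min <- !is.na(dp) & !is.na(dn) & dp < 0 & dn > 0
  sel <- is_max | is_min
  tibble(
    index = mids[sel],
    kind = ifelse(is_max[sel], "peak", "trough"),
    plateau = r$lengths[sel] > 1L
  )
}

series_values <- function(series) {
  if (inherits(series, "ppg_pulse_series")) series$value else as.numeric(series)
}

#' Gather pulse candidates
#'
#' Locates every strict local maximum (peak) and minimum (trough) of the
#' series; plateaus contribute one candidate at the plateau midpoint.
#' Candidates closer than `symmetry_window` samples to either end are dropped
#' because their symmetry windows would truncate.
#'
#' @param series A `ppg_pulse_series` (or bare numeric vector).
#' @param params [analysis_params()].
#' @return A tibble with columns `index` (1-based sample position), `kind`
#'   (`"peak"` or `"trough"`) and `plateau`.
#' @export
gather_candidates <- function(series, params = analysis_params()) {
  x <- series_values(series)
  ext <- find_extrema(x)
  sw <- params$symmetry_window
  dplyr::filter(ext, .data$index > sw, .data$index <= length(x) - sw)
}

#' Verify candidate dominance over its neighbourhood
#'
#' A peak passes iff no sample within `verify_window` samples on either side
#' exceeds its value; a trough passes iff no sample is below its value.
#' Equal-valued neighbours do not disqualify. Windows are clipped at the
#' series boundaries.
#'
#' @param series A `ppg_pulse_series` (or numeric vector).
#' @param candidates Tibble from [gather_candidates()].
#' @param params [analysis_params()].
#' @return `candidates` with a logical `verified` column added.
#' @export
verify_dominance <- function(series, candidates, params = analysis_params()) {
  x <- series_values(series)
  n <- length(x)
  vw <- params$verify_window
  verified <- purrr::map2_lgl(candidates$index, candidates$kind, function(i, kind) {
    if (i < 1L || i > n) {
      abort(sprintf("candidate index %d outside the series.", i),
            class = "ppginv_invalid_input")
    }
    w <- x[max(1L, i - vw):min(n, i + vw)]
    if (kind == "peak") !any(w > x[i]) else !any(w < x[i])
  })
  dplyr::mutate(candidates, verified = verified)
}

#' Systole/diastole symmetry criterion
#'
#' For each verified candidate, compares the mean absolute first difference
#' over the `symmetry_window` samples preceding the reference point against
#' the window following it. A real systolic endpoint is preceded by the steep
#' systolic limb, so the criterion passes iff the preceding tangent strictly
#' exceeds the following one. Passing peaks are labelled `+1` (non-inverted),
#' passing troughs `-1` (inverted); ties and unverified candidates get no
#' label.
#'
#' @param series A `ppg_pulse_series` (or numeric vector).
#' @param candidates Tibble with `verified` column, from [verify_dominance()].
#' @param params [analysis_params()].
#' @return `candidates` with `symmetry_pass` (logical) and `label`
#'   (+1 / -1 / NA) columns added.
#' @export
symmetry_check <- function(series, candidates, params = analysis_params()) {
  x <- series_values(series)
  n <- length(x)
  sw <- params$symmetry_window
  res <- purrr::pmap(list(candidates$index, candidates$kind, candidates$verified),
                     function(i, kind, verified) {
    if (!isTRUE(verified) || i - sw < 1L || i + sw > n) {
      return(list(pass = FALSE, label = NA_real_))
    }
    m_pre <- mean(abs(diff(x[(i - sw):i])))
    m_post <- mean(abs(diff(x[i:(i + sw)])))
    if (m_pre > m_post) {
      list(pass = TRUE, label = if (kind == "peak") 1 else -1)
    } else {
      list(pass = FALSE, label = NA_real_)
    }
  })
  dplyr::mutate(candidates,
                symmetry_pass = purrr::map_lgl(res, "pass"),
                label = purrr::map_dbl(res, "label"))
}

# cos of the vertex angle at P for triangle (L, P, R); coordinates are
# (time, intensity) pairs. Acute vertices give positive values.
law_of_cosines_cos <- function(p, l, r) {
  a2 <- sum((p - l)^2)
  b2 <- sum((p - r)^2)
  c2 <- sum((l - r)^2)
  (a2 + b2 - c2) / (2 * sqrt(a2 * b2))
}

#' Triangulation sharpness of verified candidates
#'
#' Each verified candidate is triangulated with the nearest local extremum of
#' the same kind on each side that was not itself retained as a verified
#' candidate (dicrotic peaks, notches, ripples). Coordinates are the sample
#' index on the time axis and the per-series z-scored value on the intensity
#' axis, which makes the angle dimensionless and invariant to gain and
#' offset. The cosine of the vertex angle at the candidate is returned:
#' positive for acute (sharp) vertices, negative for obtuse (blunt) ones.
#' Candidates missing a neighbour on either side get `NA`.
#'
#' @param series A `ppg_pulse_series` (or numeric vector).
#' @param candidates Tibble with `verified` column.
#' @return `candidates` with a `cos_theta` column added.
#' @export
triangulate_candidates <- function(series, candidates) {
  x <- series_values(series)
  z <- (x - mean(x)) / sd(x)
  ext <- find_extrema(x)
  cand_idx <- candidates$index[candidates$verified]
  # eligible neighbours: strict (non-plateau) extrema not retained as
  # verified candidates
  nb <- dplyr::filter(ext, !.data$plateau, !.data$index %in% cand_idx)
  nb_peak <- nb$index[nb$kind == "peak"]
  nb_trough <- nb$index[nb$kind == "trough"]
  cos_theta <- purrr::pmap_dbl(
    list(candidates$index, candidates$kind, candidates$verified),
    function(i, kind, verified) {
      if (!isTRUE(verified)) return(NA_real_)
      pool <- if (kind == "peak") nb_peak else nb_trough
      left <- pool[pool < i]
      right <- pool[pool > i]
      if (length(left) == 0L || length(right) == 0L) return(NA_real_)
      l <- max(left); r <- min(right)
      law_of_cosines_cos(c(i, z[i]), c(l, z[l]), c(r, z[r]))
    })
  dplyr::mutate(candidates, cos_theta = cos_theta)
}

#' Signal phase from triangulation sharpness
#'
#' Compares the mean vertex cosine of peak candidates against trough
#' candidates. An inverted signal has sharper troughs than peaks.
#'
#' @param candidates Tibble with `kind` and `cos_theta` columns.
#' @return `"inverted"`, `"non-inverted"` or `"indeterminate"` (either mean
#'   undefined, or equal means).
#' @export
phase_by_triangulation <- function(candidates) {
  ct <- candidates$cos_theta
  c_peak <- mean(ct[candidates$kind == "peak" & !is.na(ct)])
  c_trough <- mean(ct[candidates$kind == "trough" & !is.na(ct)])
  if (!is.finite(c_peak) || !is.finite(c_trough)) return("indeterminate")
  if (c_trough > c_peak) return("inverted")
  if (c_peak > c_trough) return("non-inverted")
  "indeterminate"
}

#' Run the full two-layer pulse analysis on a series
#'
#' Chains candidate gathering, dominance verification, the symmetry
#' criterion, triangulation, and the recording-level inversion estimate.
#'
#' @param series A `ppg_pulse_series`, e.g. from [prepare_channel()].
#' @param params [analysis_params()].
#' @param metric_params [metric_params()].
#' @return A `ppg_inversion` object: list with `candidates` (per-candidate
#'   diagnostics tibble), `estimate` (one-row tibble, see
#'   [estimate_inversion()]), `params`, `series_length`, `sampling_rate`,
#'   `channel`, `source_id`. Use [tidy()] for the candidate table and
#'   [glance()] for the estimate.
#' @export
analyze_pulses <- function(series, params = analysis_params(),
                           metric_params = ppginv::metric_params()) {
  cand <- gather_candidates(series, params)
  cand <- verify_dominance(series, cand, params)
  cand <- symmetry_check(series, cand, params)
  cand <- triangulate_candidates(series, cand)
  est <- estimate_inversion(cand, metric_params)
  structure(
    list(candidates = cand,
         estimate = est,
         params = params,
         metric_params = metric_params,
         series_length = nrow_or_length(series),
         sampling_rate = attr(series, "sampling_rate") %||% NA_real_,
         channel = attr(series, "channel") %||% NA_character_,
         source_id = attr(series, "source_id") %||% NA_character_),
    class = "ppg_inversion")
}

nrow_or_length <- function(series) {
  if (inherits(series, "data.frame")) nrow(series) else length(series)
}

#' @export
print.ppg_inversion <- function(x, ...) {
  e <- x$estimate
  cat("<ppg_inversion>", x$source_id, "/", x$channel, "\n")
  cat(sprintf("  pulses: %d   mu: %s   DOI: %s   phase: %s (triangulation: %s)\n",
              e$n_pulses,
              format(e$mu, digits = 4), format(e$doi, digits = 4),
              e$symmetry_phase, e$triangulation_phase))
  if (isTRUE(e$noise_flag)) cat("  flag: noise (|mu| below threshold)\n")
  if (isTRUE(e$disagreement_flag)) cat("  flag: layer disagreement\n")
  if (isTRUE(e$excluded)) cat("  excluded: no symmetry-passing pulses\n")
  invisible(x)
}
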