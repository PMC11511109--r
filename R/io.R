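# File formats, configuration and the end-to-end analysis orchestration.
#
# On disk a recording is a CSV (sample_index, ir, red, green, blue; 0-based
# sample_index) plus a JSON metadata sidecar (<stem>.json) and, when ground
# truth exists, a companion <stem>_truth.csv. In memory, tibbles use R's
# native 1-based `sample` column; the converters below own the offset.

RECORDING_COLUMNS <- c("sample_index", "ir", "red", "green", "blue")

#' Run configuration
#'
#' Bundles every tunable of the pipeline with its default. Unknown keys are
#' rejected so typos in config files fail loudly.
#'
#' @param passband_hz,stopband_hz,atten_db Baseline high-pass parameters
#'   ([highpass_baseline()]).
#' @param sg_order,sg_frame Savitzky-Golay parameters ([sgolay_smooth()]).
#' @param verify_window,symmetry_window Classifier windows
#'   ([analysis_params()]).
#' @param doi_threshold,noise_mu_threshold Metric thresholds
#'   ([metric_params()]).
#' @param exclude_source_ids Character vector of source ids to drop from
#'   aggregation (the manual-exclusion decision after flag review).
#' @return A list of class `ppg_run_config`.
#' @export
run_config <- function(passband_hz = 0.1, stopband_hz = 0.05, atten_db = 60,
                       sg_order = 20L, sg_frame = 999L,
                       verify_window = 150L, symmetry_window = 240L,
                       doi_threshold = 0.25, noise_mu_threshold = 0.3,
                       exclude_source_ids = character()) {
  structure(list(passband_hz = passband_hz, stopband_hz = stopband_hz,
                 atten_db = atten_db, sg_order = as.integer(sg_order),
                 sg_frame = as.integer(sg_frame),
                 verify_window = as.integer(verify_window),
                 symmetry_window = as.integer(symmetry_window),
                 doi_threshold = doi_threshold,
                 noise_mu_threshold = noise_mu_threshold,
                 exclude_source_ids = as.character(exclude_source_ids)),
            class = "ppg_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys override the defaults of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `ppg_run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")),
          class = "ppginv_schema")
  }
  do.call(run_config, vals)
}

#' Write a recording to disk
#'
#' Writes `<stem>.csv` (signals, 0-based `sample_index`), `<stem>.json`
#' (metadata incl. sampling rate) and, when ground truth is present,
#' `<stem>_truth.csv`. Output bytes are deterministic for identical input.
#'
#' @param recording A `ppg_recording`.
#' @param stem Output path without extension.
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "ppg_recording"))
  if (nrow(recording$signals) == 0L) {
    abort("recording has empty channels; nothing to write.",
          class = "ppginv_invalid_input")
  }
  validate_metadata(recording$metadata)
  csv_path <- paste0(stem, ".csv")
  json_path <- paste0(stem, ".json")
  sig <- recording$signals
  # fixed 6-decimal formatting keeps the bytes deterministic and immune to
  # last-ulp drift in CSV double parsing
  out <- tibble(sample_index = sig$sample - 1L,
                ir = round(sig$ir, 6), red = round(sig$red, 6),
                green = round(sig$green, 6), blue = round(sig$blue, 6))
  readr::write_csv(out, csv_path)
  meta <- c(as.list(recording$metadata), list(sampling_rate = recording$sampling_rate))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(csv_path, json_path)
  if (!is.null(recording$ground_truth)) {
    truth_path <- paste0(stem, "_truth.csv")
    gt <- dplyr::mutate(recording$ground_truth,
                        onset_sample = .data$onset_sample - 1L)
    readr::write_csv(gt, truth_path)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

validate_metadata <- function(meta) {
  pos <- meta$position_mm %||% NA
  if (!is.na(pos) && (pos != round(pos) || pos < -5 || pos > 5)) {
    abort(sprintf("metadata field position_mm = %s outside the protocol grid [-5, 5].",
                  format(pos)),
          class = "ppginv_schema")
  }
  pr <- meta$pressure %||% NA
  if (!is.na(pr) && !pr %in% PRESSURE_LEVELS) {
    abort(sprintf("metadata field pressure = \"%s\" must be one of %s.",
                  pr, paste(PRESSURE_LEVELS, collapse = "/")),
          class = "ppginv_schema")
  }
  invisible(meta)
}

#' Read a recording from disk
#'
#' Strict inverse of [write_recording()]: missing columns, length mismatches
#' or malformed metadata raise a parse error naming the offending field;
#' rows are never silently dropped.
#'
#' @param stem Path without extension, as passed to [write_recording()].
#' @return A `ppg_recording`.
#' @export
read_recording <- function(stem) {
  csv_path <- paste0(stem, ".csv")
  json_path <- paste0(stem, ".json")
  for (p in c(csv_path, json_path)) {
    if (!file.exists(p)) {
      abort(sprintf("missing file: %s.", p), class = "ppginv_schema")
    }
  }
  sig <- readr::read_csv(csv_path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(RECORDING_COLUMNS, names(sig))
  if (length(missing_cols) > 0L) {
    abort(sprintf("recording CSV is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "ppginv_schema")
  }
  if (nrow(sig) == 0L) {
    abort("recording CSV has no data rows.", class = "ppginv_schema")
  }
  if (!identical(as.integer(sig$sample_index), seq_len(nrow(sig)) - 1L)) {
    abort("sample_index must be contiguous and 0-based.", class = "ppginv_schema")
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate) || !is.numeric(meta$sampling_rate) ||
      meta$sampling_rate <= 0) {
    abort("metadata field sampling_rate is missing or invalid.",
          class = "ppginv_schema")
  }
  validate_metadata(meta)
  sampling_rate <- as.numeric(meta$sampling_rate)
  meta$sampling_rate <- NULL
  truth_path <- paste0(stem, "_truth.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
    truth$beat <- as.integer(truth$beat)
    truth$onset_sample <- as.integer(truth$onset_sample) + 1L
    truth$n_samples <- as.integer(truth$n_samples)
  }
  new_recording(
    signals = tibble(sample = seq_len(nrow(sig)), ir = sig$ir, red = sig$red,
                     green = sig$green, blue = sig$blue),
    sampling_rate = sampling_rate,
    metadata = as_tibble(lapply(meta, function(v) if (is.null(v)) NA else v)),
    ground_truth = truth)
}

#' Analyze recordings end to end
#'
#' For each recording and LED channel: preprocess, gather and classify pulse
#' candidates, and compute the inversion estimate with its flags. Per-series
#' failures (too short, unreadable, no pulses) are reported as excluded rows
#' with a reason, never dropped silently.
#'
#' @param recordings A list of `ppg_recording` objects, a single
#'   `ppg_recording`, or a character vector of file stems readable by
#'   [read_recording()].
#' @param config [run_config()].
#' @param channels LED channels to analyze. Default all four.
#' @param verbose Emit a message per flagged or excluded series.
#' @return Tibble with one row per recording-channel: `source_id`,
#'   `participant`, `position_mm`, `pressure`, `led`, `n_pulses`, `mu`,
#'   `doi`, `inverted`, `symmetry_phase`, `triangulation_phase`,
#'   `noise_flag`, `disagreement_flag`, `excluded`, `exclusion_reason`.
#' @export
run_analyze <- function(recordings, config = run_config(),
                        channels = LED_CHANNELS, verbose = FALSE) {
  if (inherits(recordings, "ppg_recording")) recordings <- list(recordings)
  aparams <- analysis_params(config$verify_window, config$symmetry_window)
  mparams <- metric_params(config$doi_threshold, config$noise_mu_threshold)
  rows <- list()
  n_failed <- 0L
  for (item in recordings) {
    rec <- tryCatch(
      if (is.character(item)) read_recording(item) else item,
      error = function(e) e)
    if (inherits(rec, "error")) {
      n_failed <- n_failed + 1L
      rows[[length(rows) + 1L]] <- excluded_row(
        source_id = if (is.character(item)) item else NA_character_,
        meta = NULL, led = NA_character_, reason = conditionMessage(rec))
      next
    }
    meta <- rec$metadata
    for (ch in channels) {
      est_row <- tryCatch({
        series <- prepare_channel(rec, ch,
                                  passband_hz = config$passband_hz,
                                  stopband_hz = config$stopband_hz,
                                  atten_db = config$atten_db,
                                  sg_order = config$sg_order,
                                  sg_frame = config$sg_frame)
        fit <- analyze_pulses(series, aparams, mparams)
        dplyr::bind_cols(meta_cols(meta, ch), fit$estimate,
                         tibble(exclusion_reason = NA_character_))
      }, error = function(e) {
        dplyr::bind_cols(
          meta_cols(meta, ch),
          tibble(n_pulses = 0L, mu = NA_real_, doi = NA_real_,
                 inverted = NA_integer_, symmetry_phase = "indeterminate",
                 triangulation_phase = "indeterminate", noise_flag = FALSE,
                 disagreement_flag = FALSE, excluded = TRUE,
                 exclusion_reason = conditionMessage(e)))
      })
      sid <- est_row$source_id
      if (sid %in% config$exclude_source_ids) {
        est_row$excluded <- TRUE
        est_row$exclusion_reason <- "listed in exclude_source_ids"
      } else if (isTRUE(est_row$excluded) && is.na(est_row$exclusion_reason)) {
        est_row$exclusion_reason <- "no symmetry-passing pulses"
      }
      if (verbose && (est_row$excluded || est_row$noise_flag || est_row$disagreement_flag)) {
        message(sprintf("%s/%s: %s", sid, ch,
                        est_row$exclusion_reason %||%
                          paste0(c("noise", "disagreement")[c(est_row$noise_flag,
                                                              est_row$disagreement_flag)],
                                 collapse = "+")))
      }
      rows[[length(rows) + 1L]] <- est_row
    }
  }
  if (length(recordings) > 0L && n_failed == length(recordings)) {
    abort("all inputs failed to load.", class = "ppginv_all_failed")
  }
  dplyr::bind_rows(rows)
}

meta_cols <- function(meta, led) {
  tibble(source_id = meta$source_id %||% NA_character_,
         participant = as.character(meta$participant %||% NA),
         position_mm = as.integer(meta$position_mm %||% NA),
         pressure = as.character(meta$pressure %||% NA),
         led = led)
}

excluded_row <- function(source_id, meta, led, reason) {
  dplyr::bind_cols(
    if (is.null(meta)) {
      tibble(source_id = source_id, participant = NA_character_,
             position_mm = NA_integer_, pressure = NA_character_, led = led)
    } else {
      meta_cols(meta, led)
    },
    tibble(n_pulses = 0L, mu = NA_real_, doi = NA_real_, inverted = NA_integer_,
           symmetry_phase = "indeterminate", triangulation_phase = "indeterminate",
           noise_flag = FALSE, disagreement_flag = FALSE, excluded = TRUE,
           exclusion_reason = reason))
}

#' Aggregate an estimates table and write the grid CSVs
#'
#' Thin wrapper around [aggregate_grid()] for file-based workflows: reads an
#' estimates CSV if given a path, writes the grid and the marginal summaries
#' as CSVs when `out_dir` is supplied (percent columns to two decimals).
#'
#' @param estimates Estimates tibble or path to an estimates CSV written by
#'   the CLI.
#' @param config [run_config()].
#' @param out_dir Optional output directory for the grid CSVs.
#' @return The `ppg_ooi_grid`, invisibly when writing files.
#' @export
run_aggregate <- function(estimates, config = run_config(), out_dir = NULL) {
  if (is.character(estimates)) {
    estimates <- readr::read_csv(estimates, show_col_types = FALSE, progress = FALSE)
    required <- c("participant", "position_mm", "pressure", "led", "doi", "excluded")
    missing_cols <- setdiff(required, names(estimates))
    if (length(missing_cols) > 0L) {
      abort(sprintf("estimates CSV is missing column(s): %s.",
                    paste(missing_cols, collapse = ", ")),
            class = "ppginv_schema")
    }
  }
  mparams <- metric_params(config$doi_threshold, config$noise_mu_threshold)
  grid <- aggregate_grid(estimates, mparams)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    as_pct <- function(df) dplyr::mutate(df, dplyr::across(
      dplyr::any_of(c("ooi", "occurrence", "mean_ooi", "median_occurrence")),
      ~ round(100 * .x, 2)))
    readr::write_csv(as_pct(grid$grid), file.path(out_dir, "ooi_grid.csv"))
    readr::write_csv(as_pct(grid$by_led), file.path(out_dir, "ooi_by_led.csv"))
    readr::write_csv(as_pct(grid$by_pressure), file.path(out_dir, "ooi_by_pressure.csv"))
    readr::write_csv(as_pct(grid$by_subject), file.path(out_dir, "ooi_by_subject.csv"))
    readr::write_csv(as_pct(grid$by_position), file.path(out_dir, "ooi_by_position.csv"))
    return(invisible(grid))
  }
  grid
}
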