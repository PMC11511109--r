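test_that("mean pulse label and degree of inversion follow their definitions", {
  expect_identical(mu_inversion(rep(1, 10)), 1)
  expect_identical(mu_inversion(rep(-1, 7)), -1)
  expect_identical(mu_inversion(c(1, 1, -1, -1)), 0)
  expect_error(mu_inversion(numeric(0)), class = "ppginv_no_pulses")
  expect_error(mu_inversion(c(1, 0.5)), class = "ppginv_invalid_input")
  expect_identical(degree_of_inversion(1), 0)
  expect_identical(degree_of_inversion(-1), 1)
  expect_identical(degree_of_inversion(0.5), 0.25)
  expect_error(degree_of_inversion(1.2), class = "ppginv_invalid_input")
})

test_that("DOI identity round-trips and the binary classification is strict", {
  mus <- seq(-1, 1, by = 0.05)
  expect_equal(1 - 2 * degree_of_inversion(mus), mus, tolerance = 1e-12)
  p <- metric_params()
  expect_identical(classify_inverted(0.25, p), 0L)  # boundary is strict
  expect_identical(classify_inverted(0.26, p), 1L)
  expect_identical(classify_inverted(0, p), 0L)
  expect_identical(classify_inverted(1, p), 1L)
})

test_that("occurrence of inversion counts threshold exceedances over analyzable recordings", {
  p <- metric_params()
  dois <- c(0.8, rep(0.01, 11))
  expect_equal(occurrence_of_inversion(dois, p), 1 / 12)
  expect_identical(occurrence_of_inversion(rep(0, 12), p), 0)
  expect_identical(occurrence_of_inversion(rep(0.9, 5), p), 1)
  expect_error(occurrence_of_inversion(numeric(0), p), class = "ppginv_empty_cell")
  # monotone: adding an inverted recording never decreases OOI
  expect_gte(occurrence_of_inversion(c(dois, 0.9), p),
             occurrence_of_inversion(dois, p))
  # permutation invariant
  expect_identical(occurrence_of_inversion(sample(dois), p),
                   occurrence_of_inversion(dois, p))
})

test_that("adding an inverted pulse label never decreases DOI", {
  labels <- c(rep(1, 8), rep(-1, 2))
  base <- degree_of_inversion(mu_inversion(labels))
  expect_gte(degree_of_inversion(mu_inversion(c(labels, -1))), base)
  expect_lte(degree_of_inversion(mu_inversion(c(labels, 1))), base)
  expect_identical(degree_of_inversion(mu_inversion(rev(labels))), base)
})

test_that("estimates carry phases and flags without altering the statistics", {
  # consistent non-inverted candidates, sharp peaks
  cand <- tibble::tibble(
    kind = rep(c("peak", "trough"), each = 5),
    symmetry_pass = rep(c(TRUE, FALSE), each = 5),
    label = c(rep(1, 5), rep(NA_real_, 5)),
    cos_theta = c(rep(0.5, 5), rep(-0.8, 5)))
  est <- estimate_inversion(cand)
  expect_identical(est$n_pulses, 5L)
  expect_identical(est$mu, 1)
  expect_identical(est$doi, 0)
  expect_identical(est$symmetry_phase, "non-inverted")
  expect_identical(est$triangulation_phase, "non-inverted")
  expect_false(est$noise_flag)
  expect_false(est$disagreement_flag)
  expect_false(est$excluded)
  # disagreement: symmetry non-inverted but troughs sharper
  cand2 <- cand
  cand2$cos_theta <- c(rep(-0.8, 5), rep(0.5, 5))
  est2 <- estimate_inversion(cand2)
  expect_identical(est2$mu, 1)               # flag does not alter mu
  expect_true(est2$disagreement_flag)
  # low |mu| raises the noise flag
  cand3 <- tibble::tibble(kind = rep("peak", 10), symmetry_pass = TRUE,
                          label = c(rep(1, 6), rep(-1, 4)), cos_theta = NA_real_)
  est3 <- estimate_inversion(cand3)
  expect_equal(est3$mu, 0.2)
  expect_true(est3$noise_flag)
  expect_identical(est3$triangulation_phase, "indeterminate")
  expect_false(est3$disagreement_flag)       # needs both phases defined
  # no symmetry-passing pulses: excluded
  cand4 <- tibble::tibble(kind = "peak", symmetry_pass = FALSE,
                          label = NA_real_, cos_theta = NA_real_)
  est4 <- estimate_inversion(cand4)
  expect_true(est4$excluded)
  expect_true(is.na(est4$mu))
})

test_that("grid aggregation recovers a planted inversion plan and keeps books straight", {
  # synthetic estimates table: 4 participants x 3 positions x 2 pressures x 2 LEDs
  grid_in <- tidyr::expand_grid(participant = sprintf("S%d", 1:4),
                                position_mm = -1:1,
                                pressure = c("low", "high"),
                                led = c("ir", "green"))
  planted <- grid_in$participant == "S1" & grid_in$position_mm == 0 & grid_in$led == "ir"
  est <- dplyr::mutate(grid_in,
                       source_id = sprintf("r%d", dplyr::row_number()),
                       doi = ifelse(planted, 0.9, 0.02),
                       excluded = FALSE)
  grid <- aggregate_grid(est)
  cells <- grid$grid
  hot <- dplyr::filter(cells, .data$position_mm == 0, .data$led == "ir")
  expect_identical(nrow(hot), 2L)             # both pressures
  expect_equal(hot$ooi, c(0.25, 0.25))        # 1 of 4 participants
  expect_identical(sum(cells$n_inverted), 2L)
  cold <- dplyr::filter(cells, !(.data$position_mm == 0 & .data$led == "ir"))
  expect_true(all(cold$ooi == 0))
  # grand mean per position equals the mean of the per-LED marginals
  by_pos <- grid$by_position
  led_mean <- grid$by_led |>
    dplyr::group_by(.data$position_mm) |>
    dplyr::summarise(m = mean(.data$ooi))
  expect_equal(by_pos$mean_ooi, led_mean$m)
  # excluded recordings leave every denominator
  est2 <- est
  est2$excluded[est2$participant == "S4"] <- TRUE
  grid2 <- aggregate_grid(est2)
  expect_true(all(grid2$grid$n_recordings == 3L))
  expect_equal(dplyr::filter(grid2$grid, .data$position_mm == 0,
                             .data$led == "ir")$ooi, c(1 / 3, 1 / 3))
  # duplicate measurement keys are an error
  expect_error(aggregate_grid(dplyr::bind_rows(est, est[1, ])),
               class = "ppginv_duplicate_measurement")
  # an all-excluded table aggregates to an empty grid with a warning
  est3 <- dplyr::mutate(est, excluded = TRUE)
  expect_warning(grid3 <- aggregate_grid(est3), "excluded")
  expect_identical(nrow(grid3$grid), 0L)
})
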