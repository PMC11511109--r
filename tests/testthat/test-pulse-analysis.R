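test_that("candidate gathering finds strict extrema, plateau midpoints, and drops edge candidates", {
  # monotone ramp: no interior extrema
  expect_identical(nrow(gather_candidates(seq(0, 1, length.out = 1000))), 0L)
  # constant series: no strict extrema
  expect_identical(nrow(gather_candidates(rep(2, 1000))), 0L)
  # one period of a sine: peak at 1/4, trough at 3/4 (within one sample)
  n <- 4000L
  x <- sin(2 * pi * (0:(n - 1)) / n)
  cand <- gather_candidates(x)
  expect_identical(cand$kind, c("peak", "trough"))
  expect_lt(abs(cand$index[1] - (n / 4 + 1)), 2)
  expect_lt(abs(cand$index[2] - (3 * n / 4 + 1)), 2)
  # plateau contributes a single midpoint candidate
  x <- c(rep(0, 300), seq(0, 0.99, length.out = 100), rep(1, 11),
         seq(0.99, 0, length.out = 100), rep(0, 300))
  cand <- gather_candidates(x)
  expect_identical(nrow(cand), 1L)
  expect_true(cand$plateau)
  expect_identical(cand$index, 406L)  # midpoint of the 401..411 plateau
  # candidates within the symmetry window of either end are dropped
  x <- sin(2 * pi * (0:999) / 250)
  cand <- gather_candidates(x)
  all_ext <- ppginv:::find_extrema(x)
  expect_gt(nrow(all_ext), nrow(cand))  # some extrema lie in the margins
  expect_true(all(cand$index > 240 & cand$index <= 1000 - 240))
  dropped <- setdiff(all_ext$index, cand$index)
  expect_true(all(dropped <= 240 | dropped > 1000 - 240))
  expect_error(gather_candidates(c(1, 2)), class = "ppginv_too_short")
})

test_that("dominance verification matches the +/-150-sample rule including ties", {
  params <- analysis_params()
  # clean 60 bpm train: exactly the systolic peaks are dominant (dicrotic
  # peaks are shadowed by the decaying systolic limb within 150 samples)
  series <- clean_train(duration_s = 10)
  cand <- verify_dominance(series, gather_candidates(series, params), params)
  peaks <- cand[cand$kind == "peak" & cand$verified, ]
  expect_gte(nrow(peaks), 8)  # ~one per beat inside the edge margins
  x <- series$value
  for (i in peaks$index) {  # brute-force dominance scan
    w <- x[max(1, i - 150):min(length(x), i + 150)]
    expect_true(all(w <= x[i]))
  }
  # systolic summits dominate their windows; dicrotic peaks must not
  dicrotic <- cand[cand$kind == "peak" & !cand$verified, ]
  expect_gt(nrow(dicrotic), 0)
  expect_true(all(x[dicrotic$index] < max(x) * 0.6))
  # a larger sample 100 later disqualifies a peak
  x <- rep(0, 1000); x[500] <- 1; x[600] <- 2
  cand <- verify_dominance(x, gather_candidates(x, params), params)
  expect_false(cand$verified[cand$index == 500])
  expect_true(cand$verified[cand$index == 600])
  # equal-valued neighbours do not disqualify (strict comparison)
  x2 <- c(rep(1, 300), 0.8, rep(1, 99), 0.5, rep(1, 149), 0.5, rep(1, 300))
  # trough at 401 has an equal-valued sample at 551 inside its window: still verified
  cand <- verify_dominance(x2, gather_candidates(x2, params), params)
  tr <- cand[cand$index == 401L, ]
  expect_identical(tr$kind, "trough")
  expect_true(tr$verified)
})

test_that("symmetry criterion compares mean absolute tangents strictly", {
  params <- analysis_params()
  # rise slope 2 then fall slope 1: m_pre = 2 > m_post = 1, peak labelled +1
  tri <- triangle_series(2, 1)
  cand <- tibble::tibble(index = tri$apex, kind = "peak", plateau = FALSE, verified = TRUE)
  out <- symmetry_check(tri$x, cand, params)
  expect_true(out$symmetry_pass)
  expect_identical(out$label, 1)
  # mirrored around a trough: labelled -1
  tri <- triangle_series(2, 1)
  cand <- tibble::tibble(index = tri$apex, kind = "trough", plateau = FALSE, verified = TRUE)
  out <- symmetry_check(-tri$x, cand, params)
  expect_true(out$symmetry_pass)
  expect_identical(out$label, -1)
  # symmetric triangle ties and fails (strict inequality)
  tri <- triangle_series(1, 1)
  cand <- tibble::tibble(index = tri$apex, kind = "peak", plateau = FALSE, verified = TRUE)
  out <- symmetry_check(tri$x, cand, params)
  expect_false(out$symmetry_pass)
  expect_true(is.na(out$label))
  # reversed asymmetry (slow rise, steep fall) fails
  tri <- triangle_series(1, 2)
  cand <- tibble::tibble(index = tri$apex, kind = "peak", plateau = FALSE, verified = TRUE)
  expect_false(symmetry_check(tri$x, cand, params)$symmetry_pass)
})

test_that("the vertex cosine follows the law of cosines and its sign convention", {
  loc <- ppginv:::law_of_cosines_cos
  expect_equal(loc(c(1, 1), c(0, 0), c(2, 0)), 0)            # right angle
  expect_equal(loc(c(1, 2), c(0, 0), c(2, 0)), 0.6)          # acute, sharp apex
  expect_equal(loc(c(1, 0.2), c(0, 0), c(2, 0)), (1.04 + 1.04 - 4) / (2 * 1.04))
  # sharper apex -> larger cosine
  expect_gt(loc(c(1, 3), c(0, 0), c(2, 0)), loc(c(1, 2), c(0, 0), c(2, 0)))
})

test_that("triangulation uses nearest non-candidate extrema and is gain/offset invariant", {
  series <- clean_train(duration_s = 20)
  cand <- gather_candidates(series)
  cand <- verify_dominance(series, cand)
  cand <- symmetry_check(series, cand)
  out <- triangulate_candidates(series, cand)
  with_angle <- out[!is.na(out$cos_theta), ]
  expect_gt(nrow(with_angle), 10)
  expect_true(all(with_angle$cos_theta >= -1 & with_angle$cos_theta <= 1))
  # positive affine transform of intensity leaves every cosine unchanged
  series2 <- series
  series2$value <- 3.2 * series$value + 500
  out2 <- triangulate_candidates(series2, cand)
  expect_equal(out2$cos_theta, out$cos_theta, tolerance = 1e-9)
  # phase of a clean non-inverted recording: peaks sharper than troughs
  expect_identical(phase_by_triangulation(out), "non-inverted")
})

test_that("phase by triangulation orders mean cosines and degrades to indeterminate", {
  cand <- tibble::tibble(kind = c("trough", "trough", "peak"),
                         cos_theta = c(0.6, 0.6, -0.9))
  expect_identical(phase_by_triangulation(cand), "inverted")
  cand$cos_theta <- NA_real_
  expect_identical(phase_by_triangulation(cand), "indeterminate")
  cand <- tibble::tibble(kind = c("trough", "peak"), cos_theta = c(0.3, 0.3))
  expect_identical(phase_by_triangulation(cand), "indeterminate")
})

test_that("analyzing the negated series swaps kinds, flips labels, keeps cosines", {
  series <- clean_train(duration_s = 20, fraction_inverted = 0.4, seed = 23,
                        noise_sd = 0.02)
  neg <- series
  neg$value <- -series$value
  f1 <- analyze_pulses(series)
  f2 <- analyze_pulses(neg)
  expect_identical(f1$candidates$index, f2$candidates$index)
  expect_identical(ifelse(f1$candidates$kind == "peak", "trough", "peak"),
                   f2$candidates$kind)
  expect_identical(f1$candidates$verified, f2$candidates$verified)
  expect_identical(f1$candidates$symmetry_pass, f2$candidates$symmetry_pass)
  expect_identical(f1$candidates$label, -f2$candidates$label)
  expect_identical(f1$candidates$cos_theta, f2$candidates$cos_theta)
  expect_identical(f1$estimate$mu, -f2$estimate$mu)
})

test_that("gather + dominance agrees with the exhaustive oracle on small series", {
  withr::local_seed(41)
  params <- analysis_params()
  for (rep in 1:8) {
    n <- sample(600:2000, 1)
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 12, 12), sides = 2))
    x[is.na(x)] <- 0
    if (rep %% 2 == 0) x <- round(x, 1)  # induce ties and plateaus
    got <- verify_dominance(x, gather_candidates(x, params), params)
    want <- oracle_candidates(x)
    expect_identical(got$index, as.integer(want$index))
    expect_identical(got$kind, want$kind)
    expect_identical(got$verified, want$verified)
  }
})
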