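test_that("baseline correction recovers additive constants on noiseless curves", {
  # exponential plus constant: baseline identifiable from the early cycles
  s <- simulate_amplification(e = 2, n0 = 0.001, baseline = 0.05)
  cv <- correct_baseline(s$curve)
  expect_equal(cv$baseline, 0.05, tolerance = 1e-6)
  expect_equal(cv$corrected, s$curve$signal - cv$baseline)

  # already baseline-free
  s0 <- simulate_amplification(e = 2, n0 = 0.001)
  expect_equal(correct_baseline(s0$curve)$baseline, 0, tolerance = 1e-6)

  # constant signal: flat/failed reaction
  flat <- amp_curve(1:40, rep(0.05, 40))
  expect_error(correct_baseline(flat), "[Ff]lat")
  expect_error(correct_baseline(amp_curve(1:10, 2^(1:10))), "at least 15 cycles")
})

test_that("window-of-linearity fit recovers efficiency on noiseless curves", {
  s <- simulate_amplification(e = 1.9, n0 = 0.001)
  cv <- fit_efficiency(correct_baseline(s$curve))
  expect_equal(cv$efficiency, 1.9, tolerance = 1e-6)
  expect_false(cv$flagged)
  expect_gte(cv$r_squared, 0.99)

  # plateau clamps growth from ~cycle 12: window must stay in the
  # exponential phase and the efficiency stays exact
  sp <- simulate_amplification(e = 2, n0 = 0.001, plateau = 3)
  cvp <- fit_efficiency(correct_baseline(sp$curve))
  expect_lt(cvp$window[2], 12)
  expect_equal(cvp$efficiency, 2, tolerance = 1e-6)

  # efficiency is invariant to multiplying the whole curve by a constant
  scaled <- amp_curve(s$curve$cycle, s$curve$signal * 37)
  cvs <- fit_efficiency(correct_baseline(scaled))
  expect_equal(cvs$efficiency, cv$efficiency, tolerance = 1e-9)

  expect_error(fit_efficiency(s$curve), "correct_baseline")
  expect_error(fit_efficiency(correct_baseline(s$curve), window_len = 3),
               "4-7")
})

test_that("noisy curves are flagged below the R^2 gate but still fitted", {
  s <- simulate_amplification(e = 1.85, n0 = 1e-4, baseline = 0.05,
                              noise_sd = 0.2, seed = 2)
  cv <- suppressWarnings(fit_efficiency(correct_baseline(s$curve)))
  expect_true(is.finite(cv$efficiency))
  # with 20% multiplicative noise the quality gate should usually trip;
  # either way the flag must agree with the fitted R^2
  expect_identical(cv$flagged, cv$r_squared < 0.99)
})

test_that("efficiency recovery on realistic noisy curves stays in the
           Monte-Carlo-calibrated band", {
  # oracle calibration (200 curves, E = 1.85, 2% multiplicative noise):
  # ~97.5% of recovered efficiencies fall within 0.05 of truth,
  # median absolute error ~0.011
  err <- vapply(1:50, function(i) {
    s <- simulate_amplification(1.85, 1e-4, baseline = 0.05,
                                noise_sd = 0.02, seed = 1000 + i)
    cv <- suppressWarnings(fit_efficiency(correct_baseline(s$curve)))
    cv$efficiency - 1.85
  }, numeric(1))
  expect_gte(mean(abs(err) <= 0.05), 0.9)
  expect_lt(stats::median(abs(err)), 0.03)
})

test_that("amplicon groups pool efficiencies and extract fractional Cts", {
  # closed form: 0.01 * 2^c crosses 0.16 at cycle 4
  s <- simulate_amplification(e = 2, n0 = 0.01)
  cv <- fit_efficiency(correct_baseline(s$curve))
  g <- amplicon_group(list(cv), threshold = 0.16)
  expect_equal(g$cts$ct, 4, tolerance = 1e-9)

  # two identical curves: group efficiency = per-curve, equal Cts
  cv2 <- fit_efficiency(correct_baseline(
    simulate_amplification(e = 2, n0 = 0.01, well_id = "w2")$curve))
  g2 <- amplicon_group(list(cv, cv2))
  expect_equal(g2$efficiency, cv$efficiency)
  expect_equal(g2$cts$ct[1], g2$cts$ct[2], tolerance = 1e-9)

  # doubling the template lowers Ct by exactly one cycle at E = 2
  ga <- amplicon_group(list(fit_efficiency(correct_baseline(
    simulate_amplification(e = 2, n0 = 0.001)$curve))), threshold = 0.5)
  gb <- amplicon_group(list(fit_efficiency(correct_baseline(
    simulate_amplification(e = 2, n0 = 0.002)$curve))), threshold = 0.5)
  expect_equal(gb$cts$ct - ga$cts$ct, -1, tolerance = 1e-9)

  # recovered Ct matches the generator's analytic truth
  expect_equal(ga$cts$ct, simulate_amplification(2, 0.001)$truth$ct_at(0.5),
               tolerance = 1e-3)

  # threshold never reached -> missing Ct
  low <- amplicon_group(list(cv), threshold = 1e12)
  expect_true(is.na(low$cts$ct))

  expect_error(amplicon_group(list()), "No curves")
  expect_error(amplicon_group(list(s$curve)), "fit_efficiency")
})

test_that("raw curve files read into per-well curves", {
  d <- tidyr::expand_grid(well_id = c("w1", "w2"), cycle = 1:40) |>
    dplyr::mutate(amplicon_id = "amp1",
                  fluorescence = ifelse(well_id == "w1", 0.001, 0.002) * 2^cycle)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, f)
  curves <- read_amp_curves(f)
  expect_length(curves, 2)
  expect_equal(curves[[1]]$well_id, "w1")
  expect_equal(curves[[2]]$signal[1], 0.004)
})
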