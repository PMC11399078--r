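# Module-level fit tests run scaled-down configurations (coarser grids,
# fewer realizations, small ROIs) so the default suite stays fast; the full
# stated parameter-recovery worlds live in test-acceptance.R.

test_that("labeling_efficiency counts ratio and guards", {
  expect_equal(labeling_efficiency(50, 50), 0.5)
  expect_equal(labeling_efficiency(100, 0), 0.0)
  expect_equal(labeling_efficiency(25, 75), 0.75)
  expect_error(labeling_efficiency(0, 0), "zero")
  expect_error(labeling_efficiency(-1, 5), ">= 0")
  # scale invariance
  for (k in c(2L, 7L, 100L)) {
    expect_equal(labeling_efficiency(25L * k, 75L * k), 0.75)
  }
})

test_that("fit_labeling_efficiency validates inputs and respects LE_max", {
  roi <- roi_rect(0, 0, 5000, 5000)
  h <- histogram_nnd(runif(100, 0, 500))
  expect_error(fit_labeling_efficiency(h, 0, 10, roi = roi), "> 0")
  expect_error(fit_labeling_efficiency(histogram_nnd(numeric(0)), 10, 10, roi = roi),
               "empty")
  cfg <- fit_config(grid_step = 0.05, n_realizations = 3, seed = 5)
  # target density below reference: candidate grid capped at the ratio
  set.seed(51)
  f <- simulate_two_channel_field(sim_params(roi, 30, 8, 2, seed = 1), seed = 2)
  hh <- histogram_nnd(cross_nnd(f$reference, f$target))
  fit <- fit_labeling_efficiency(hh, 32, 10, d_off = 15, uncertainty = 5,
                                 roi = roi, config = cfg)
  expect_equal(fit$le_max, 10 / 32)
  expect_lte(fit$labeling_efficiency, fit$le_max)
  expect_true(all(fit$residual_curve$le <= fit$le_max))
})

test_that("pure-CSR data yield a near-zero labeling efficiency", {
  roi <- roi_rect(0, 0, 10000, 10000)
  f <- simulate_two_channel_field(sim_params(roi, 30, 30, 0, uncertainty = 5),
                                  seed = 52)
  h <- histogram_nnd(cross_nnd(f$reference, f$target))
  fit <- fit_labeling_efficiency(h, nrow(f$reference) / 100, nrow(f$target) / 100,
                                 d_off = 15, uncertainty = 5, roi = roi,
                                 config = fit_config(grid_step = 0.02,
                                                     n_realizations = 8, seed = 6))
  expect_lte(fit$labeling_efficiency, 0.05)
})

test_that("residual curve attains its minimum at the returned estimate", {
  roi <- roi_rect(0, 0, 8000, 8000)
  f <- simulate_two_channel_field(sim_params(roi, 15, 15, 15, d_off = 15,
                                             uncertainty = 5), seed = 53)
  h <- histogram_nnd(cross_nnd(f$reference, f$target))
  a <- roi_area(roi)
  fit <- fit_labeling_efficiency(h, nrow(f$reference) / a, nrow(f$target) / a,
                                 d_off = 15, uncertainty = 5, roi = roi,
                                 config = fit_config(grid_step = 0.05,
                                                     n_realizations = 5, seed = 7))
  rc <- fit$residual_curve
  expect_equal(rc$le[which.min(rc$rss)], fit$labeling_efficiency)
  expect_equal(min(rc$rss), fit$best_residual)
  expect_equal(fit$labeling_efficiency,
               fit$p_ref_target / (fit$p_ref + fit$p_ref_target))
  # roughly recovers the true mixing (0.5) even at this small scale
  expect_lt(abs(fit$labeling_efficiency - 0.5), 0.1)
})

test_that("fits are deterministic given the seed", {
  roi <- roi_rect(0, 0, 6000, 6000)
  f <- simulate_two_channel_field(sim_params(roi, 20, 20, 10), seed = 54)
  h <- histogram_nnd(cross_nnd(f$reference, f$target))
  a <- roi_area(roi)
  cfg <- fit_config(grid_step = 0.1, n_realizations = 3, seed = 11)
  f1 <- fit_labeling_efficiency(h, nrow(f$reference) / a, nrow(f$target) / a,
                                roi = roi, config = cfg)
  f2 <- fit_labeling_efficiency(h, nrow(f$reference) / a, nrow(f$target) / a,
                                roi = roi, config = cfg)
  expect_identical(f1$residual_curve, f2$residual_curve)
})

test_that("fit_dimer_fraction recovers a monomer-only field and validates", {
  roi <- roi_rect(0, 0, 10000, 10000)
  f <- simulate_single_channel_field(sim_params(roi, rho_ref_mono = 30,
                                                uncertainty = 5), seed = 55)
  h <- histogram_nnd(self_nnd(f))
  expect_error(fit_dimer_fraction(h, 30, labeling_efficiency = 0, roi = roi),
               "labeling_efficiency")
  fit <- fit_dimer_fraction(h, sum(f$detected) / 100, labeling_efficiency = 1,
                            d_off = 15, uncertainty = 5, roi = roi,
                            config = fit_config(grid_step = 0.02,
                                                n_realizations = 8, seed = 8))
  expect_lte(fit$dimer_fraction, 0.05)
  expect_true(fit$apparent)
  # density identity: (rho_mono + 2 rho_dimer) * LE = rho_obs by construction
  expect_equal((fit$rho_mono + 2 * fit$rho_dimer) * fit$labeling_efficiency,
               fit$rho_obs)
  expect_equal(fit$dimer_fraction,
               2 * fit$rho_dimer / (fit$rho_mono + 2 * fit$rho_dimer))
})

test_that("correct_dimer_fraction wraps the corrected re-fit", {
  roi <- roi_rect(0, 0, 10000, 10000)
  p <- sim_params(roi, rho_ref_mono = 20, rho_dimer = 10, d_off = 15,
                  uncertainty = 5, labeling_efficiency = 0.6)
  f <- simulate_single_channel_field(p, seed = 56)
  h <- histogram_nnd(self_nnd(f))
  rho_obs <- sum(f$detected) / 100
  cfg <- fit_config(grid_step = 0.05, n_realizations = 8, seed = 9)
  apparent <- fit_dimer_fraction(h, rho_obs, labeling_efficiency = 1,
                                 d_off = 15, uncertainty = 5, roi = roi, config = cfg)
  corrected <- correct_dimer_fraction(apparent, 0.6)
  expect_false(corrected$apparent)
  expect_lt(apparent$dimer_fraction, corrected$dimer_fraction)
  expect_identical(corrected$apparent_fit$residual_curve, apparent$residual_curve)
  expect_error(correct_dimer_fraction(corrected, 0.6), "apparent")
  # LE = 1 correction is the identity up to the apparent flag
  same <- correct_dimer_fraction(apparent, 1)
  expect_equal(same$dimer_fraction, apparent$dimer_fraction)
  expect_identical(same$residual_curve, apparent$residual_curve)
})

test_that("fit results serialize to JSON with grid, residuals and seed", {
  roi <- roi_rect(0, 0, 5000, 5000)
  f <- simulate_two_channel_field(sim_params(roi, 20, 20, 10), seed = 57)
  h <- histogram_nnd(cross_nnd(f$reference, f$target))
  a <- roi_area(roi)
  fit <- fit_labeling_efficiency(h, nrow(f$reference) / a, nrow(f$target) / a,
                                 roi = roi,
                                 config = fit_config(grid_step = 0.1,
                                                     n_realizations = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$type, "labeling_efficiency")
  expect_equal(j$seed, 3)
  expect_equal(j$residual_curve$rss, fit$residual_curve$rss)
})
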