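# an exactly-continuous member of the model family, used wherever a
# constrained refit must reproduce its generator to machine precision
# (the published coefficients are continuous only to printed rounding)
continuous_icon_model <- function() {
  low <- c(0.5278, 0.5730, -0.2871, -0.5845)
  low_at_1 <- sum(low)
  delta_r_model(low, c(low_at_1 - 0.2424, 0.2424),
                valid_range = c(0.001, 44.91), continuity_tol = 1e-9,
                provenance = "continuous variant")
}

table1_volumes <- c(0.001, 0.10, 0.19, 0.55, 0.99, 1.00, 1.94, 2.94, 3.95,
                    6.91, 20.41, 44.91)

test_that("published coefficients reproduce the fitted calibration columns", {
  m <- default_gk_icon_model()
  t1 <- table1_fixture()
  low_rows <- !is.na(t1$delta_r_fit_low_cm)
  high_rows <- !is.na(t1$delta_r_fit_high_cm)
  got_low <- eval_delta_r(m, t1$v_ptv_cc[low_rows & t1$v_ptv_cc < 1])
  expect_true(all(abs(got_low - t1$delta_r_fit_low_cm[low_rows & t1$v_ptv_cc < 1]) <= 0.001))
  got_high <- eval_delta_r(m, t1$v_ptv_cc[high_rows & t1$v_ptv_cc > 1])
  expect_true(all(abs(got_high - t1$delta_r_fit_high_cm[high_rows & t1$v_ptv_cc > 1]) <= 0.001))
  # the boundary row tabulates both branches: 0.229 (low) and 0.224 (high)
  expect_lte(abs(sum(m$low_coeffs) - 0.229), 0.001)
  expect_lte(abs(m$high_coeffs[1] + m$high_coeffs[2] - 0.224), 0.001)
})

test_that("the two branches agree at the 1 cm^3 boundary", {
  m <- default_gk_icon_model()
  expect_lte(abs(eval_delta_r(m, 1) - 0.226), 0.003)
  # at the boundary the mean of the branches is returned
  low <- 0.5278 + 0.5730 - 0.2871 - 0.5845
  high <- -0.018 + 0.2424
  expect_equal(eval_delta_r(m, 1), (low + high) / 2, tolerance = 1e-12)
})

test_that("a constant model evaluates to its constant everywhere", {
  k <- 0.31
  m <- delta_r_model(c(k, 0, 0, 0), c(k, 0), valid_range = c(0.001, 50))
  expect_equal(eval_delta_r(m, c(0.01, 0.5, 1, 7, 44)), rep(k, 5))
})

test_that("evaluation outside the calibrated range warns but evaluates", {
  m <- default_gk_icon_model()
  expect_warning(v <- eval_delta_r(m, 50), "outside the calibrated range")
  expect_gt(v, eval_delta_r(m, 44.91))
  expect_warning(eval_delta_r(m, 5e-4), "extrapolating")
})

test_that("a non-positive drop-off is a hard error, not a silent floor", {
  # cube-root branch crosses zero near 4e-4 cm^3; a model whose boundary
  # sits below that exposes the negative region
  b <- 1e-4
  h <- -0.018 + 0.2424 * b^(1 / 3)
  m <- delta_r_model(c(h, 0, 0, 0), c(-0.018, 0.2424), boundary_volume = b,
                     valid_range = c(1e-5, 1))
  expect_error(suppressWarnings(eval_delta_r(m, 2e-4)), "non-positive drop-off")
})

test_that("measured drop-off is the difference of equivalent radii", {
  expect_equal(measured_delta_r(4 * pi / 3, 4 * pi / 3 * 8), 1, tolerance = 1e-12)
  # forward construction then inversion
  v <- 1.94
  v50 <- sphere_volume(effective_radius(v) + 0.29)
  expect_equal(measured_delta_r(v, v50), 0.29, tolerance = 1e-12)
  # calibration row: 0.99 cm^3 measured 0.22 cm
  v50b <- sphere_volume(effective_radius(0.99) + 0.22)
  expect_equal(measured_delta_r(0.99, v50b), 0.22, tolerance = 1e-12)
  expect_error(measured_delta_r(2, 1.5), "invalid measurement")
  expect_error(measured_delta_r(2, 2), "invalid measurement")
})

test_that("constrained fit recovers a continuous generator exactly", {
  gen <- continuous_icon_model()
  vols <- table1_volumes[table1_volumes != 1]
  meas <- make_phantom_calibration_set(gen, vols, noise_sd = 0)
  fit <- fit_delta_r_model(meas)
  expect_equal(fit$low_coeffs, gen$low_coeffs, tolerance = 1e-6)
  expect_equal(fit$high_coeffs, gen$high_coeffs, tolerance = 1e-6)
  # continuity of the refit model at machine precision
  b <- fit$boundary_volume
  lo <- sum(fit$low_coeffs * c(1, b, b^(2 / 3), b^(1 / 3)))
  hi <- fit$high_coeffs[1] + fit$high_coeffs[2] * b^(1 / 3)
  expect_lt(abs(lo - hi), 1e-9)
})

test_that("refit of the phantom calibration data beats the printed fit's worst residual", {
  fit <- fit_delta_r_model(table1_measurements())
  expect_lte(fit$fit$max_abs_residual, 0.04)
  b <- fit$boundary_volume
  lo <- sum(fit$low_coeffs * c(1, b, b^(2 / 3), b^(1 / 3)))
  hi <- fit$high_coeffs[1] + fit$high_coeffs[2] * b^(1 / 3)
  expect_lt(abs(lo - hi), 1e-9)
  # residual report covers every measurement
  expect_equal(nrow(fit$fit$residuals), 11)
})

test_that("noisy calibration data still recovers the drop-off curve", {
  gen <- continuous_icon_model()
  vols <- rep(table1_volumes[table1_volumes != 1], 2)
  meas <- make_phantom_calibration_set(gen, vols, noise_sd = 0.01, seed = 1)
  fit <- fit_delta_r_model(meas)
  at <- table1_volumes[table1_volumes != 1]
  expect_true(all(abs(eval_delta_r(fit, at) - eval_delta_r(gen, at)) <= 0.02))
})

test_that("underdetermined branches are reported by name", {
  gen <- continuous_icon_model()
  few_low <- make_phantom_calibration_set(gen, c(0.1, 0.5, 2, 5, 10, 20), noise_sd = 0)
  expect_error(fit_delta_r_model(few_low), "low branch underdetermined")
  few_high <- make_phantom_calibration_set(gen, c(0.01, 0.1, 0.3, 0.5, 0.9, 5), noise_sd = 0)
  expect_error(fit_delta_r_model(few_high), "high branch underdetermined")
})

test_that("free-exponent fit recovers a non-cube-root drop-off law", {
  low <- c(0.5278, 0.5730, -0.2871, -0.5845)
  gen <- delta_r_model(low, c(sum(low) - 0.30, 0.30), high_exponent = 0.5,
                       valid_range = c(0.001, 45), continuity_tol = 1e-9)
  vols <- c(0.005, 0.05, 0.2, 0.5, 0.9, 2, 5, 10, 20, 40)
  meas <- make_phantom_calibration_set(gen, vols, noise_sd = 0)
  fit <- fit_delta_r_model(meas, free_exponent = TRUE)
  expect_equal(fit$high_exponent, 0.5, tolerance = 1e-3)
  expect_equal(eval_delta_r(fit, vols), eval_delta_r(gen, vols), tolerance = 1e-4)
})

test_that("high branch is strictly increasing in volume when its slope is positive", {
  m <- default_gk_icon_model()
  v <- seq(1, 44.9, length.out = 200)
  expect_true(all(diff(eval_delta_r(m, v)) > 0))
})

test_that("phantom CSV and model JSON round-trip", {
  meas <- table1_measurements()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_phantom_csv(meas, csv)
  back <- read_phantom_csv(csv)
  expect_equal(back$v_ptv_cc, meas$v_ptv_cc, tolerance = 1e-12)
  expect_equal(back$delta_r_measured_cm, meas$delta_r_measured_cm,
               tolerance = 1e-10)

  js <- withr::local_tempfile(fileext = ".json")
  fit <- fit_delta_r_model(meas)
  write_delta_r_model(fit, js)
  back_m <- read_delta_r_model(js)
  expect_equal(back_m$low_coeffs, fit$low_coeffs, tolerance = 1e-12)
  expect_equal(back_m$high_coeffs, fit$high_coeffs, tolerance = 1e-12)
  v <- c(0.01, 0.8, 1, 7, 40)
  expect_equal(eval_delta_r(back_m, v), eval_delta_r(fit, v), tolerance = 1e-12)
})
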