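printed_model <- calibration_model(-144.5, 1007.5)

test_that("noiseless fits recover the generating coefficients exactly", {
  pts <- generate_calibration_set(calibration_design(c(30, 130, 330)))
  fit <- fit_log_model(pts)
  expect_equal(fit$coeff_a_fF, -144.5, tolerance = 1e-12)
  expect_equal(fit$coeff_b_fF, 1007.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  two <- fit_log_model(tibble::tibble(thickness_um = c(50, 150),
                                      capacitance_fF = c(500, 300)))
  expect_equal(two$r_squared, 1)

  expect_error(fit_log_model(tibble::tibble(thickness_um = c(-1, 10),
                                            capacitance_fF = c(1, 2))),
               class = "irritrace_domain_error")
  expect_error(fit_log_model(tibble::tibble(thickness_um = c(10, 10),
                                            capacitance_fF = c(1, 2))),
               class = "irritrace_rank_deficiency")
})

test_that("noisy fits land within three standard errors of truth", {
  d <- calibration_design(c(20, 50, 100, 170, 250, 330), reps = 2,
                          noise_rms_fF = 10, seed = 12)
  pts <- generate_calibration_set(d)
  fit <- fit_log_model(pts)
  # OLS covariance oracle from an independent lm refit
  ref <- summary(lm(capacitance_fF ~ log(thickness_um), data = pts))$coefficients
  expect_lt(abs(fit$coeff_a_fF - (-144.5)), 3 * ref["log(thickness_um)", "Std. Error"])
  expect_lt(abs(fit$coeff_b_fF - 1007.5), 3 * ref["(Intercept)", "Std. Error"])
})

test_that("prediction evaluates the log model", {
  expect_equal(predict(printed_model, 1), 1007.5)
  expect_equal(predict(printed_model, exp(1)), 1007.5 - 144.5)
  # hand evaluation of -144.5*ln(170) + 1007.5
  expect_equal(predict(printed_model, 170), 265.3771, tolerance = 1e-6)
  expect_error(predict(printed_model, -3), class = "irritrace_domain_error")
})

test_that("prediction is strictly decreasing for a negative log coefficient", {
  xs <- c(10, 30, 100, 170, 330)
  expect_true(all(diff(predict(printed_model, xs)) < 0))
})

test_that("inverse prediction is the exact inverse of prediction", {
  expect_equal(invert_thickness(printed_model, 1007.5), 1)
  for (x in c(30, 170, 330)) {
    expect_equal(invert_thickness(printed_model, predict(printed_model, x)), x,
                 tolerance = 1e-9)
  }
  # hand evaluation of exp((1007.5 - 220)/144.5)
  expect_equal(invert_thickness(printed_model, 220), 232.7179, tolerance = 1e-6)
  expect_error(invert_thickness(calibration_model(0, 5), 1),
               class = "irritrace_non_invertible")
})

test_that("working-point report composes inversion, margin and discrepancy", {
  wp <- working_point_report(printed_model, 220)
  expect_equal(wp$thickness_um, invert_thickness(printed_model, 220))
  expect_equal(wp$margin_fF, 220)

  agree <- working_point_report(printed_model, 220,
                                measured_C_fF = predict(printed_model, 170),
                                at_thickness_um = 170)
  expect_equal(agree$abs_error_fF, 0)

  # measured 220 fF at the 170 um tape vs the model's 265.377 fF
  disc <- working_point_report(printed_model, 220, measured_C_fF = 220,
                               at_thickness_um = 170)
  expect_equal(disc$abs_error_fF, 45.3771, tolerance = 1e-4)
  expect_equal(disc$rel_error_pct, 100 * 45.3771 / 265.3771, tolerance = 1e-4)
})

test_that("tidy and glance expose the fit in broom shape", {
  pts <- generate_calibration_set(calibration_design(c(30, 130, 330)))
  fit <- fit_log_model(pts)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$r.squared, 1, tolerance = 1e-12)
  expect_equal(gl$nobs, 3)
  expect_s3_class(autoplot(fit), "ggplot")
})
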