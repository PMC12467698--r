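test_that("no stimulus and no noise give a constant trace at baseline", {
  prof <- substance_profile("PBS", "control_negative", 0)
  tr <- generate_trace(prof, no_event_protocol(100), quiet_noise())
  expect_equal(diff(range(tr$capacitance_fF)), 0)
})

test_that("generated white noise has the configured RMS", {
  prof <- substance_profile("PBS", "control_negative", 0)
  tr <- generate_trace(prof, no_event_protocol(600),
                       noise_model(white_rms_fF = 1.8, seed = 2024))
  expect_equal(rms_noise(tr, c(0, 600)), 1.8, tolerance = 0.2 / 1.8)
})

test_that("generation is deterministic given the seed", {
  prof <- substance_profile("SDS", "category2", 8)
  prot <- standard_protocol("SDS")
  a <- generate_trace(prof, prot, noise_model(seed = 7))
  b <- generate_trace(prof, prot, noise_model(seed = 7))
  expect_identical(a, b)
  c <- generate_trace(prof, prot, noise_model(seed = 8))
  expect_false(identical(a$capacitance_fF, c$capacitance_fF))
})

test_that("noise is additive: replicate mean converges to the noiseless trajectory", {
  prof <- substance_profile("SDS", "category2", 5)
  prot <- standard_protocol("SDS", duration_s = 600)
  kin <- match_kinetics_to_rate(5)
  prof$kinetics <- kin
  clean <- generate_trace(prof, prot, quiet_noise())
  acc <- 0
  n_rep <- 50
  for (i in seq_len(n_rep)) {
    acc <- acc + generate_trace(prof, prot, noise_model(seed = 100 + i))$capacitance_fF
  }
  resid <- acc / n_rep - clean$capacitance_fF
  expect_lt(sqrt(mean(resid^2)), 2 * 1.8 / sqrt(n_rep))
})

test_that("a tuned trace analysed by the pipeline returns the target rate", {
  prof <- substance_profile("SDS", "category2", 10)
  tr <- generate_trace(prof, standard_protocol("SDS"), quiet_noise())
  got <- rate_windowed(tr, t_apply_s = trace_meta(tr)$t_apply_s)$rate_fF_per_s
  expect_equal(got, 10, tolerance = 0.01)
})

test_that("removal events relax the signal back toward baseline", {
  prof <- substance_profile("SDS", "category2", 10)
  prot <- exposure_protocol(
    tibble::tibble(kind = c("apply", "remove"), substance = "SDS", t_s = c(20, 300)),
    duration_s = 900
  )
  tr <- generate_trace(prof, prot, quiet_noise(), recovery_rate_per_s = 0.02)
  base <- tr$capacitance_fF[1]
  peak <- tr$capacitance_fF[tr$time_s == 300]
  final <- tail(tr$capacitance_fF, 1)
  expect_gt(peak, base + 100)
  expect_lt(final, base + 0.05 * (peak - base))
})

test_that("events outside the trace duration are rejected", {
  expect_error(
    exposure_protocol(tibble::tibble(kind = "apply", substance = "X", t_s = 700),
                      duration_s = 600),
    class = "irritrace_protocol_error"
  )
})

test_that("batch generation partitions traces and injects the stated variability", {
  prof <- substance_profile("SDS", "category2", 10)
  prot <- standard_protocol("SDS", duration_s = 900)

  b0 <- generate_batch(prof, prot, n_devices = 2, n_days = 1, n_reps = 2,
                       baseline_cv_pct = 0, rate_cv_pct = 0,
                       noise = quiet_noise(), seed = 3)
  expect_equal(nrow(b0), 4)
  expect_identical(b0$trace[[1]]$capacitance_fF, b0$trace[[4]]$capacitance_fF)
  expect_equal(nrow(dplyr::distinct(b0[, c("device_id", "day_id", "rep_id")])), 4)

  b <- generate_batch(prof, prot, n_devices = 3, n_days = 1, n_reps = 5,
                      baseline_cv_pct = 0.7, rate_cv_pct = 0, seed = 11)
  baselines <- vapply(b$trace, function(tr) estimate_baseline(tr)$baseline_fF,
                      numeric(1))
  cv <- 100 * sd(baselines) / mean(baselines)
  expect_gt(cv, 0.3)
  expect_lt(cv, 1.2)
})

test_that("calibration sets lie on the log model and round-trip through the fit", {
  d <- calibration_design(c(30, 130, 330), noise_rms_fF = 0)
  pts <- generate_calibration_set(d)
  expect_equal(pts$capacitance_fF, -144.5 * log(pts$thickness_um) + 1007.5)

  one <- generate_calibration_set(calibration_design(1, noise_rms_fF = 0))
  expect_equal(one$capacitance_fF, 1007.5) # ln(1) = 0 leaves the intercept

  fit <- fit_log_model(pts)
  expect_equal(fit$coeff_a_fF, -144.5, tolerance = 1e-12)
  expect_equal(fit$coeff_b_fF, 1007.5, tolerance = 1e-12)

  expect_error(calibration_design(c(0, 30)), class = "irritrace_domain_error")

  noisy1 <- generate_calibration_set(calibration_design(c(30, 130), reps = 3,
                                                        noise_rms_fF = 5, seed = 4))
  noisy2 <- generate_calibration_set(calibration_design(c(30, 130), reps = 3,
                                                        noise_rms_fF = 5, seed = 4))
  expect_identical(noisy1, noisy2)
})
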