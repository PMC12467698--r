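test_that("classification thresholds rates with a strict cutoff", {
  cfg <- classification_config()
  expect_equal(as.character(classify(0.4, cfg)), "no_classification")
  expect_equal(as.character(classify(1.3, cfg)), "no_classification")
  expect_equal(as.character(classify(8, cfg)), "category2")
  expect_equal(as.character(classify(40, cfg)), "category2")
  expect_equal(as.character(classify(3.5, cfg)), "no_classification") # tie
  expect_equal(as.character(classify(-1, cfg)), "no_classification")
  expect_error(classify(NaN, cfg), class = "irritrace_invalid_metric")
})

test_that("classification is monotone in the rate", {
  cfg <- classification_config()
  rates <- sort(runif(50, 0, 10))
  labels <- classify(rates, cfg) == "category2"
  expect_true(all(diff(labels) >= 0))
})

test_that("blank QC passes intact barriers and fails disrupted ones", {
  prot <- standard_protocol("SDS")
  flat <- make_trace(rep(220, 9000))
  qc <- blank_qc(flat, prot)
  expect_true(qc$pass)
  expect_equal(qc$slope_fF_per_s, 0)

  # Category-2-like kinetics active during the blank window
  prof <- substance_profile("SDS", "category2", 8)
  early <- exposure_protocol(
    tibble::tibble(kind = "apply", substance = "SDS", t_s = 30),
    duration_s = 900
  )
  bad <- generate_trace(prof, early, quiet_noise())
  expect_false(blank_qc(bad, prot)$pass)

  # slope exactly at the cutoff fails (strict inequality)
  t <- seq(0, by = 0.1, length.out = 9000)
  at_cut <- make_trace(220 + 3.5 * t)
  expect_false(blank_qc(at_cut, prot)$pass)

  no_blank <- exposure_protocol(
    tibble::tibble(kind = "apply", substance = "SDS", t_s = 30),
    duration_s = 900
  )
  expect_error(blank_qc(flat, no_blank), class = "irritrace_protocol_error")
})

test_that("group comparisons apply Welch t-tests with Bonferroni control", {
  cfg <- classification_config()
  set.seed(5)
  rates <- tibble::tibble(
    substance = rep(c("PBS", "same", "hot"), each = 3),
    rate_fF_per_s = c(0.4, 0.41, 0.39,
                      0.4, 0.41, 0.39,
                      8, 9, 10)
  )
  cmp <- compare_to_control(rates, cfg)
  expect_equal(nrow(cmp), 2)
  hot <- cmp[cmp$substance == "hot", ]
  expect_true(hot$significant)
  expect_lt(hot$p_adjusted, 0.01)
  same <- cmp[cmp$substance == "same", ]
  expect_false(same$significant)
  # bonferroni flag identical to raw p < alpha/m
  expect_equal(cmp$significant, cmp$p_value < cfg$alpha / 2)
  # adjusted p capped at 1
  expect_true(all(cmp$p_adjusted <= 1))

  ident <- tibble::tibble(substance = rep(c("PBS", "x"), each = 3),
                          rate_fF_per_s = rep(c(1, 2, 3), 2))
  cmp2 <- compare_to_control(ident, cfg)
  expect_equal(cmp2$t_statistic, 0)
  expect_false(cmp2$significant)

  weak <- tibble::tibble(substance = rep(c("PBS", "y"), each = 3),
                         rate_fF_per_s = c(1, 2, 3, 1.1, 2.1, 3.3))
  expect_true(all(compare_to_control(weak, classification_config(n_comparisons = 50))$p_adjusted <= 1))

  few <- tibble::tibble(substance = c("PBS", "PBS", "z"),
                        rate_fF_per_s = c(1, 2, 3))
  expect_error(compare_to_control(few, cfg),
               class = "irritrace_insufficient_replicates")
})

test_that("coefficient of variation follows its definition", {
  expect_equal(cv_percent(c(9, 10, 11)), 10)
  expect_equal(cv_percent(rep(4, 5)), 0)
  expect_error(cv_percent(3), class = "irritrace_insufficient_replicates")
  expect_error(cv_percent(c(-1, 1)), class = "irritrace_undefined_cv")
})

test_that("reproducibility CVs reflect injected inter-device variability", {
  prof <- substance_profile("SDS", "category2", 10)
  prot <- standard_protocol("SDS")
  b <- generate_batch(prof, prot, n_devices = 3, n_days = 1, n_reps = 5,
                      baseline_cv_pct = 0, rate_cv_pct = 0,
                      rate_cv_device_pct = 3, seed = 19)
  met <- analyze_batch(b, protocol = prot)
  met$rate_fF_per_s <- met$rate_window_fF_per_s
  rep_tbl <- reproducibility(met[, c("substance", "device_id", "day_id", "rate_fF_per_s")])
  expect_gt(rep_tbl$cv_inter_device_pct, 1.5)
  expect_lt(rep_tbl$cv_inter_device_pct, 5)
  # no replicate-level variability injected: intra-day CV sits at the noise floor
  expect_lt(rep_tbl$cv_intra_day_pct, 0.5)

  expect_error(reproducibility(met[0, c("substance", "device_id", "day_id", "rate_fF_per_s")]),
               class = "irritrace_insufficient_replicates")
})
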