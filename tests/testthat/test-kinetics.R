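test_that("frozen kinetics give a constant trace at the pre-exposure level", {
  st <- circuit_state(C_s_fF = 1000, C_a_fF = 200)
  kin <- disruption_kinetics(0, 0, C_a_prime_final_fF = 5000, t_apply_s = 10)
  tr <- disruption_trajectory(st, kin, seq(0, 60, by = 0.1))
  expect_equal(diff(range(tr$capacitance_fF)), 0)
  expect_equal(tr$capacitance_fF[1],
               series_oracle(1000, 200 + 1e6 / (2 * pi * 1000 * 1e4)),
               tolerance = 1e-12)
})

test_that("the trajectory approaches the asymptotic electrolyte state", {
  st <- circuit_state(C_s_fF = 1e4, C_a_fF = 200)
  kin <- disruption_kinetics(0.05, 0.05, C_a_prime_final_fF = 3000,
                             R_leak_final_Gohm = 10, t_apply_s = 0)
  tr <- disruption_trajectory(st, kin, seq(0, 400, by = 0.1))
  target <- series_oracle(1e4, 3000 + 1e6 / (2 * pi * 1000 * 10))
  expect_equal(tail(tr$capacitance_fF, 1), target, tolerance = 1e-6)
  # monotone non-decreasing after onset when asymptotes exceed initial values
  expect_true(all(diff(tr$capacitance_fF) >= -1e-12))
})

test_that("early-time slope matches the analytic derivative of the relaxation", {
  st <- circuit_state(C_s_fF = 2e5, C_a_fF = 220)
  k <- 0.002
  A <- 5000
  kin <- disruption_kinetics(k, 0, C_a_prime_final_fF = A, t_apply_s = 0)
  dt <- 0.1
  tr <- disruption_trajectory(st, kin, seq(0, 1, by = dt))
  fd <- (tr$capacitance_fF[2] - tr$capacitance_fF[1]) / dt
  # analytic: dC/dt = h'(C_eff) * dC_contact/dt at the midpoint t = dt/2
  leak <- 1e6 / (2 * pi * 1000 * st$R_leak_Gohm)
  C_c <- A + (st$C_a_prime_fF - A) * exp(-k * dt / 2)
  C_eff <- C_c + leak
  h <- series_oracle(st$C_s_fF, C_eff)
  dh <- (h / C_eff)^2
  analytic <- dh * k * (A - st$C_a_prime_fF) * exp(-k * dt / 2)
  expect_equal(fd, analytic, tolerance = 0.01)
})

test_that("invalid time grids are rejected", {
  st <- circuit_state(1000, 200)
  kin <- disruption_kinetics()
  expect_error(disruption_trajectory(st, kin, c(0, 1, 1.5)),
               class = "irritrace_invalid_grid")
  expect_error(disruption_trajectory(st, kin, c(0, -1, -2)),
               class = "irritrace_invalid_grid")
})

test_that("rate matching reproduces target windowed slopes on noiseless traces", {
  st <- default_circuit_state()
  win <- c(60, 450)
  t_grid <- seq(0, 460, by = 0.1)
  for (target in c(0.4, 8)) {
    kin <- match_kinetics_to_rate(target, window = win, state0 = st)
    tr <- disruption_trajectory(st, kin, t_grid)
    got <- rate_windowed(tr, analysis_windows(analysis_window_s = win), 0)$rate_fF_per_s
    expect_equal(got, target, tolerance = 0.01)
  }
  z <- match_kinetics_to_rate(0, state0 = st)
  expect_equal(z$rate_perm_per_s, 0)
  expect_equal(z$C_a_prime_final_fF, st$C_a_prime_fF)
})

test_that("larger targets produce larger early-window slopes", {
  st <- default_circuit_state()
  t_grid <- seq(0, 460, by = 0.1)
  slopes <- vapply(c(0.5, 2, 10, 30), function(target) {
    kin <- match_kinetics_to_rate(target, state0 = st)
    tr <- disruption_trajectory(st, kin, t_grid)
    rate_windowed(tr, t_apply_s = 0)$rate_fF_per_s
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("targets beyond the stack ceiling raise an infeasible-target error", {
  tiny <- circuit_state(C_s_fF = 100, C_a_fF = 20)
  expect_error(match_kinetics_to_rate(40, state0 = tiny),
               class = "irritrace_infeasible_target")
})
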