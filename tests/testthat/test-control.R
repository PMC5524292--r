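test_that("baroreflex is at equilibrium on the set-point", {
  bp <- baroreflex_params(Pset = 88)
  st <- control_state(88)
  for (i in 1:2000) st <- baroreflex_update(88, bp, st, dt = 0.05)
  eff <- baroreflex_effectors(st, bp)
  expect_equal(eff$hr, 1, tolerance = 1e-6)
  expect_equal(eff$es, 1, tolerance = 1e-6)
  expect_equal(eff$r_art, 1, tolerance = 1e-6)
  expect_equal(eff$vu, 1, tolerance = 1e-6)
})

test_that("hypotension raises heart rate, contractility and resistance", {
  bp <- baroreflex_params(Pset = 88)
  st <- control_state(88)
  for (i in 1:2000) st <- baroreflex_update(68, bp, st, dt = 0.05)
  eff <- baroreflex_effectors(st, bp)
  expect_gt(eff$hr, 1)
  expect_gt(eff$es, 1)
  expect_gt(eff$r_art, 1)
  expect_lt(eff$vu, 1) # venous tone mobilises unstressed volume
  # symmetric opposite for hypertension
  st2 <- control_state(88)
  for (i in 1:2000) st2 <- baroreflex_update(108, bp, st2, dt = 0.05)
  eff2 <- baroreflex_effectors(st2, bp)
  expect_lt(eff2$hr, 1)
  expect_gt(eff2$vu, 1)
})

test_that("effector states follow first-order dynamics", {
  bp <- baroreflex_params(Pset = 88, tau_p = 0.05, tau_hr = 3)
  st <- control_state(88)
  # pressure step 88 -> 78: with a fast filter the HR effector relaxes to
  # tanh(10/kb) with time constant tau_hr
  target <- tanh(10 / bp$kb)
  dt <- 0.001
  n <- round(bp$tau_hr / dt)
  for (i in seq_len(n)) st <- baroreflex_update(78, bp, st, dt = dt)
  expect_equal(st$x_hr, target * (1 - exp(-1)), tolerance = 0.03)
})

test_that("exercise resets the set-point linearly in oxygen uptake", {
  bp <- baroreflex_params(Pset = 88, resetting_gain = 1.6)
  expect_equal(baroreflex_reset(3.45, 3.45, bp), 88)
  vo2 <- seq(3.45, 11.5, length.out = 7)
  ps <- baroreflex_reset(vo2, 3.45, bp)
  expect_true(all(diff(ps) > 0))
  expect_equal(diff(ps), rep(1.6 * diff(vo2)[1], 6), tolerance = 1e-12)
  expect_error(baroreflex_reset(2, 3.45, bp), ">= VO2_rest")
})

test_that("heart-rate command is anchored at rest and capped by imbalance", {
  bp <- baroreflex_params(Pset = 88, hr_max = 112)
  st <- control_state(88)
  expect_equal(heart_rate_command(st, bp, HR_rest = 81), 81)
  # saturated sympathetic drive hits the imbalance ceiling, not 220 - age
  st$x_hr <- 1
  expect_equal(heart_rate_command(st, bp, 81), 112)
  # monotone in the drive
  hrs <- vapply(seq(0, 1, 0.1), function(x) {
    st$x_hr <- x; heart_rate_command(st, bp, 81)
  }, numeric(1))
  expect_true(all(diff(hrs) >= 0))
})

test_that("metabolic vasodilation is anchored, monotone and floored", {
  mp <- metabolic_params(ref = 10, floor = 0.2)
  expect_equal(metabolic_vasodilation_static(10, mp), 1)
  expect_equal(metabolic_vasodilation_static(14, mp), 1)
  expect_lt(metabolic_vasodilation_static(4, mp), 1)
  grid <- metabolic_vasodilation_static(seq(12, 0, by = -0.5), mp)
  expect_true(all(diff(grid) <= 0))
  expect_gte(min(grid), 0.2)
  # first-order relaxation toward the static value
  m <- 1
  for (i in 1:5000) m <- metabolic_vasodilation(m, 4, mp, dt = 0.05)
  expect_equal(m, metabolic_vasodilation_static(4, mp), tolerance = 1e-4)
})

test_that("vasodilation in the simulated exercise loop is local to the legs", {
  pr <- cached_protocol("hf")
  ex <- pr$results$exercise$final_state
  expect_lt(ex[["m_ll"]], 0.5)  # exercising legs dilate strongly
  expect_lt(ex[["m_rl"]], 0.5)
  expect_gt(ex[["m_kid"]], 0.9) # kidney bed does not
})
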