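test_that("pump head is quadratic in speed and decreasing in flow", {
  vp <- vad_params(k_w = 1.52e-6, k_q1 = 0.78, k_q2 = 0.003)
  expect_equal(vad_pressure_head(0, 9500, vp), 1.52e-6 * 9500^2)
  q <- seq(-50, 200, by = 5)
  expect_true(all(diff(vad_pressure_head(q, 9500, vp)) < 0))
  # shutoff head grows with speed
  h0 <- vapply(seq(6000, 12000, 500), function(w)
    vad_pressure_head(0, w, vp), numeric(1))
  expect_true(all(diff(h0) > 0))
  expect_error(vad_pressure_head(0, 14000, vp), "speed")
  expect_error(vad_params(-1, 1, 1), ">= 0")
})

test_that("zero-head flow matches the quadratic-root oracle", {
  vp <- vad_params(k_w = 1.52e-6, k_q1 = 0.78, k_q2 = 0.003)
  for (w in c(8000, 9500, 12000)) {
    # oracle: positive root of k_q2 q^2 + k_q1 q - k_w w^2 = 0
    q_oracle <- (-vp$k_q1 + sqrt(vp$k_q1^2 + 4 * vp$k_q2 * vp$k_w * w^2)) /
      (2 * vp$k_q2)
    q_num <- stats::uniroot(function(q) vad_pressure_head(q, w, vp),
                            c(0, 1000), tol = 1e-10)$root
    expect_equal(q_num, q_oracle, tolerance = 1e-7)
  }
})

test_that("pump flow dynamics: equilibrium, backflow, relaxation", {
  vp <- vad_params(k_w = 1.52e-6, k_q1 = 0.78, k_q2 = 0.003,
                   Rc = 0.035, Lc = 0.005)
  # equilibrium: Pao - Plv = H(Q*) - Rc Q* gives dQ/dt = 0
  w <- 9500; Q <- 70
  H <- vad_pressure_head(Q, w, vp)
  Pao <- 10 + H - vp$Rc * Q
  expect_equal(vad_flow_derivative(10, Pao, Q, w, vp), 0, tolerance = 1e-9)
  # unpowered pump with adverse gradient tends to regurgitate
  expect_lt(vad_flow_derivative(10, 80, 0, omega = 0, vp), 0)
  # speed step relaxes with the linearised time constant Lc / R_eff
  Plv <- 15; Pao2 <- 90
  q <- 0
  dt <- 1e-5
  qs <- numeric(0)
  for (i in seq_len(round(0.05 / dt))) {
    q <- q + dt * vad_flow_derivative(Plv, Pao2, q, 9500, vp)
    qs <- c(qs, q)
  }
  qstar <- qs[length(qs)]
  reff <- vp$k_q1 + 2 * vp$k_q2 * abs(qstar) + vp$Rc
  tau <- vp$Lc / reff
  # flow at t = tau is within a few percent of the 63 % analytic mark
  q_tau <- qs[round(tau / dt)]
  expect_equal(q_tau / qstar, 1 - exp(-1), tolerance = 0.1)
})

test_that("coefficient calibration recovers known pumps from anchors", {
  truth <- vad_params(k_w = 1.4e-6, k_q1 = 0.7, k_q2 = 0.004)
  mk <- function(om, q) data.frame(omega = om, Q = q,
                                   H = vad_pressure_head(q, om, truth))
  # three anchors: exact recovery of all three coefficients
  fit <- calibrate_vad(mk(c(9500, 9500, 12000), c(60, 90, 130)))
  expect_equal(fit$k_w, truth$k_w, tolerance = 1e-9)
  expect_equal(fit$k_q1, truth$k_q1, tolerance = 1e-7)
  expect_equal(fit$k_q2, truth$k_q2, tolerance = 1e-7)
  # overdetermined consistent set: still exact
  fit2 <- calibrate_vad(mk(c(8000, 9000, 10000, 11000), c(50, 70, 90, 110)))
  expect_equal(fit2$k_q1, truth$k_q1, tolerance = 1e-7)
  # two anchors: linear H-Q model, reproduces both anchors exactly
  two <- mk(c(9500, 12000), c(70, 130))
  lin <- vad_params(k_w = 1.4e-6, k_q1 = 0.7, k_q2 = 0)
  two$H <- vad_pressure_head(two$Q, two$omega, lin)
  fit3 <- calibrate_vad(two)
  expect_equal(fit3$k_q2, 0)
  expect_equal(vad_pressure_head(two$Q, two$omega, fit3), two$H,
               tolerance = 1e-9)
  # degenerate sets error out
  expect_error(calibrate_vad(mk(9500, 70)), "two anchors")
  expect_error(calibrate_vad(mk(c(9500, 9500), c(70, 80))), "two anchors")
})
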