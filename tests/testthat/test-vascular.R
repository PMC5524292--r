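test_that("vessel pressure is linear in range and stiffens outside it", {
  expect_equal(vessel_pressure(500, C = 25, Vu = 500), 0)
  expect_equal(vessel_pressure(550, C = 25, Vu = 500), 2)
  expect_equal(vessel_pressure(550, C = 25, Vu = 500, P_ext = 5), 7)
  # collapsible vein: local slope exceeds 1/C when nearly empty
  C <- 25; Vu <- 500; k3 <- 4; Vn <- C * 18
  slope <- function(V) {
    (vessel_pressure(V + 0.5, C, Vu, 0, k3, Vn) -
       vessel_pressure(V - 0.5, C, Vu, 0, k3, Vn))
  }
  expect_gt(slope(Vu - 1.5 * Vn), 1 / C)
  expect_gt(slope(Vu + 1.5 * Vn), 1 / C)       # and when overdistended
  expect_equal(slope(Vu), 1 / C, tolerance = 1e-4) # linear near Vu
})

test_that("pulmonary arterial compliance falls with wedge congestion", {
  base <- 3.2
  expect_equal(pulmonary_arterial_compliance(14, base), base)
  expect_lt(pulmonary_arterial_compliance(28, base), base)
  grid <- pulmonary_arterial_compliance(seq(0, 45, by = 1), base)
  expect_true(all(diff(grid) <= 0))
  expect_gte(min(grid), 0.5 * base) # floor
  expect_error(pulmonary_arterial_compliance(-1, base), ">= 0")
})

test_that("muscle pump is periodic, non-negative and antiphase across legs", {
  t <- seq(0, 4, by = 0.001)
  expect_true(all(muscle_pump_pressure(t, 1, 30, active = FALSE) == 0))
  pl <- muscle_pump_pressure(t, cadence = 1, amplitude = 30, leg = "left")
  pr <- muscle_pump_pressure(t, cadence = 1, amplitude = 30, leg = "right")
  expect_true(all(pl >= 0))
  expect_gt(mean(pl), 0)
  # period 1/cadence
  expect_equal(pl[t >= 1], pl[t < 3 + 1e-9], tolerance = 1e-9)
  # left(t) = right(t + half period)
  half <- which(t >= 0.5)[1] - 1
  expect_equal(pl[seq_len(length(t) - half)], pr[(half + 1):length(t)],
               tolerance = 1e-9)
})

test_that("starling resistor implements the vascular waterfall", {
  expect_equal(starling_resistor_flow(20, 5, 0, R = 0.5), 30)   # ordinary
  expect_equal(starling_resistor_flow(20, 5, 12, R = 0.5), 16)  # waterfall
  expect_equal(starling_resistor_flow(20, 5, 25, R = 0.5), 0)   # collapsed
  expect_error(starling_resistor_flow(1, 0, 0, R = 0), "positive")
})

test_that("resistance estimation reproduces mean-hemodynamics arithmetic", {
  r <- estimate_resistances(Pas = 89, Pcv = 8, Pap = 26, Pwedge = 14,
                            CO = 3.7)
  expect_equal(r$Ras, (89 - 8) / (3.7 * 1000 / 60))
  expect_equal(r$Ras, 1.3135, tolerance = 1e-4)
  expect_equal(r$Rap, (26 - 14) / (3.7 * 1000 / 60))
  expect_equal(r$Rap, 0.1946, tolerance = 1e-3)
  # both resistances vanish as CO grows without bound
  expect_lt(estimate_resistances(89, 8, 26, 14, 1e6)$Ras, 1e-4)
  expect_error(estimate_resistances(8, 9, 26, 14, 3.7), "Pas")
  expect_error(estimate_resistances(89, 8, 13, 14, 3.7), "Pap")
  expect_error(estimate_resistances(89, 8, 26, 14, 0), "positive")
})

test_that("splitting a systemic resistance preserves the parallel sum", {
  parallel_sum <- function(r) 1 / sum(1 / r) # brute-force oracle
  # default split reproduces the published heart-failure regional beds
  reg <- split_systemic_resistance(parallel_sum(c(5.2, 5.4, 4.0, 9.4, 9.4)))
  expect_equal(unname(reg), c(5.2, 5.4, 4.0, 9.4, 9.4), tolerance = 1e-9)
  # identity for a single region
  expect_equal(unname(split_systemic_resistance(2, c(x = 1))), 2)
  # random conductance splits recombine exactly
  set.seed(42)
  for (i in 1:20) {
    fr <- stats::runif(4); fr <- fr / sum(fr)
    reg <- split_systemic_resistance(1.31, fr)
    expect_equal(parallel_sum(reg), 1.31, tolerance = 1e-9)
  }
  expect_error(split_systemic_resistance(1, c(0.5, 0.4)), "sum to 1")
})

test_that("an isolated Windkessel compartment decays exponentially", {
  skip_if_not_installed("deSolve")
  # dV/dt = -(P - P_out)/R with P = (V - Vu)/C: analytic exp(-t/(RC)) decay
  C <- 10; Vu <- 100; R <- 0.8; V0 <- 180
  rhs <- function(t, y, parms) {
    list(-(vessel_pressure(y[1], C, Vu) - 0) / R)
  }
  tc <- R * C
  times <- seq(0, 5 * tc, length.out = 200)
  num <- deSolve::lsoda(c(V = V0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  ana <- Vu + (V0 - Vu) * exp(-times / tc)
  expect_lt(max(abs(num[, "V"] - ana) / (V0 - Vu)), 1e-3)
  # after 5 time constants the remaining stressed volume is < 0.1 % off
  expect_lt(abs(num[nrow(num), "V"] - ana[length(ana)]) / (V0 - Vu), 1e-3)
})
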