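test_that("oxygen content follows a saturating Hill dissociation curve", {
  expect_lt(o2_content(0, Hb = 14.5), 1e-9)
  expect_equal(o2_content(1e6, Hb = 14.5) - 0.003 * 1e6, 1.34 * 14.5,
               tolerance = 1e-3)
  # half saturation at P50 by definition
  expect_equal(o2_content(26.6, 14.5) - 0.003 * 26.6, 1.34 * 14.5 / 2,
               tolerance = 1e-9)
  expect_true(all(diff(o2_content(seq(0, 150, 5), 14.5)) > 0))
})

test_that("CO2 content law inverts exactly", {
  p <- seq(20, 70, by = 5)
  expect_equal(co2_partial_pressure(co2_content(p)), p)
})

test_that("ventilation command is anchored at rest and driven by CO2", {
  vp <- ventilation_params()
  expect_equal(ventilation_control(100, 35, vco2 = 207, vp), 9.2)
  # strictly increasing in PaCO2 and in metabolic CO2 production
  ve <- vapply(seq(30, 60, 2), function(pc)
    ventilation_control(100, pc, 207, vp), numeric(1))
  expect_true(all(diff(ve) > 0))
  ve2 <- vapply(seq(207, 1400, 100), function(v)
    ventilation_control(100, 35, v, vp), numeric(1))
  expect_true(all(diff(ve2) > 0))
  # hypoxia below threshold adds drive
  expect_gt(ventilation_control(50, 35, 207, vp),
            ventilation_control(100, 35, 207, vp))
})

test_that("breathing pattern partitions ventilation monotonically", {
  vp <- ventilation_params()
  pat <- lapply(c(9.2, 20, 33, 44), function(v) ventilation_pattern(v, vp))
  f <- vapply(pat, `[[`, numeric(1), "f")
  vt <- vapply(pat, `[[`, numeric(1), "Vt")
  va <- vapply(pat, `[[`, numeric(1), "VA")
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(vt) > 0))
  expect_true(all(diff(va) > 0))
  expect_equal(f * vt, c(9.2, 20, 33, 44)) # Ve = f * Vt
})

test_that("respiratory mechanics: apnea, periodicity and elastic recoil", {
  t <- seq(0, 10, by = 0.005)
  ap <- respiratory_mechanics(t, Vt = 0, f = 12)
  expect_true(all(ap$flow == 0))
  expect_equal(diff(range(ap$Ppl)), 0)
  br <- respiratory_mechanics(t, Vt = 0.77, f = 12)
  # closed breath: mean flow integrates to zero lung volume change
  expect_equal(mean(br$flow[t < 5]), 0, tolerance = 1e-3)
  expect_lt(mean(br$Ppl), 0) # pleural pressure stays sub-atmospheric on average
  # alveolar-pleural difference is the elastic recoil Elungs * Vlung
  expect_equal(br$Palv - br$Ppl, 3.5 * br$Vlung, tolerance = 1e-12)
  # flow equals the derivative of lung volume (finite-difference check)
  fd <- diff(br$Vlung) / diff(t)
  expect_lt(max(abs(fd - br$flow[-1])), 0.05)
})

test_that("lung exchange equilibrates blood toward alveolar tensions", {
  # venous blood already at alveolar tensions: no net exchange
  st <- lung_gas_exchange(PAO2 = 100, PACO2 = 40, flow = 80,
                          CvO2 = o2_content(100, 14.5),
                          CvCO2 = co2_content(40), VA = 5, dt = 0.01)
  expect_equal(st$VO2, 0, tolerance = 1e-9)
  expect_equal(st$VCO2, 0, tolerance = 1e-9)
  # venous blood below alveolar O2 takes up oxygen
  st2 <- lung_gas_exchange(100, 40, 80, CvO2 = 13, CvCO2 = co2_content(46),
                           VA = 5, dt = 0.01)
  expect_gt(st2$VO2, 0)
  expect_gt(st2$VCO2, 0)
  expect_error(lung_gas_exchange(100, 40, -1, 13, 50, 5, 0.01), ">= 0")
})

test_that("tissue exchange satisfies the Fick principle at steady state", {
  # no consumption: venous O2 relaxes to the arterial level
  cv <- list(CvO2 = 12, CvCO2 = 50)
  for (i in 1:20000) {
    cv <- tissue_gas_exchange(cv$CvO2, cv$CvCO2, flow = 10, CaO2 = 19.5,
                              CaCO2 = 47, VO2 = 0, RQ = 0.8, dt = 0.05)
  }
  expect_equal(cv$CvO2, 19.5, tolerance = 1e-3)
  expect_equal(cv$CvCO2, 47, tolerance = 1e-3)
  # delivery = 2 x demand -> 50 % extraction (CaO2 20 -> CvO2 10)
  flow <- 20; CaO2 <- 20
  vo2 <- 0.5 * flow * 0.6 * CaO2 # ml/min, half the delivery
  cv <- list(CvO2 = 15, CvCO2 = 48)
  for (i in 1:20000) {
    cv <- tissue_gas_exchange(cv$CvO2, cv$CvCO2, flow, CaO2, 47, vo2,
                              RQ = 0.8, dt = 0.05)
  }
  expect_equal(cv$CvO2, 10, tolerance = 1e-3)
  # supply limitation floors venous O2 at zero with a warning
  expect_warning(
    tissue_gas_exchange(0.01, 50, flow = 1, CaO2 = 5, CaCO2 = 47,
                        VO2 = 500, RQ = 0.8, dt = 1),
    "supply-limited")
})

test_that("whole-body Fick arithmetic matches the resting simulation", {
  # CO 3.7 l/min with a 7.0 ml/dl a-v difference transports ~259 ml O2/min
  expect_equal(3.7 * 10 * 7.0, 259)
  sm <- cached_protocol("hf")$summaries$rest
  expect_equal(sm$VO2, sm$CO * 10 * sm$avO2, tolerance = 0.02)
})
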