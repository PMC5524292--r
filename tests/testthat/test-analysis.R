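test_that("ejection fraction arithmetic and guards", {
  expect_equal(ejection_fraction(320, 275), 100 * 45 / 320)
  expect_equal(ejection_fraction(320, 275), 14.0625)
  expect_equal(ejection_fraction(355, 297), 16.338, tolerance = 1e-4)
  expect_equal(ejection_fraction(100, 0), 100)
  expect_error(ejection_fraction(100, 100), "VED > VES")
  expect_error(ejection_fraction(100, -5), "VED > VES")
})

test_that("exponential stiffness fit is exact on noise-free data", {
  for (cf in list(c(a = 0.01, b = 0.044), c(a = 0.0532, b = 0.0194))) {
    V <- seq(120, 260, by = 20)
    P <- cf[["a"]] * exp(cf[["b"]] * V)
    fit <- fit_diastolic_stiffness(V, P)
    expect_equal(fit$a, cf[["a"]], tolerance = 1e-10)
    expect_equal(fit$b, cf[["b"]], tolerance = 1e-10)
    expect_length(fit$excluded, 0)
  }
  expect_error(fit_diastolic_stiffness(1:3, c(1, 2, 3)), "at least 4")
  expect_error(fit_diastolic_stiffness(1:4, c(1, 2, -1, 3)), "positive")
})

test_that("planted stiffness outliers are excluded exactly and refit", {
  V <- seq(110, 275, by = 15) # 12 points
  P <- 0.01 * exp(0.044 * V)
  out_idx <- c(3, 7, 11)
  P[out_idx] <- P[out_idx] * 6 # much stiffer ventricles
  fit <- fit_diastolic_stiffness(V, P)
  expect_setequal(fit$excluded, out_idx)
  expect_equal(fit$a, 0.01, tolerance = 1e-9)
  expect_equal(fit$b, 0.044, tolerance = 1e-9)
  # threshold Inf disables exclusion
  fit2 <- fit_diastolic_stiffness(V, P, exclude_threshold = Inf)
  expect_length(fit2$excluded, 0)
})

test_that("stiffness linearisation matches numeric differentiation", {
  a <- 0.01; b <- 0.044
  for (vw in c(140, 160, 182)) {
    fd <- (a * exp(b * (vw + 1e-4)) - a * exp(b * (vw - 1e-4))) / 2e-4
    expect_equal(linearize_stiffness(a, b, vw), fd, tolerance = 1e-6)
    # algebraic identity: slope = b * P(V_work)
    expect_equal(linearize_stiffness(a, b, vw), b * a * exp(b * vw))
  }
  expect_equal(linearize_stiffness(0.5, 0, 100), 0)
})

test_that("summaries recover known means from synthetic series", {
  res <- synthetic_result(channels = list(
    Paa = 90, Pla = 14, Pra = 8, Ppa = 25, Qav = 60, Qrap = 60,
    Ve = 9.2, avO2 = 7, Vlv = function(t) 270 + 50 * abs(sin(pi * t))))
  sm <- cvr_summarize(res, n_cycles = 15)
  expect_equal(sm$Pas, 90)
  expect_equal(sm$Pwedge, 14)
  expect_equal(sm$CO, 60 * 0.06)
  expect_equal(sm$HR, 60)
  expect_equal(sm$VED, 320, tolerance = 1e-3)
  expect_equal(sm$VES, 270, tolerance = 1e-3)
  expect_equal(sm$EF, 100 * 50 / 320, tolerance = 1e-3)
  # a sinusoid with known mean is recovered by cycle averaging
  res2 <- synthetic_result(channels = list(
    Paa = function(t) 90 + 12 * sin(2 * pi * t)))
  expect_equal(cvr_summarize(res2, 15)$Pas, 90, tolerance = 1e-6)
  expect_error(cvr_summarize(res2, 50), "complete cycles")
})

test_that("PV loop extraction measures a synthetic rectangular loop", {
  # rectangle: fill at P=10 (V 100->160), pressurise to 110, eject back
  cyc <- function(t) {
    ph <- t %% 1
    V <- ifelse(ph < 0.25, 100 + 240 * ph,
         ifelse(ph < 0.5, 160,
         ifelse(ph < 0.75, 160 - 240 * (ph - 0.5), 100)))
    V
  }
  pres <- function(t) {
    ph <- t %% 1
    ifelse(ph < 0.25, 10, ifelse(ph < 0.5, 110, ifelse(ph < 0.75, 110, 10)))
  }
  res <- synthetic_result(channels = list(Vlv = cyc, Plv = pres))
  loops <- extract_pv_loops(res, "lv", n = 3)
  expect_length(loops, 3)
  lp <- loops[[3]]
  expect_equal(lp$SV, 60, tolerance = 1e-6)
  expect_equal(lp$VED, 160)
  expect_equal(lp$VES, 100)
  expect_equal(lp$P_peak, 110)
  # closed curve
  expect_equal(lp$V[1], lp$V[length(lp$V)])
  expect_error(extract_pv_loops(res, "lv", n = 100), "fewer complete cycles")
})
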