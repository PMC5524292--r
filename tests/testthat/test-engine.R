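test_that("compiled and reference derivatives agree at random states", {
  set.seed(7)
  for (cond in c("hf", "hf_vad")) {
    p <- scenario_params(cond)
    s0 <- initial_state(p)
    for (k in 1:10) {
      s <- s0 * exp(stats::rnorm(length(s0), 0, 0.05))
      s["theta"] <- stats::runif(1)
      s["xhr"] <- stats::runif(1, -0.8, 0.8)
      s["xsym"] <- stats::runif(1, -0.8, 0.8)
      s["Qvad"] <- stats::runif(1, -20, 150)
      tt <- stats::runif(1, 0, 100)
      r <- network_derivatives(s, p, t = tt)
      e <- cvrsim:::engine_rhs(tt, unname(s[cvr_state_names()]), p)
      expect_equal(unname(r$deriv), as.numeric(e$deriv), tolerance = 1e-12)
      expect_equal(unname(r$derived), as.numeric(e$derived),
                   tolerance = 1e-12)
    }
  }
})

test_that("volume derivatives are conservative at any state", {
  set.seed(11)
  p <- scenario_params("hf_vad")
  s0 <- initial_state(p)
  vols <- 1:14 # chamber + compartment volumes in the state layout
  for (k in 1:10) {
    s <- s0 * exp(stats::rnorm(length(s0), 0, 0.1))
    d <- network_derivatives(s, p, t = k)$deriv
    expect_equal(sum(d[vols]), 0, tolerance = 1e-10)
  }
})

test_that("engine trajectory matches a deSolve integration of the reference",
{
  skip_if_not_installed("deSolve")
  cfg <- scenario_config("hf")
  s0 <- initial_state(cfg$params)
  horizon <- 0.5 # within the first cardiac cycle (no discrete HR resampling)
  res <- cvr_simulate(cfg, duration = horizon, dt = 2.5e-4, dt_out = 0.05)
  f <- function(t, y, parms) {
    names(y) <- cvr_state_names()
    list(unname(network_derivatives(y, parms, t)$deriv))
  }
  ref <- deSolve::lsoda(unname(s0), seq(0, horizon, by = 0.05), f,
                        cfg$params, rtol = 1e-9, atol = 1e-9)
  eng <- res$timeseries[, 1 + seq_along(s0)]
  for (j in c(1:14, 16)) { # volumes and pump flow
    denom <- max(abs(ref[, 1 + j]), 1)
    expect_lt(max(abs(eng[, j] - ref[, 1 + j])) / denom, 1e-4)
  }
})

test_that("repeated runs are bit-identical (the model has no randomness)", {
  cfg <- scenario_config("hf_vad")
  r1 <- cvr_simulate(cfg, duration = 3)
  r2 <- cvr_simulate(cfg, duration = 3)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(r1$final_state, r2$final_state)
})

test_that("total blood volume is conserved over a minute of simulation", {
  res <- cached_rest_run(60)
  ts <- res$timeseries
  vols <- ts[, 1 + 1:14]
  total <- rowSums(vols)
  expect_lt(max(abs(total - total[1])), 0.1) # cm^3 drift
})

test_that("halving the integration step leaves the summary unchanged", {
  cfg <- scenario_config("hf")
  s0 <- initial_state(cfg$params)
  r1 <- cvr_simulate(cfg, duration = 25, state = s0, dt = 2.5e-4)
  r2 <- cvr_simulate(cfg, duration = 25, state = s0, dt = 1.25e-4)
  sm1 <- cvr_summarize(r1, 15)
  sm2 <- cvr_summarize(r2, 15)
  expect_equal(sm1$CO, sm2$CO, tolerance = 0.005)
  expect_equal(sm1$Pas, sm2$Pas, tolerance = 0.005)
  expect_equal(sm1$Pwedge, sm2$Pwedge, tolerance = 0.005)
})

test_that("steady state is reached and flagged; pathological configs error", {
  cfg <- scenario_config("hf")
  phase <- list(name = "rest", vo2 = 3.45, rq = 0.8, omega = NA_real_,
                ramp = 0, max_dur = 300)
  st <- run_to_steady_state(cfg, phase)
  expect_s3_class(st$summary, "cvr_summary")
  # an impossible convergence demand times out with trend diagnostics
  tight <- phase; tight$max_dur <- 15
  expect_error(
    run_to_steady_state(cfg, tight, tol = 1e-9, min_settle = 5),
    "did not reach steady state")
})

test_that("non-finite states abort with an integration failure", {
  p <- scenario_params("hf")
  s <- initial_state(p)
  s["Vlv"] <- NaN
  expect_error(network_derivatives(s, p), "non-finite")
})
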