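#' @keywords internal
#' @aliases cvrsim-package
#' @importFrom Rcpp evalCpp
#' @useDynLib cvrsim, .registration = TRUE
"_PACKAGE"

#' Integrate the closed-loop model
#'
#' Advances the coupled cardiac, vascular, control, respiratory and VAD
#' equations with the compiled fixed-step fourth-order Runge-Kutta
#' integrator. The step is small against the fastest valve/compliance time
#' constants (convergence under step halving is exercised in the test
#' suite), and the fixed grid makes repeated runs bit-identical: the model
#' contains no randomness. Heart rate is re-sampled from the baroreflex at
#' each cardiac cycle boundary and held within the cycle, so cycles are
#' crisp units for averaging.
#'
#' @param config A `cvr_config` from [scenario_config()] / [load_config()].
#' @param duration Simulated time (s).
#' @param state Optional initial state (defaults to [initial_state()]).
#' @param t0 Start time (s); protocol ramps reference absolute time.
#' @param dt Integration step (s).
#' @param dt_out Output sampling interval (s).
#' @param inputs Optional named list overriding the protocol input
#'   parameters (`in_vo2_a`, `in_vo2_b`, `in_t0`, `in_ramp`, `in_rq_a`,
#'   `in_rq_b`, `in_omega`).
#' @return A `cvr_result`: list with `timeseries` (matrix: time, states,
#'   derived channels), `final_state`, `final_time`, `params` and warning
#'   counters (`n_suction` steps with left ventricular volume below the
#'   suction threshold, `n_o2_clamp` steps with exhausted regional venous
#'   oxygen).
#' @export
cvr_simulate <- function(config, duration, state = NULL, t0 = 0,
                         dt = 2.5e-4, dt_out = 5e-3, inputs = NULL) {
  stopifnot(inherits(config, "cvr_config"))
  params <- config$params
  if (!is.null(inputs)) {
    bad <- setdiff(names(inputs), names(params))
    if (length(bad)) stop("unknown input override: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    params[names(inputs)] <- inputs
  }
  if (is.null(state)) state <- initial_state(params)
  res <- engine_run(unname(state[cvr_state_names()]), params, t0, duration,
                    dt, dt_out)
  colnames(res$out) <- c("time", cvr_state_names(), cvr_derived_names())
  fin <- stats::setNames(as.numeric(res$final_state), cvr_state_names())
  if (res$n_suction > 0) {
    warning("left ventricular volume fell below the suction threshold during ",
            res$n_suction, " integration steps", call. = FALSE)
  }
  structure(list(timeseries = res$out, final_state = fin,
                 final_time = res$final_time, params = params,
                 n_suction = res$n_suction, n_o2_clamp = res$n_o2_clamp),
            class = "cvr_result")
}

#' Hemodynamic summary over the last cardiac cycles of a simulation
#'
#' Means over the last `n_cycles` complete cardiac cycles (cycle boundaries
#' come from the activation clock), the averaging window used to suppress
#' the ventilatory modulation of the hemodynamic signals. Wedge pressure is
#' reported as the mean left atrial pressure, and end-diastolic /
#' end-systolic volumes as per-cycle extrema averaged across the window.
#'
#' @param result A `cvr_result`.
#' @param n_cycles Number of cycles to average (default 15).
#' @return A `cvr_summary`: named list with `HR` (bpm), `CO`, `Q_LV`,
#'   `Q_VAD` (l/min), `Pas`, `Pap`, `Pwedge`, `Pra` (mmHg), `VED`, `VES`,
#'   `SV` (cm^3), `EF` (%), `Ve` (l/min), `avO2` (ml/dl), `VO2` (ml/min),
#'   and `t_window` (s, time span averaged).
#' @export
cvr_summarize <- function(result, n_cycles = 15) {
  stopifnot(inherits(result, "cvr_result"))
  ts <- result$timeseries
  cyc <- ts[, "cycle"]
  ids <- unique(cyc)
  ids <- ids[ids > min(cyc) & ids < max(cyc)] # complete cycles only
  if (length(ids) < n_cycles) {
    stop("result spans ", length(ids), " complete cycles; ", n_cycles,
         " required", call. = FALSE)
  }
  ids <- utils::tail(ids, n_cycles)
  sel <- cyc %in% ids
  w <- ts[sel, , drop = FALSE]
  mean_of <- function(col) mean(w[, col])
  per_cycle <- function(col, fn) {
    vapply(split(w[, col], w[, "cycle"]), fn, numeric(1))
  }
  ved <- mean(per_cycle("Vlv", max))
  ves <- mean(per_cycle("Vlv", min))
  q_lv <- mean_of("Qav") * 0.06      # cm^3/s -> l/min
  q_vad <- mean_of("Qvad") * 0.06
  out <- list(
    HR = mean(per_cycle("HR", mean)),
    CO = q_lv + q_vad,
    Q_LV = q_lv,
    Q_VAD = q_vad,
    Pas = mean_of("Paa"),
    Pap = mean_of("Ppa"),
    Pwedge = mean_of("Pla"),
    Pra = mean_of("Pra"),
    VED = ved,
    VES = ves,
    SV = ved - ves,
    EF = 100 * (ved - ves) / ved,
    Ve = mean_of("Ve"),
    avO2 = mean_of("avO2"),
    VO2 = mean_of("Qrap") * 0.6 * mean_of("avO2"),
    t_window = diff(range(w[, "time"]))
  )
  structure(out, class = "cvr_summary")
}

#' @export
print.cvr_summary <- function(x, ...) {
  cat("Hemodynamic summary (", round(x$t_window, 1), " s window)\n", sep = "")
  cat(sprintf("  HR %6.1f bpm   CO %5.2f l/min  (LV %4.2f + VAD %4.2f)\n",
              x$HR, x$CO, x$Q_LV, x$Q_VAD))
  cat(sprintf("  Pas %5.1f  Pap %5.1f  Pwedge %5.1f  Pra %5.1f mmHg\n",
              x$Pas, x$Pap, x$Pwedge, x$Pra))
  cat(sprintf("  VED %5.1f  VES %5.1f cm^3   SV %4.1f  EF %4.1f %%\n",
              x$VED, x$VES, x$SV, x$EF))
  cat(sprintf("  Ve %5.1f l/min   a-v O2 %4.1f ml/dl   VO2 %5.0f ml/min\n",
              x$Ve, x$avO2, x$VO2))
  invisible(x)
}

#' Run one protocol phase to steady state
#'
#' Integrates in windows of `n_cycles` cardiac cycles and declares steady
#' state when the windowed means of cardiac output, systemic arterial
#' pressure and wedge pressure each change by less than `tol` (relative)
#' between consecutive windows, after the input ramp has completed. Errors
#' if the phase does not settle within `max_dur` simulated seconds.
#'
#' @param config A `cvr_config`.
#' @param phase Phase definition (see [scenario_protocol()]).
#' @param state Initial state (defaults to [initial_state()]).
#' @param t0 Absolute start time (s).
#' @param tol Relative steady-state tolerance (default 0.005).
#' @param n_cycles Averaging window in cycles (default 15).
#' @param dt,dt_out Integrator steps (s).
#' @param min_settle Minimum settling time before testing convergence (s).
#' @return List with `result` (`cvr_result` of the final window),
#'   `summary` (`cvr_summary`), `state` (final state), `t_end`.
#' @export
run_to_steady_state <- function(config, phase, state = NULL, t0 = 0,
                                tol = 0.005, n_cycles = 15, dt = 2.5e-4,
                                dt_out = 5e-3, min_settle = 30) {
  stopifnot(inherits(config, "cvr_config"))
  params <- config$params
  inputs <- list(
    in_vo2_a = if (is.null(state)) phase$vo2 else params$in_vo2_b,
    in_vo2_b = phase$vo2,
    in_rq_a = if (is.null(state)) phase$rq else params$in_rq_b,
    in_rq_b = phase$rq,
    in_t0 = t0, in_ramp = phase$ramp,
    in_omega = if (is.na(phase$omega)) params$in_omega else phase$omega
  )
  # window long enough for n_cycles + 2 partial cycles at the slowest rate
  t <- t0
  prev <- NULL
  res <- NULL
  repeat {
    hr_now <- if (is.null(state)) params$hr0 else state[["hrc"]]
    win <- (n_cycles + 2.5) * 60 / max(40, hr_now * 0.8)
    cfg_run <- config
    cfg_run$params[names(inputs)] <- inputs
    res <- cvr_simulate(cfg_run, duration = win, state = state, t0 = t,
                        dt = dt, dt_out = dt_out)
    state <- res$final_state
    t <- res$final_time
    sm <- cvr_summarize(res, n_cycles)
    ramp_done <- t - t0 >= phase$ramp + min_settle
    if (!is.null(prev) && ramp_done) {
      dco <- abs(sm$CO - prev$CO) / max(abs(prev$CO), 0.1)
      dpas <- abs(sm$Pas - prev$Pas) / max(abs(prev$Pas), 1)
      dpw <- abs(sm$Pwedge - prev$Pwedge) / max(abs(prev$Pwedge), 1)
      if (dco < tol && dpas < tol && dpw < tol) break
    }
    prev <- sm
    if (t - t0 > phase$max_dur) {
      stop(sprintf(paste0("phase '%s' did not reach steady state within %g s ",
                          "(last window: CO %.2f l/min, Pas %.1f mmHg, ",
                          "Pwedge %.1f mmHg)"),
                   phase$name, phase$max_dur, sm$CO, sm$Pas, sm$Pwedge),
           call. = FALSE)
    }
  }
  # record the phase inputs so the next phase starts from them
  attr(state, "inputs") <- inputs
  list(result = res, summary = cvr_summarize(res, n_cycles), state = state,
       t_end = t)
}

#' Run a full scenario protocol
#'
#' Executes the ordered phases of the scenario (rest, exercise, optional
#' pump-speed change), carrying the physiological state from each phase
#' into the next, and returns the steady-state summary of every phase.
#'
#' @param config A `cvr_config`.
#' @param keep_results Keep the final-window `cvr_result` of each phase
#'   (memory-heavier); default TRUE.
#' @param ... Passed to [run_to_steady_state()].
#' @return A `cvr_protocol_result`: list with `summaries` (named list of
#'   `cvr_summary`), `results` (named list of `cvr_result` or NULL) and
#'   `condition`.
#' @export
run_protocol <- function(config, keep_results = TRUE, ...) {
  stopifnot(inherits(config, "cvr_config"))
  state <- NULL
  t0 <- 0
  summaries <- list()
  results <- list()
  for (phase in config$protocol) {
    step <- run_to_steady_state(config, phase, state = state, t0 = t0, ...)
    summaries[[phase$name]] <- step$summary
    results[[phase$name]] <- if (keep_results) step$result else NULL
    state <- step$state
    t0 <- step$t_end
    # subsequent phases ramp from the inputs reached here
    config$params[names(attr(state, "inputs"))] <- attr(state, "inputs")
  }
  structure(list(summaries = summaries, results = results,
                 condition = config$condition),
            class = "cvr_protocol_result")
}
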