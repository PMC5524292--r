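#' Continuous-flow VAD parameter set
#'
#' Axial rotary blood pump (HeartMate II class) between the left ventricular
#' apex and the ascending aorta. The static characteristic is quadratic in
#' both speed and flow, `H = k_w * w^2 - k_q1 * Q - k_q2 * Q * |Q|`, and the
#' pump branch carries a cannula resistance and inertance so that the flow
#' responds with first-order dynamics to pressure imbalances.
#'
#' @param k_w Speed coefficient (mmHg/rpm^2).
#' @param k_q1 Linear flow coefficient (mmHg s/cm^3).
#' @param k_q2 Quadratic flow coefficient (mmHg s^2/cm^6).
#' @param Rc Cannula resistance (mmHg s/cm^3).
#' @param Lc Cannula + impeller inertance (mmHg s^2/cm^3).
#' @param speed_min,speed_max Admissible speed range (rpm).
#' @return A `cvr_vad` parameter list.
#' @export
vad_params <- function(k_w, k_q1, k_q2, Rc = 0.035, Lc = 0.005,
                       speed_min = 6000, speed_max = 12000) {
  if (any(c(k_w, k_q1, k_q2, Rc, Lc) < 0)) {
    stop("VAD coefficients must be >= 0", call. = FALSE)
  }
  structure(list(k_w = k_w, k_q1 = k_q1, k_q2 = k_q2, Rc = Rc, Lc = Lc,
                 speed_min = speed_min, speed_max = speed_max),
            class = "cvr_vad")
}

#' Pump pressure head at a given flow and speed
#'
#' @param Q Pump flow (cm^3/s); may be negative (backflow).
#' @param omega Pump speed (rpm), within the configured bounds.
#' @param params A `cvr_vad` parameter set.
#' @return Pressure head (mmHg); decreasing in `Q` at fixed speed.
#' @export
vad_pressure_head <- function(Q, omega, params) {
  stopifnot(inherits(params, "cvr_vad"))
  if (any(omega < params$speed_min | omega > params$speed_max)) {
    stop(sprintf("pump speed must lie in [%g, %g] rpm",
                 params$speed_min, params$speed_max), call. = FALSE)
  }
  params$k_w * omega^2 - params$k_q1 * Q - params$k_q2 * Q * abs(Q)
}

#' Time derivative of the pump flow
#'
#' `dQ/dt = (Plv - Pao + H(Q, omega) - Rc * Q) / Lc`. Instantaneous negative
#' flow (diastolic backflow, or regurgitation through an unpowered pump) is
#' admitted and flagged by the caller.
#'
#' @param Plv Left ventricular pressure (mmHg).
#' @param Pao Aortic pressure at the outflow graft (mmHg).
#' @param Q Current pump flow (cm^3/s).
#' @param omega Pump speed (rpm); 0 is accepted here to represent an
#'   unpowered pump.
#' @param params A `cvr_vad` parameter set.
#' @return `dQ/dt` (cm^3/s^2).
#' @export
vad_flow_derivative <- function(Plv, Pao, Q, omega, params) {
  stopifnot(inherits(params, "cvr_vad"))
  H <- params$k_w * omega^2 - params$k_q1 * Q - params$k_q2 * Q * abs(Q)
  (Plv - Pao + H - params$Rc * Q) / params$Lc
}

#' Calibrate pump coefficients from operating-point anchors
#'
#' Least-squares fit of `(k_w, k_q1, k_q2)` to anchors `(omega, Q, H)`
#' describing mean operating points of the pump (speed in rpm, flow in
#' cm^3/s, head in mmHg). At least two anchors at distinct speeds are
#' required; with fewer, or with a rank-deficient design, the problem is
#' underdetermined and an error is raised. Coefficients are constrained to
#' be non-negative.
#'
#' @param anchors Data frame (or matrix) with columns `omega`, `Q`, `H`.
#' @param Rc,Lc Cannula properties passed through to the result.
#' @return A `cvr_vad` parameter set.
#' @export
calibrate_vad <- function(anchors, Rc = 0.035, Lc = 0.005) {
  anchors <- as.data.frame(anchors)
  if (!all(c("omega", "Q", "H") %in% names(anchors))) {
    stop("anchors must have columns omega, Q and H", call. = FALSE)
  }
  if (nrow(anchors) < 2 || length(unique(anchors$omega)) < 2) {
    stop("need at least two anchors at distinct speeds", call. = FALSE)
  }
  X <- cbind(w2 = anchors$omega^2, q1 = -anchors$Q,
             q2 = -anchors$Q * abs(anchors$Q))
  # with only two anchors the quadratic flow term is unidentifiable: drop it
  p <- if (nrow(anchors) == 2) 2L else 3L
  X <- X[, seq_len(p), drop = FALSE]
  if (qr(X)$rank < p) {
    stop("degenerate anchor set: design matrix is rank deficient",
         call. = FALSE)
  }
  # scale columns for numerical balance, then ordinary least squares
  sc <- apply(abs(X), 2, max)
  beta <- qr.solve(sweep(X, 2, sc, "/"), anchors$H) / sc
  if (p == 2L) beta <- c(beta, 0)
  beta <- pmax(beta, 0)
  vad_params(k_w = beta[[1]], k_q1 = beta[[2]], k_q2 = beta[[3]],
             Rc = Rc, Lc = Lc)
}
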