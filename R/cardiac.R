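#' Cardiac cycle timing from heart rate
#'
#' Partitions the RR interval into systole and diastole. Systole duration
#' follows the classical systolic-interval relation `Tsys = ks * sqrt(RR)`,
#' so that as heart rate rises diastole shortens proportionally more than
#' systole (the systolic fraction `Tsys/RR` grows with HR).
#'
#' @param HR Heart rate (bpm), between 30 and 220.
#' @param ks Systolic interval constant (s^0.5), default 0.3.
#' @return An object of class `cvr_timing`: list with `HR`, `RR`, `Tsys`,
#'   `Tdias` (all in s except `HR`).
#' @examples
#' cardiac_cycle_timing(60) # RR = 1 s, Tsys = 0.3 s, Tdias = 0.7 s
#' @export
cardiac_cycle_timing <- function(HR, ks = 0.3) {
  if (!is.numeric(HR) || length(HR) != 1L || !is.finite(HR) || HR < 30 || HR > 220) {
    stop("HR must be a single value between 30 and 220 bpm", call. = FALSE)
  }
  RR <- 60 / HR
  Tsys <- ks * sqrt(RR)
  Tdias <- RR - Tsys
  if (Tdias <= 0) {
    stop("non-positive diastolic interval: ks too large for this heart rate",
         call. = FALSE)
  }
  structure(list(HR = HR, RR = RR, Tsys = Tsys, Tdias = Tdias),
            class = "cvr_timing")
}

#' Ventricular activation function
#'
#' Dimensionless contraction function `vc(t)` that weights the systolic
#' elastance against the diastolic stiffness of a ventricle. It rises as a
#' squared half-sine from 0 at the onset of systole to 1 at end systole
#' (`t = Tsys`), decays smoothly back to 0 over a short isovolumic
#' relaxation tail of duration `relax_frac * Tsys`, and is identically 0 for
#' the remainder of diastole. Times outside `[0, RR)` are wrapped modulo the
#' cycle length.
#'
#' @param t Time within the cardiac cycle (s); wrapped modulo `RR`.
#' @param timing A `cvr_timing` object from [cardiac_cycle_timing()].
#' @param relax_frac Relaxation tail duration as a fraction of `Tsys`.
#' @return Activation in `[0, 1]` (vectorised over `t`).
#' @export
ventricular_activation <- function(t, timing, relax_frac = 0.3) {
  stopifnot(inherits(timing, "cvr_timing"))
  t <- t %% timing$RR
  Tsys <- timing$Tsys
  Trel <- relax_frac * Tsys
  vc <- numeric(length(t))
  rise <- t <= Tsys
  vc[rise] <- sin(pi * t[rise] / (2 * Tsys))^2
  fall <- !rise & t <= Tsys + Trel
  vc[fall] <- cos(pi * (t[fall] - Tsys) / (2 * Trel))^2
  vc
}

#' Ventricle parameter set
#'
#' @param Es End-systolic elastance (mmHg/cm^3).
#' @param V0 Zero-pressure volume of the systolic elastance line (cm^3).
#' @param a Diastolic stiffness scale (mmHg).
#' @param b Diastolic stiffness exponent (cm^-3).
#' @return A `cvr_ventricle` parameter list.
#' @export
ventricle_params <- function(Es, V0, a, b) {
  if (Es <= 0 || a <= 0 || b <= 0) {
    stop("Es, a and b must all be positive", call. = FALSE)
  }
  structure(list(Es = Es, V0 = V0, a = a, b = b), class = "cvr_ventricle")
}

#' Instantaneous ventricular pressure
#'
#' Blends the systolic elastance line with the exponential end-diastolic
#' pressure-volume relation through the activation `vc`:
#' `P = vc * Es * (V - V0) + (1 - vc) * a * exp(b * V) + Pintr`.
#' At `vc = 1` this is exactly the time-varying elastance relation; at
#' `vc = 0` exactly the exponential diastolic stiffness. The exponent acts on
#' the absolute volume (not `V - V0`), matching the form in which the
#' diastolic coefficients were fitted.
#'
#' @param V Ventricular volume (cm^3).
#' @param vc Activation in `[0, 1]` (see [ventricular_activation()]).
#' @param params A `cvr_ventricle` parameter set.
#' @param Pintr Intrathoracic (pleural) pressure (mmHg), default 0.
#' @return Pressure (mmHg).
#' @export
ventricular_pressure <- function(V, vc, params, Pintr = 0) {
  stopifnot(inherits(params, "cvr_ventricle"))
  vc * params$Es * (V - params$V0) +
    (1 - vc) * params$a * exp(params$b * V) + Pintr
}

#' Atrium parameter set
#'
#' Atria are linear compliances with an active late-diastolic contraction
#' ("atrial kick"): a Gaussian elastance pulse centred in the last part of
#' the RR interval, just before ventricular systole, that tops up
#' ventricular filling.
#'
#' @param C Compliance (cm^3/mmHg).
#' @param V0 Unstressed volume (cm^3).
#' @param kick_amplitude Peak active elastance increment (mmHg/cm^3).
#' @param kick_center Centre of the kick as a fraction of the RR interval.
#' @param kick_width Width (2 sigma) of the kick as a fraction of RR.
#' @return A `cvr_atrium` parameter list.
#' @export
atrium_params <- function(C, V0, kick_amplitude = 0, kick_center = 0.925,
                          kick_width = 0.075) {
  if (C <= 0) stop("atrial compliance must be positive", call. = FALSE)
  if (kick_amplitude < 0) stop("kick_amplitude must be >= 0", call. = FALSE)
  if (kick_center < 0 || kick_center >= 1 || kick_width <= 0 || kick_width >= 1) {
    stop("kick timing fractions must lie in [0, 1)", call. = FALSE)
  }
  structure(list(C = C, V0 = V0, kick_amplitude = kick_amplitude,
                 kick_center = kick_center, kick_width = kick_width),
            class = "cvr_atrium")
}

#' Active atrial elastance at a phase of the cycle
#'
#' @param phase Cardiac phase in `[0, 1)` (fraction of the RR interval).
#' @param params A `cvr_atrium` parameter set.
#' @return Active elastance increment (mmHg/cm^3).
#' @export
atrial_activation <- function(phase, params) {
  stopifnot(inherits(params, "cvr_atrium"))
  phase <- phase %% 1
  s <- params$kick_width / 2
  params$kick_amplitude * exp(-((phase - params$kick_center) / s)^2)
}

#' Instantaneous atrial pressure
#'
#' `P = (V - V0)/C + e_act(phase) * (V - V0) + Pintr`, where `e_act` is the
#' Gaussian active elastance of the late-diastolic kick.
#'
#' @param V Atrial volume (cm^3).
#' @param phase Cardiac phase in `[0, 1)`.
#' @param params A `cvr_atrium` parameter set.
#' @param Pintr Intrathoracic pressure (mmHg), default 0.
#' @return Pressure (mmHg).
#' @export
atrial_pressure <- function(V, phase, params, Pintr = 0) {
  stopifnot(inherits(params, "cvr_atrium"))
  dv <- V - params$V0
  dv / params$C + atrial_activation(phase, params) * dv + Pintr
}

#' Flow through a competent heart valve
#'
#' Diode-resistor valve: forward flow proportional to the positive pressure
#' gradient, zero flow otherwise (no regurgitation).
#'
#' @param P_up Upstream pressure (mmHg).
#' @param P_down Downstream pressure (mmHg).
#' @param R Valve resistance (mmHg s/cm^3), must be positive.
#' @return Flow (cm^3/s), never negative.
#' @export
valve_flow <- function(P_up, P_down, R) {
  if (!is.numeric(R) || any(R <= 0)) {
    stop("valve resistance must be positive", call. = FALSE)
  }
  pmax(0, (P_up - P_down) / R)
}
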