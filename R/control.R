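#' Baroreflex parameter set
#'
#' Short-term arterial baroreflex acting on heart rate, ventricular
#' contractility, regional arterial resistance and venous tone. The static
#' characteristic is a saturating sigmoid of the deviation of (filtered)
#' aortic pressure from the set-point; each effector follows it with
#' first-order dynamics. Exercise shifts the set-point upward (baroreflex
#' resetting) in proportion to oxygen uptake above rest, and a sympathetic
#' ceiling on the heart-rate effector reproduces the chronotropic
#' incompetence of heart failure.
#'
#' @param Pset Set-point pressure at rest (mmHg).
#' @param kb Sigmoid width (mmHg): effector drive is
#'   `tanh((Pset_eff - Pas)/kb)`.
#' @param resetting_gain Set-point shift per unit of oxygen uptake above
#'   rest (mmHg per ml/min/kg).
#' @param g_hr Fractional heart-rate rise at full sympathetic drive.
#' @param hr_max Sympathetic ceiling on heart rate (bpm); the imbalance
#'   between sympathetic and vagal limbs is expressed as this reduced
#'   attainable maximum.
#' @param hr_min Vagal floor on heart rate (bpm).
#' @param g_es Fractional contractility rise at full sympathetic drive.
#' @param g_r Fractional arterial resistance rise at full sympathetic drive.
#' @param g_vu Fractional venous unstressed-volume reduction at full
#'   sympathetic drive.
#' @param tau_p Time constant of the aortic pressure filter (s).
#' @param tau_hr Time constant of the heart-rate effector (s).
#' @param tau_sym Time constant of the slower sympathetic effectors (s).
#' @return A `cvr_baroreflex` parameter list.
#' @export
baroreflex_params <- function(Pset, kb = 5, resetting_gain = 1,
                              g_hr = 0.55, hr_max = 112, hr_min = 45,
                              g_es = 0.35, g_r = 0.6, g_vu = 0.1,
                              tau_p = 2, tau_hr = 3, tau_sym = 8) {
  if (Pset <= 0) stop("Pset must be positive", call. = FALSE)
  if (any(c(tau_p, tau_hr, tau_sym) <= 0)) {
    stop("time constants must be positive", call. = FALSE)
  }
  structure(list(Pset = Pset, kb = kb, resetting_gain = resetting_gain,
                 g_hr = g_hr, hr_max = hr_max, hr_min = hr_min,
                 g_es = g_es, g_r = g_r, g_vu = g_vu,
                 tau_p = tau_p, tau_hr = tau_hr, tau_sym = tau_sym),
            class = "cvr_baroreflex")
}

#' Initial (equilibrium) baroreflex control state
#'
#' @param Pas Initial filtered arterial pressure (mmHg).
#' @return A `cvr_control_state` list with the filtered pressure and the
#'   heart-rate and sympathetic effector activities (in `[-1, 1]`, 0 at
#'   equilibrium).
#' @export
control_state <- function(Pas) {
  structure(list(P_filt = Pas, x_hr = 0, x_sym = 0),
            class = "cvr_control_state")
}

#' Advance the baroreflex state by one time step
#'
#' First-order relaxation of the filtered pressure and of the two effector
#' activities toward the static sigmoid `tanh((Pset_eff - P_filt)/kb)`.
#' When the sensed pressure is below the (effective) set-point, sympathetic
#' activity becomes positive: heart rate, contractility and arterial
#' resistance multipliers rise above 1 and venous unstressed volume falls;
#' the response is symmetric for pressures above the set-point.
#'
#' @param Pas Current mean aortic pressure sample (mmHg).
#' @param params A `cvr_baroreflex` parameter set.
#' @param state A `cvr_control_state`.
#' @param dt Time step (s), > 0.
#' @param Pset_eff Effective set-point (mmHg); defaults to the resting
#'   `Pset` (see [baroreflex_reset()] for exercise).
#' @return Updated `cvr_control_state`.
#' @export
baroreflex_update <- function(Pas, params, state, dt, Pset_eff = params$Pset) {
  stopifnot(inherits(params, "cvr_baroreflex"),
            inherits(state, "cvr_control_state"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  state$P_filt <- state$P_filt + dt * (Pas - state$P_filt) / params$tau_p
  sigma <- tanh((Pset_eff - state$P_filt) / params$kb)
  state$x_hr <- state$x_hr + dt * (sigma - state$x_hr) / params$tau_hr
  state$x_sym <- state$x_sym + dt * (sigma - state$x_sym) / params$tau_sym
  state
}

#' Effector multipliers of the current control state
#'
#' @param state A `cvr_control_state`.
#' @param params A `cvr_baroreflex` parameter set.
#' @return Named list: `hr` (bpm multiplier before clamping), `es`
#'   (contractility multiplier), `r_art` (arterial resistance multiplier),
#'   `vu` (venous unstressed-volume multiplier). All equal 1 at equilibrium.
#' @export
baroreflex_effectors <- function(state, params) {
  stopifnot(inherits(params, "cvr_baroreflex"),
            inherits(state, "cvr_control_state"))
  list(hr = 1 + params$g_hr * state$x_hr,
       es = max(0.3, 1 + params$g_es * state$x_sym),
       r_art = max(0.4, 1 + params$g_r * state$x_sym),
       vu = 1 - params$g_vu * state$x_sym)
}

#' Exercise resetting of the baroreflex set-point
#'
#' The operating point of the baroreflex shifts to higher pressures during
#' exercise, linearly in the oxygen uptake above rest.
#'
#' @param VO2 Current oxygen uptake (ml/min/kg), >= `VO2_rest`.
#' @param VO2_rest Resting oxygen uptake (ml/min/kg).
#' @param params A `cvr_baroreflex` parameter set.
#' @return Effective set-point pressure (mmHg).
#' @export
baroreflex_reset <- function(VO2, VO2_rest, params) {
  stopifnot(inherits(params, "cvr_baroreflex"))
  if (any(VO2 < VO2_rest)) stop("VO2 must be >= VO2_rest", call. = FALSE)
  params$Pset + params$resetting_gain * (VO2 - VO2_rest)
}

#' Heart rate commanded by the baroreflex
#'
#' Scales the resting heart rate by the heart-rate effector and clamps the
#' result between the vagal floor and the sympathetic ceiling `hr_max`. The
#' ceiling implements the sympathovagal imbalance of heart failure: however
#' strong the sympathetic drive, the commanded rate cannot exceed it, which
#' caps the attainable peak-exercise heart rate well below the age-predicted
#' maximum (chronotropic incompetence).
#'
#' @param state A `cvr_control_state`.
#' @param params A `cvr_baroreflex` parameter set.
#' @param HR_rest Resting heart rate (bpm), > 0.
#' @return Commanded heart rate (bpm).
#' @export
heart_rate_command <- function(state, params, HR_rest) {
  if (HR_rest <= 0) stop("HR_rest must be positive", call. = FALSE)
  eff <- baroreflex_effectors(state, params)
  min(params$hr_max, max(params$hr_min, HR_rest * eff$hr))
}

#' Metabolic control parameter set
#'
#' @param ref Reference venous oxygen concentration (ml O2/dl blood), > 0.
#' @param floor Minimum resistance multiplier (fraction of the resting
#'   resistance), in (0, 1].
#' @param width Oxygen deficit scale of the vasodilation law (ml/dl).
#' @param tau Time constant of the local vasodilation dynamics (s).
#' @return A `cvr_metabolic` parameter list.
#' @export
metabolic_params <- function(ref, floor = 0.2, width = 2.5, tau = 15) {
  if (ref <= 0) stop("reference venous O2 must be positive", call. = FALSE)
  if (floor <= 0 || floor > 1) stop("floor must lie in (0, 1]", call. = FALSE)
  structure(list(ref = ref, floor = floor, width = width, tau = tau),
            class = "cvr_metabolic")
}

#' Static metabolic vasodilation characteristic
#'
#' Resistance multiplier of a regional arterial bed as a function of the
#' local venous oxygen concentration. At or above the reference value the
#' multiplier is 1 (no vasodilation); as the venous oxygen content falls the
#' multiplier decreases monotonically (Gaussian decay in the deficit) toward
#' the configured floor. The control is strictly local: each region responds
#' only to its own venous oxygen level.
#'
#' @param CvO2 Regional venous oxygen concentration (ml/dl), >= 0.
#' @param params A `cvr_metabolic` parameter set.
#' @return Resistance multiplier in `[floor, 1]`.
#' @export
metabolic_vasodilation_static <- function(CvO2, params) {
  stopifnot(inherits(params, "cvr_metabolic"))
  if (any(CvO2 < 0)) stop("CvO2 must be >= 0", call. = FALSE)
  deficit <- pmax(0, params$ref - CvO2)
  params$floor + (1 - params$floor) * exp(-(deficit / params$width)^2)
}

#' Advance a regional vasodilation multiplier by one time step
#'
#' First-order relaxation of the local resistance multiplier toward the
#' static characteristic [metabolic_vasodilation_static()].
#'
#' @param m Current resistance multiplier.
#' @param CvO2 Regional venous oxygen concentration (ml/dl).
#' @param params A `cvr_metabolic` parameter set.
#' @param dt Time step (s), > 0.
#' @return Updated multiplier.
#' @export
metabolic_vasodilation <- function(m, CvO2, params, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  target <- metabolic_vasodilation_static(CvO2, params)
  m + dt * (target - m) / params$tau
}
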