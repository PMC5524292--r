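#' Oxygen content of blood
#'
#' Hill-type oxyhemoglobin dissociation plus physically dissolved oxygen:
#' `CaO2 = 1.34 * Hb * S(PO2) + 0.003 * PO2` with
#' `S = PO2^n / (PO2^n + P50^n)`.
#'
#' @param PO2 Oxygen partial pressure (mmHg), >= 0.
#' @param Hb Hemoglobin concentration (g/dl).
#' @param P50 Half-saturation pressure (mmHg), default 26.6.
#' @param n Hill coefficient, default 2.7.
#' @return Oxygen content (ml O2/dl blood).
#' @export
o2_content <- function(PO2, Hb, P50 = 26.6, n = 2.7) {
  if (any(PO2 < 0)) stop("PO2 must be >= 0", call. = FALSE)
  sat <- PO2^n / (PO2^n + P50^n)
  1.34 * Hb * sat + 0.003 * PO2
}

#' Carbon dioxide content of blood
#'
#' Linearised CO2 dissociation law `C = c0 + slope * PCO2`, adequate over
#' the physiological range of this simulator (no acid-base chemistry).
#'
#' @param PCO2 CO2 partial pressure (mmHg).
#' @param c0 Intercept (ml/dl), default 21.5.
#' @param slope Slope (ml/dl/mmHg), default 0.6625 (content 48 ml/dl at
#'   40 mmHg).
#' @return CO2 content (ml/dl).
#' @export
co2_content <- function(PCO2, c0 = 21.5, slope = 0.6625) {
  c0 + slope * PCO2
}

#' CO2 partial pressure from content (inverse of [co2_content()])
#' @param C CO2 content (ml/dl).
#' @inheritParams co2_content
#' @return PCO2 (mmHg).
#' @export
co2_partial_pressure <- function(C, c0 = 21.5, slope = 0.6625) {
  (C - c0) / slope
}

#' Ventilation control parameter set
#'
#' Minute ventilation is commanded by a feed-forward term proportional to
#' the whole-body CO2 production (the dominant exercise hyperpnea drive)
#' plus feedback corrections for arterial CO2 deviations and for hypoxia.
#'
#' @param Ve0 Resting minute ventilation (l/min).
#' @param vco2_ref Resting CO2 production (ml/min).
#' @param k_ff Feed-forward gain (l/min per ml/min of VCO2).
#' @param g_co2 PaCO2 feedback gain (l/min per mmHg).
#' @param paco2_ref PaCO2 reference (mmHg).
#' @param g_o2 Hypoxic gain (l/min per mmHg below `pao2_thr`).
#' @param pao2_thr Hypoxic drive threshold (mmHg).
#' @param f0 Resting breathing frequency (1/min).
#' @param k_f Frequency increase per l/min of ventilation above rest.
#' @param VD Anatomical + alveolar dead space per breath (l).
#' @param tau Time constant of the ventilation response (s).
#' @return A `cvr_ventilation` parameter list.
#' @export
ventilation_params <- function(Ve0 = 9.2, vco2_ref = 207, k_ff = 0.02908,
                               g_co2 = 0.15, paco2_ref = 35, g_o2 = 0.25,
                               pao2_thr = 60, f0 = 12, k_f = 0.8,
                               VD = 0.3, tau = 15) {
  structure(list(Ve0 = Ve0, vco2_ref = vco2_ref, k_ff = k_ff,
                 g_co2 = g_co2, paco2_ref = paco2_ref, g_o2 = g_o2,
                 pao2_thr = pao2_thr, f0 = f0, k_f = k_f, VD = VD,
                 tau = tau),
            class = "cvr_ventilation")
}

#' Commanded minute ventilation
#'
#' @param PaO2 Arterial O2 partial pressure (mmHg).
#' @param PaCO2 Arterial CO2 partial pressure (mmHg).
#' @param vco2 Current whole-body CO2 production (ml/min).
#' @param params A `cvr_ventilation` parameter set.
#' @return Commanded minute ventilation (l/min), floored at 2 l/min.
#' @export
ventilation_control <- function(PaO2, PaCO2, vco2, params) {
  stopifnot(inherits(params, "cvr_ventilation"))
  ve <- params$Ve0 + params$k_ff * (vco2 - params$vco2_ref) +
    params$g_co2 * (PaCO2 - params$paco2_ref) +
    params$g_o2 * pmax(0, params$pao2_thr - PaO2)
  pmax(2, ve)
}

#' Partition minute ventilation into frequency and tidal volume
#'
#' Monotone partition: breathing frequency rises linearly with ventilation
#' above its resting value and tidal volume is the quotient, so both grow
#' with the ventilatory demand.
#'
#' @param Ve Minute ventilation (l/min).
#' @param params A `cvr_ventilation` parameter set.
#' @return List with `f` (1/min), `Vt` (l) and alveolar ventilation `VA`
#'   (l/min, dead space subtracted, floored at 0.5).
#' @export
ventilation_pattern <- function(Ve, params) {
  stopifnot(inherits(params, "cvr_ventilation"))
  f <- params$f0 + params$k_f * pmax(0, Ve - params$Ve0)
  Vt <- Ve / f
  VA <- pmax(0.5, Ve - f * params$VD)
  list(f = f, Vt = Vt, VA = VA)
}

#' Respiratory mechanics over a breath
#'
#' Lung volume above functional residual capacity follows a raised-cosine
#' breath of tidal volume `Vt` at frequency `f`. Pleural pressure swings
#' with lung volume around a negative baseline; alveolar pressure is the
#' pleural pressure plus the elastic recoil `Elungs * Vlung`, and airflow is
#' driven through the airway resistance. With `Vt = 0` (apnea) pleural
#' pressure is constant and airflow zero.
#'
#' @param t Time (s), vectorised.
#' @param Vt Tidal volume (l).
#' @param f Breathing frequency (1/min).
#' @param Elungs Lung elastance (mmHg/l).
#' @param Raw Airway resistance (mmHg/(l/s)).
#' @param ppl_base End-expiratory pleural pressure (mmHg).
#' @param k_pl Pleural pressure swing per litre of lung inflation (mmHg/l).
#' @return List of vectors: `Vlung` (l above FRC), `Ppl` (mmHg), `Palv`
#'   (mmHg relative to atmosphere), `flow` (l/s, inspiratory positive).
#' @export
respiratory_mechanics <- function(t, Vt, f, Elungs = 3.5, Raw = 1.5,
                                  ppl_base = -2.5, k_pl = 3) {
  fs <- f / 60
  Vlung <- Vt / 2 * (1 - cos(2 * pi * fs * t))
  flow <- Vt / 2 * 2 * pi * fs * sin(2 * pi * fs * t)
  Ppl <- ppl_base - k_pl * Vlung
  Palv <- Ppl + Elungs * Vlung
  list(Vlung = Vlung, Ppl = Ppl, Palv = Palv, flow = flow)
}

#' Alveolar gas exchange step
#'
#' End-capillary blood leaving the lung equilibrates with the alveolar gas;
#' alveolar partial pressures evolve from the balance between alveolar
#' ventilation and the blood-gas fluxes (863 mmHg converts STPD gas flow to
#' partial-pressure units at body temperature).
#'
#' @param PAO2,PACO2 Alveolar partial pressures (mmHg).
#' @param flow Pulmonary capillary blood flow (cm^3/s), >= 0.
#' @param CvO2,CvCO2 Mixed-venous blood gas contents (ml/dl).
#' @param VA Alveolar ventilation (l/min).
#' @param dt Time step (s).
#' @param Hb Hemoglobin (g/dl).
#' @param Valv Effective alveolar gas volume (l).
#' @param PIO2 Inspired O2 partial pressure (mmHg).
#' @return List: updated `PAO2`, `PACO2`, end-capillary contents `CcO2`,
#'   `CcCO2`, and instantaneous lung `VO2`/`VCO2` (ml/min).
#' @export
lung_gas_exchange <- function(PAO2, PACO2, flow, CvO2, CvCO2, VA, dt,
                              Hb = 14.5, Valv = 2.5, PIO2 = 150) {
  if (flow < 0) stop("pulmonary flow must be >= 0", call. = FALSE)
  CcO2 <- o2_content(PAO2, Hb)
  CcCO2 <- co2_content(PACO2)
  q_dl_min <- flow * 0.6
  vo2 <- q_dl_min * (CcO2 - CvO2)    # ml/min taken up from alveoli
  vco2 <- q_dl_min * (CvCO2 - CcCO2) # ml/min released to alveoli
  dPAO2 <- (VA * (PIO2 - PAO2) - 0.863 * vo2) / (Valv * 60)
  dPACO2 <- (0.863 * vco2 - VA * PACO2) / (Valv * 60)
  list(PAO2 = PAO2 + dt * dPAO2, PACO2 = PACO2 + dt * dPACO2,
       CcO2 = CcO2, CcCO2 = CcCO2, VO2 = vo2, VCO2 = vco2)
}

#' Tissue gas exchange step for one vascular region
#'
#' First-order venous store dynamics: oxygen is extracted from the regional
#' inflow at the rate demanded by the regional metabolism, CO2 is added at
#' `RQ` times that rate. At steady state the venous oxygen content is
#' `CaO2 - VO2 / (0.6 * flow)` (Fick). If perfusion cannot cover the demand
#' the venous oxygen content floors at zero and a supply-limitation warning
#' is raised.
#'
#' @param CvO2,CvCO2 Current regional venous contents (ml/dl).
#' @param flow Regional blood flow (cm^3/s), > 0.
#' @param CaO2,CaCO2 Arterial contents (ml/dl).
#' @param VO2 Regional oxygen consumption (ml/min).
#' @param RQ Respiratory quotient.
#' @param dt Time step (s).
#' @param Vtis Effective venous/tissue distribution volume (dl).
#' @return List with updated `CvO2`, `CvCO2`.
#' @export
tissue_gas_exchange <- function(CvO2, CvCO2, flow, CaO2, CaCO2, VO2, RQ, dt,
                                Vtis = 2.5) {
  if (flow <= 0) stop("flow must be positive", call. = FALSE)
  q <- 0.01 * flow # dl/s
  dO2 <- (q * (CaO2 - CvO2) - VO2 / 60) / Vtis
  dCO2 <- (RQ * VO2 / 60 - q * (CvCO2 - CaCO2)) / Vtis
  CvO2n <- CvO2 + dt * dO2
  if (CvO2n < 0) {
    warning("regional venous O2 exhausted: oxygen delivery is supply-limited",
            call. = FALSE)
    CvO2n <- 0
  }
  list(CvO2 = CvO2n, CvCO2 = CvCO2 + dt * dCO2)
}
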