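#' Pressure of a vascular compartment
#'
#' Linear Windkessel pressure-volume relation with an optional smooth cubic
#' stiffening term used for the collapsible venous compartments (upper body,
#' splanchnic, legs and vena cava). In the normal working range the relation
#' is `(V - Vu)/C + P_ext`; far from it the cubic term makes `dP/dV` grow,
#' representing venous collapse when the vessel empties and wall stiffening
#' when it is overdistended.
#'
#' @param V Volume (cm^3).
#' @param C Compliance (cm^3/mmHg).
#' @param Vu Unstressed volume (cm^3).
#' @param P_ext External (e.g. intrathoracic or muscular) pressure (mmHg).
#' @param k3 Cubic stiffening coefficient (mmHg); 0 disables the
#'   nonlinearity (purely linear compartment).
#' @param Vn Stiffening volume scale (cm^3); the cubic term reaches `k3`
#'   when `|V - Vu| = Vn`.
#' @return Pressure (mmHg).
#' @export
vessel_pressure <- function(V, C, Vu, P_ext = 0, k3 = 0, Vn = 1) {
  if (C <= 0) stop("compliance must be positive", call. = FALSE)
  dv <- V - Vu
  P <- dv / C + P_ext
  if (k3 != 0) P <- P + k3 * (dv / Vn)^3
  P
}

#' Wedge-dependent pulmonary arterial compliance
#'
#' Pulmonary vascular congestion stiffens the pulmonary arterial tree: above
#' a wedge-pressure threshold the compliance decreases linearly with the
#' (mean) wedge pressure, with a floor at a fraction of the baseline value.
#' At and below the resting reference wedge pressure the baseline compliance
#' is returned unchanged. A systemic-resistance hook is part of the
#' signature for compatibility with alternative formulations but is inert by
#' default.
#'
#' @param Pwedge Mean left atrial (wedge) pressure (mmHg), >= 0.
#' @param base Baseline compliance (cm^3/mmHg).
#' @param threshold Wedge pressure above which stiffening begins (mmHg).
#' @param slope Fractional compliance loss per mmHg above threshold.
#' @param floor Minimum compliance as a fraction of `base`.
#' @param Ras Systemic arterial resistance hook (unused by default).
#' @return Compliance (cm^3/mmHg).
#' @export
pulmonary_arterial_compliance <- function(Pwedge, base, threshold = 15,
                                          slope = 0.05, floor = 0.5,
                                          Ras = NULL) {
  if (any(Pwedge < 0)) stop("Pwedge must be >= 0", call. = FALSE)
  base * pmax(floor, 1 - slope * pmax(0, Pwedge - threshold))
}

#' Leg muscle pump pressure
#'
#' External pressure exerted by the contracting leg muscles on the leg
#' venous compartments during cycling. Each leg is squeezed by a
#' half-rectified squared sinusoid at the pedalling cadence; the two legs
#' work in antiphase. At rest (`active = FALSE` or zero amplitude) the
#' pressure is identically zero.
#'
#' @param t Time (s).
#' @param cadence Pedalling cadence per leg (Hz).
#' @param amplitude Peak muscular pressure (mmHg), >= 0.
#' @param active Logical; whether the muscle pump is engaged.
#' @param leg `"left"` or `"right"` (legs are in antiphase).
#' @return External pressure (mmHg), vectorised over `t`.
#' @export
muscle_pump_pressure <- function(t, cadence, amplitude, active = TRUE,
                                 leg = c("left", "right")) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  leg <- match.arg(leg)
  if (!active || amplitude == 0) return(rep(0, length(t)))
  shift <- if (leg == "right") 0.5 else 0
  amplitude * pmax(0, sin(2 * pi * (cadence * t + shift)))^2
}

#' Flow through a Starling resistor
#'
#' Collapsible-tube (vascular waterfall) behaviour: when the surrounding
#' pressure exceeds the downstream luminal pressure, the effective
#' downstream pressure becomes the surrounding pressure; when it exceeds the
#' upstream pressure as well, the tube collapses and flow stops.
#'
#' @param P_up Upstream pressure (mmHg).
#' @param P_down Downstream pressure (mmHg).
#' @param P_ext Surrounding (external) pressure (mmHg).
#' @param R Resistance (mmHg s/cm^3), must be positive.
#' @return Flow (cm^3/s), never negative.
#' @export
starling_resistor_flow <- function(P_up, P_down, P_ext, R) {
  if (any(R <= 0)) stop("resistance must be positive", call. = FALSE)
  pmax(0, (P_up - pmax(P_down, P_ext)) / R)
}

#' Estimate systemic and pulmonary arterial resistances
#'
#' Mean-hemodynamics estimates `Ras = (Pas - Pcv)/CO` and
#' `Rap = (Pap - Pwedge)/CO`, with cardiac output converted from l/min to
#' cm^3/s internally so that the resistances come out in mmHg s/cm^3.
#'
#' @param Pas Mean systemic arterial pressure (mmHg).
#' @param Pcv Mean central venous pressure (mmHg).
#' @param Pap Mean pulmonary arterial pressure (mmHg).
#' @param Pwedge Mean pulmonary capillary wedge pressure (mmHg).
#' @param CO Cardiac output (l/min), > 0.
#' @return List with `Ras` and `Rap` (mmHg s/cm^3).
#' @export
estimate_resistances <- function(Pas, Pcv, Pap, Pwedge, CO) {
  if (CO <= 0) stop("CO must be positive", call. = FALSE)
  if (Pas <= Pcv) stop("Pas must exceed Pcv", call. = FALSE)
  if (Pap <= Pwedge) stop("Pap must exceed Pwedge", call. = FALSE)
  q <- CO * 1000 / 60
  list(Ras = (Pas - Pcv) / q, Rap = (Pap - Pwedge) / q)
}

#' Split a total systemic resistance into regional resistances
#'
#' Distributes the lumped systemic arterial resistance over parallel
#' regional beds (upper body, kidneys, splanchnic circulation, left and
#' right legs) according to conductance fractions. The parallel combination
#' of the returned resistances equals `Ras` exactly.
#'
#' @param Ras Total systemic arterial resistance (mmHg s/cm^3).
#' @param fractions Named numeric vector of conductance fractions, summing
#'   to 1 (each region receives `fraction` of the total conductance).
#' @return Named numeric vector of regional resistances.
#' @export
split_systemic_resistance <- function(Ras, fractions = NULL) {
  if (is.null(fractions)) {
    # default split: conductance shares of the heart-failure regional beds
    g <- 1 / c(ub = 5.2, kid = 5.4, sp = 4.0, ll = 9.4, rl = 9.4)
    fractions <- g / sum(g)
  }
  if (Ras <= 0) stop("Ras must be positive", call. = FALSE)
  if (any(fractions <= 0)) stop("fractions must be positive", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("conductance fractions must sum to 1", call. = FALSE)
  }
  Ras / fractions
}
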