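#' State variable names of the closed-loop model
#'
#' Layout of the 44-element state vector used by [network_derivatives()]
#' and the compiled integrator: chamber and compartment volumes (cm^3),
#' inertial flows (cm^3/s), the cardiac phase clock, control states,
#' regional vasodilation multipliers, ventilation and blood-gas states.
#'
#' @return Character vector of state names, in canonical order.
#' @export
cvr_state_names <- function() {
  c("Vlv", "Vrv", "Vla", "Vra",
    "Vaa", "Vda", "Vub", "Vkid", "Vsp", "Vll", "Vrl", "Vvc", "Vpa", "Vpu",
    "Qda", "Qvad",
    "theta", "hrc", "cycle",
    "Pbar", "xhr", "xsym",
    "m_ub", "m_kid", "m_sp", "m_ll", "m_rl",
    "Ve", "ph_resp",
    "PAO2", "PACO2", "CaO2", "CaCO2",
    "CvO2_ub", "CvO2_kid", "CvO2_sp", "CvO2_ll", "CvO2_rl",
    "CvCO2_ub", "CvCO2_kid", "CvCO2_sp", "CvCO2_ll", "CvCO2_rl",
    "Pwb")
}

#' Baseline parameter set of a packaged scenario
#'
#' Returns the full flat parameter list of the simulator for one of the two
#' packaged conditions: severe heart failure (`"hf"`) or severe heart
#' failure supported by a continuous-flow VAD (`"hf_vad"`). Values fall in
#' three groups: (i) the published patient-characterisation parameters
#' (heart rate, ventricular elastances and diastolic stiffness
#' coefficients, regional arterial resistances, pulmonary resistance,
#' baroreflex set-point, reference venous O2 concentrations); (ii) standard
#' lumped-parameter constants (compliances, unstressed volumes, valve and
#' venous resistances, dissociation-curve constants); and (iii) closed-loop
#' calibration constants (control gains, pump coefficients, stressed
#' volume) tuned once so that the resting and peak-exercise states of each
#' condition reproduce the corresponding published hemodynamics.
#'
#' Units: pressures mmHg, volumes cm^3, flows cm^3/s, resistances
#' mmHg s/cm^3, compliances cm^3/mmHg, inertances mmHg s^2/cm^3, time s,
#' ventilation l/min, gas contents ml/dl, pump speed rpm.
#'
#' @param condition `"hf"` or `"hf_vad"`.
#' @return Named list of parameters.
#' @export
scenario_params <- function(condition = c("hf", "hf_vad")) {
  condition <- match.arg(condition)
  p <- list(
    # -- cardiac timing and chambers --
    hr0 = 81, ks = 0.3, relax_frac = 0.3,
    lv_Es = 0.5, lv_V0 = 50, lv_a = 0.0532, lv_b = 0.0194,
    rv_Es = 0.37, rv_V0 = -20, rv_a = 0.05, rv_b = 0.045,
    la_C = 5, la_Vu = 15, la_kick = 0.08,
    ra_C = 6, ra_Vu = 15, ra_kick = 0.15,
    kick_center = 0.925, kick_width = 0.12,
    R_mv = 0.0035, R_av = 0.006, R_tv = 0.0035, R_puv = 0.02,
    # -- aorta --
    C_aa = 0.35, Vu_aa = 60, C_da = 0.75, Vu_da = 150,
    R_da = 0.025, L_da = 0.0022,
    # -- systemic districts: upper body, kidneys, splanchnic, legs --
    Ra_ub = 5.2, Ra_kid = 5.4, Ra_sp = 4.0, Ra_ll = 9.4, Ra_rl = 9.4,
    Rv_ub = 0.35, Rv_kid = 0.40, Rv_sp = 0.28, Rv_ll = 0.35, Rv_rl = 0.35,
    C_ub = 10, C_kid = 3, C_sp = 24, C_ll = 7, C_rl = 7,
    Vu_ub = 380, Vu_kid = 70, Vu_sp = 1500, Vu_ll = 380, Vu_rl = 380,
    k3_ub = 4, k3_kid = 0, k3_sp = 4, k3_ll = 4, k3_rl = 4,
    vn_pressure = 18,
    # -- vena cava --
    C_vc = 32, Vu_vc = 350, k3_vc = 4, R_vc = 0.008,
    # -- pulmonary circulation --
    C_pa_base = 3.2, Vu_pa = 60, R_ap = 0.18,
    C_pv = 7, Vu_pv = 120, R_pv = 0.01,
    cap_thresh = 15, cap_slope = 0.05, cap_floor = 0.5, tau_wedge = 8,
    # -- intrathoracic pressure / breathing mechanics --
    ppl_base = -2.5, k_pl = 3,
    # -- baroreflex --
    Pset = 88, kb = 5, resetting_gain = 1.6,
    g_hr = 0.6, hr_max = 112, hr_min = 45,
    g_es_lv = 0.03, g_es_rv = 1.1, g_r = 0.5, g_vu = 0.15,
    tau_p = 2, tau_hr = 3, tau_sym = 8,
    # -- metabolic peripheral control --
    met_ref_ub = 10, met_ref_kid = 13.5, met_ref_sp = 11,
    met_ref_ll = 10, met_ref_rl = 10,
    met_floor_ub = 0.55, met_floor_kid = 0.9, met_floor_sp = 0.6,
    met_floor_ll = 0.13, met_floor_rl = 0.13,
    met_width = 2.5, tau_met = 15,
    # -- leg muscle pump --
    mp_gain = 5, mp_cadence = 0.9,
    # -- metabolism / gas transport --
    weight = 75, vo2_rest = 3.45,
    hb = 14.5, p50 = 26.6, hill_n = 2.7,
    co2_c0 = 21.5, co2_slope = 0.6625,
    fr_ub = 0.27, fr_kid = 0.17, fr_sp = 0.33, fr_ll = 0.115, fr_rl = 0.115,
    fi_ub = 0.06, fi_kid = 0, fi_sp = 0.03, fi_ll = 0.455, fi_rl = 0.455,
    valv = 2.5, vart = 3, vtis = 2.5, pio2 = 150,
    # -- ventilation control --
    ve0 = 9.2, vco2_ref = 207, k_ff = 0.02908,
    g_co2 = 0.15, paco2_ref = 35, g_o2 = 0.25, pao2_thr = 60,
    f0 = 12, k_f = 0.8, vd = 0.3, tau_ve = 15,
    # -- VAD --
    vad_on = 0, vad_kw = 1.55e-6, vad_kq1 = 0.8, vad_kq2 = 0.003,
    vad_Rc = 0.035, vad_Lc = 0.005, vad_wmin = 6000, vad_wmax = 12000,
    # -- protocol inputs (overwritten phase by phase by the runner) --
    in_vo2_a = 3.45, in_vo2_b = 3.45, in_t0 = 0, in_ramp = 60,
    in_rq_a = 0.8, in_rq_b = 0.8, in_omega = 9500,
    # -- initialisation / diagnostics --
    vol_shift = 40, suction_V = 10
  )
  if (condition == "hf_vad") {
    p[c("hr0", "lv_V0", "lv_a", "lv_b")] <- list(76, 0, 0.01, 0.044)
    p[c("Ra_ub", "Ra_kid", "Ra_sp", "Ra_ll", "Ra_rl")] <-
      list(4.2, 4.3, 3.2, 7.6, 7.6)
    p[c("Rv_ub", "Rv_kid", "Rv_sp", "Rv_ll", "Rv_rl")] <-
      list(0.40, 0.44, 0.33, 0.42, 0.42)
    p$R_ap <- 0.10
    p$Pset <- 91
    p$hr_max <- 115
    p$vad_on <- 1
    # reverse-remodelled ventricle and VAD-population control calibration:
    # the assisted LV keeps some inotropic reserve (it resumes ejecting at
    # peak exercise), the RV response is weaker, venoconstriction and leg
    # vasodilation are stronger at the higher attainable workload
    p$g_es_lv <- 0.46
    p$g_es_rv <- 0.3
    p$resetting_gain <- 1.25
    p$vol_shift <- 0
    p$met_floor_ll <- 0.08
    p$met_floor_rl <- 0.08
    p$met_floor_sp <- 0.5
    p$g_vu <- 0.22
    p$g_r <- 0.8
    p$la_kick <- 0.13
    p$vad_kw <- 1.50e-6
    p$vad_kq1 <- 0.78
  }
  p
}

#' Default exercise protocol of a packaged scenario
#'
#' The heart-failure protocol runs rest to steady state, then ramps oxygen
#' uptake to 11.5 ml/min/kg (cycling at roughly 56 W). The VAD protocol
#' rests at 9500 rpm, ramps to 15.2 ml/min/kg (about 80 W) at 9500 rpm, and
#' finally steps the pump to its 12000 rpm maximum at unchanged workload.
#' The respiratory quotient ramps with workload from its resting value to
#' the peak-exercise value of each condition.
#'
#' @param condition `"hf"` or `"hf_vad"`.
#' @return List of phase definitions (`name`, `vo2` in ml/min/kg, `rq`,
#'   `omega` in rpm or `NA`, `ramp` and `max_dur` in s).
#' @export
scenario_protocol <- function(condition = c("hf", "hf_vad")) {
  condition <- match.arg(condition)
  if (condition == "hf") {
    list(
      list(name = "rest", vo2 = 3.45, rq = 0.8, omega = NA_real_,
           ramp = 0, max_dur = 300),
      list(name = "exercise", vo2 = 11.5, rq = 1.186, omega = NA_real_,
           ramp = 60, max_dur = 600)
    )
  } else {
    list(
      list(name = "rest", vo2 = 3.45, rq = 0.8, omega = 9500,
           ramp = 0, max_dur = 300),
      list(name = "exercise", vo2 = 15.2, rq = 1.23, omega = 9500,
           ramp = 60, max_dur = 600),
      list(name = "exercise_speed_up", vo2 = 15.2, rq = 1.23, omega = 12000,
           ramp = 0, max_dur = 600)
    )
  }
}

#' Assemble a scenario configuration
#'
#' @param condition `"hf"` or `"hf_vad"`.
#' @param params Optional named list of parameter overrides.
#' @param protocol Optional protocol (see [scenario_protocol()]).
#' @return A `cvr_config` object.
#' @export
scenario_config <- function(condition = c("hf", "hf_vad"), params = NULL,
                            protocol = NULL) {
  condition <- match.arg(condition)
  base <- scenario_params(condition)
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(base))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    base[names(params)] <- params
  }
  validate_params(base)
  structure(list(condition = condition, params = base,
                 protocol = if (is.null(protocol)) scenario_protocol(condition)
                            else protocol),
            class = "cvr_config")
}

validate_params <- function(p) {
  pos <- c("hr0", "ks", "lv_Es", "lv_a", "lv_b", "rv_Es", "rv_a", "rv_b",
           "la_C", "ra_C", "R_mv", "R_av", "R_tv", "R_puv",
           "C_aa", "C_da", "R_da", "L_da",
           "Ra_ub", "Ra_kid", "Ra_sp", "Ra_ll", "Ra_rl",
           "Rv_ub", "Rv_kid", "Rv_sp", "Rv_ll", "Rv_rl",
           "C_ub", "C_kid", "C_sp", "C_ll", "C_rl",
           "C_vc", "R_vc", "C_pa_base", "R_ap", "C_pv", "R_pv",
           "Pset", "kb", "tau_p", "tau_hr", "tau_sym",
           "met_ref_ub", "met_ref_kid", "met_ref_sp", "met_ref_ll",
           "met_ref_rl", "met_width", "tau_met",
           "weight", "vo2_rest", "hb", "tau_ve", "valv", "vart", "vtis")
  bad <- pos[vapply(pos, function(nm) !is.numeric(p[[nm]]) ||
                      !is.finite(p[[nm]]) || p[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  floors <- c("met_floor_ub", "met_floor_kid", "met_floor_sp",
              "met_floor_ll", "met_floor_rl")
  badf <- floors[vapply(floors, function(nm) p[[nm]] <= 0 || p[[nm]] > 1,
                        logical(1))]
  if (length(badf)) {
    stop("vasodilation floor(s) must lie in (0, 1]: ",
         paste(badf, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' Load a scenario configuration from a YAML file
#'
#' The file must carry a `condition` field (`hf` or `hf_vad`); any
#' `params` entries override the packaged baseline after key validation
#' (unknown keys are rejected, listing every offending key), and an
#' optional `protocol` section replaces the default phase list.
#'
#' @param path Path to a YAML scenario file.
#' @return A `cvr_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  allowed_top <- c("condition", "params", "protocol", "units", "schema")
  unknown <- setdiff(names(doc), allowed_top)
  if (length(unknown)) {
    stop("unknown top-level key(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(doc$condition)) stop("config must declare a condition", call. = FALSE)
  proto <- NULL
  if (!is.null(doc$protocol)) {
    proto <- lapply(doc$protocol, function(ph) {
      list(name = ph$name %||% "phase",
           vo2 = as.numeric(ph$vo2), rq = as.numeric(ph$rq),
           omega = if (is.null(ph$omega)) NA_real_ else as.numeric(ph$omega),
           ramp = as.numeric(ph$ramp %||% 60),
           max_dur = as.numeric(ph$max_dur %||% 600))
    })
  }
  scenario_config(doc$condition, params = doc$params, protocol = proto)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged scenario fixture path
#'
#' @param condition `"hf"` or `"hf_vad"`.
#' @return Path to the installed YAML fixture.
#' @export
scenario_fixture <- function(condition = c("hf", "hf_vad")) {
  condition <- match.arg(condition)
  system.file("extdata", paste0(condition, ".yaml"), package = "cvrsim",
              mustWork = TRUE)
}

#' Build the resting initial state for a scenario
#'
#' Distributes blood over the compartments at physiologically sensible
#' resting pressures (the closed loop conserves the resulting total volume
#' exactly thereafter; `vol_shift` adds blood to the vena cava to tune the
#' operating point). Blood-gas states start near their resting values.
#'
#' @param params Parameter list from [scenario_params()].
#' @return Named state vector (see [cvr_state_names()]).
#' @export
initial_state <- function(params) {
  p <- params
  pintr <- p$ppl_base - 1.2 # approximate breathing-cycle mean
  pas <- p$Pset + 1
  pra <- 8
  wedge <- 14
  s <- stats::setNames(numeric(length(cvr_state_names())), cvr_state_names())
  s["Vlv"] <- log(max(2, wedge - pintr) / p$lv_a) / p$lv_b
  s["Vrv"] <- log(max(2, pra - pintr) / p$rv_a) / p$rv_b
  s["Vla"] <- p$la_Vu + p$la_C * (wedge - pintr)
  s["Vra"] <- p$ra_Vu + p$ra_C * (pra - pintr)
  s["Vaa"] <- p$Vu_aa + p$C_aa * (pas - pintr)
  s["Vda"] <- p$Vu_da + p$C_da * pas
  s["Vub"] <- p$Vu_ub + p$C_ub * 12
  s["Vkid"] <- p$Vu_kid + p$C_kid * 12
  s["Vsp"] <- p$Vu_sp + p$C_sp * 12
  s["Vll"] <- p$Vu_ll + p$C_ll * 11
  s["Vrl"] <- p$Vu_rl + p$C_rl * 11
  s["Vvc"] <- p$Vu_vc + p$C_vc * (pra + 0.5) + p$vol_shift
  s["Vpa"] <- p$Vu_pa + p$C_pa_base * (24 - pintr)
  s["Vpu"] <- p$Vu_pv + p$C_pv * (wedge + 0.5 - pintr)
  s["Qda"] <- 60
  s["Qvad"] <- 0
  s["theta"] <- 0
  s["hrc"] <- p$hr0
  s["cycle"] <- 0
  s["Pbar"] <- pas
  s["xhr"] <- 0
  s["xsym"] <- 0
  s[c("m_ub", "m_kid", "m_sp", "m_ll", "m_rl")] <- 1
  s["Ve"] <- p$ve0
  s["ph_resp"] <- 0
  s["PAO2"] <- 108
  s["PACO2"] <- 35
  s["CaO2"] <- o2_content(97, p$hb, p$p50, p$hill_n)
  s["CaCO2"] <- co2_content(35, p$co2_c0, p$co2_slope)
  s["CvO2_ub"] <- p$met_ref_ub + 1.5
  s["CvO2_kid"] <- p$met_ref_kid + 1.5
  s["CvO2_sp"] <- p$met_ref_sp + 1.5
  s["CvO2_ll"] <- p$met_ref_ll + 1.5
  s["CvO2_rl"] <- p$met_ref_rl + 1.5
  s[c("CvCO2_ub", "CvCO2_kid", "CvCO2_sp", "CvCO2_ll", "CvCO2_rl")] <-
    s[["CaCO2"]] + 4
  s["Pwb"] <- wedge
  s
}
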