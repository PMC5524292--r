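#' Assemble the full network of model derivatives
#'
#' Reference (pure R) right-hand side of the closed-loop model: cardiac
#' chambers, the systemic and pulmonary vascular network of the simulator
#' (LV -> ascending aorta -> descending aorta -> upper body / kidneys /
#' splanchnic / legs in parallel -> vena cava -> RA -> RV -> pulmonary
#' artery -> pulmonary veins -> LA, with the VAD branch LV -> ascending
#' aorta), the baroreflex and metabolic controls, ventilation and gas
#' transport. Volume bookkeeping is conservative by construction: the
#' compartment volume derivatives sum to zero at any state.
#'
#' This function defines the model semantics; the compiled integrator used
#' by [cvr_simulate()] implements the identical equations and is verified
#' against this reference in the test suite.
#'
#' @param state Named state vector (see [cvr_state_names()]).
#' @param params Parameter list (see [scenario_params()]).
#' @param t Time (s).
#' @return List with `deriv` (named derivative vector) and `derived`
#'   (named vector of algebraic channels: pressures, flows, control and
#'   gas-exchange quantities).
#' @export
network_derivatives <- function(state, params, t = 0) {
  p <- params
  s <- as.list(state)
  if (any(!is.finite(unlist(s)))) {
    stop("non-finite state detected: integration failure at t = ", t,
         call. = FALSE)
  }

  ## ---- protocol inputs ----
  frac <- if (p$in_ramp > 0) min(1, max(0, (t - p$in_t0) / p$in_ramp))
          else as.numeric(t >= p$in_t0)
  vo2_perkg <- p$in_vo2_a + (p$in_vo2_b - p$in_vo2_a) * frac
  rq <- p$in_rq_a + (p$in_rq_b - p$in_rq_a) * frac
  vo2_tot <- vo2_perkg * p$weight
  vo2_base <- p$vo2_rest * p$weight
  vo2_inc <- max(0, vo2_tot - vo2_base)
  delta_vo2 <- max(0, vo2_perkg - p$vo2_rest)

  ## ---- cardiac timing ----
  hr <- s$hrc
  RR <- 60 / hr
  Tsys <- p$ks * sqrt(RR)
  Trel <- p$relax_frac * Tsys
  tc <- (s$theta %% 1) * RR
  vc <- if (tc <= Tsys) sin(pi * tc / (2 * Tsys))^2
        else if (tc <= Tsys + Trel) cos(pi * (tc - Tsys) / (2 * Trel))^2
        else 0
  sk <- p$kick_width / 2
  ea_la <- p$la_kick * exp(-(((s$theta %% 1) - p$kick_center) / sk)^2)
  ea_ra <- p$ra_kick * exp(-(((s$theta %% 1) - p$kick_center) / sk)^2)

  ## ---- ventilation pattern and intrathoracic pressure ----
  f <- p$f0 + p$k_f * max(0, s$Ve - p$ve0)
  Vt <- s$Ve / f
  VA <- max(0.5, s$Ve - f * p$vd)
  Vlung <- Vt / 2 * (1 - cos(2 * pi * s$ph_resp))
  Pintr <- p$ppl_base - p$k_pl * Vlung

  ## ---- control effectors ----
  Pset_eff <- p$Pset + p$resetting_gain * delta_vo2
  es_lv <- max(0.3, 1 + p$g_es_lv * s$xsym)
  es_rv <- max(0.3, 1 + p$g_es_rv * s$xsym)
  r_m <- max(0.4, 1 + p$g_r * s$xsym)
  vu_m <- 1 - p$g_vu * s$xsym

  ## ---- chamber pressures ----
  Plv <- vc * p$lv_Es * es_lv * (s$Vlv - p$lv_V0) +
    (1 - vc) * p$lv_a * exp(p$lv_b * s$Vlv) + Pintr
  Prv <- vc * p$rv_Es * es_rv * (s$Vrv - p$rv_V0) +
    (1 - vc) * p$rv_a * exp(p$rv_b * s$Vrv) + Pintr
  Pla <- (s$Vla - p$la_Vu) / p$la_C + ea_la * (s$Vla - p$la_Vu) + Pintr
  Pra <- (s$Vra - p$ra_Vu) / p$ra_C + ea_ra * (s$Vra - p$ra_Vu) + Pintr

  ## ---- vascular pressures ----
  Paa <- (s$Vaa - p$Vu_aa) / p$C_aa + Pintr
  Pda <- (s$Vda - p$Vu_da) / p$C_da
  amp_mp <- p$mp_gain * delta_vo2
  Pmus_ll <- amp_mp * max(0, sin(2 * pi * p$mp_cadence * t))^2
  Pmus_rl <- amp_mp * max(0, sin(2 * pi * (p$mp_cadence * t + 0.5)))^2
  dist_p <- function(V, C, Vu, k3, P_ext = 0) {
    Vu_eff <- Vu * vu_m
    dv <- V - Vu_eff
    Vn <- C * p$vn_pressure
    dv / C + k3 * (dv / Vn)^3 + P_ext
  }
  Pub <- dist_p(s$Vub, p$C_ub, p$Vu_ub, p$k3_ub)
  Pkid <- dist_p(s$Vkid, p$C_kid, p$Vu_kid, p$k3_kid)
  Psp <- dist_p(s$Vsp, p$C_sp, p$Vu_sp, p$k3_sp)
  Pll <- dist_p(s$Vll, p$C_ll, p$Vu_ll, p$k3_ll, Pmus_ll)
  Prl <- dist_p(s$Vrl, p$C_rl, p$Vu_rl, p$k3_rl, Pmus_rl)
  Pvc <- dist_p(s$Vvc, p$C_vc, p$Vu_vc, p$k3_vc)
  Cap_now <- p$C_pa_base *
    max(p$cap_floor, 1 - p$cap_slope * max(0, s$Pwb - p$cap_thresh))
  Ppa <- (s$Vpa - p$Vu_pa) / Cap_now + Pintr
  Ppu <- (s$Vpu - p$Vu_pv) / p$C_pv + Pintr

  ## ---- flows ----
  Qmv <- max(0, Pla - Plv) / p$R_mv
  Qav <- max(0, Plv - Paa) / p$R_av
  Qtv <- max(0, Pra - Prv) / p$R_tv
  Qpuv <- max(0, Prv - Ppa) / p$R_puv
  q_ub <- (Pda - Pub) / (p$Ra_ub * s$m_ub * r_m)
  q_kid <- (Pda - Pkid) / (p$Ra_kid * s$m_kid * r_m)
  q_sp <- (Pda - Psp) / (p$Ra_sp * s$m_sp * r_m)
  q_ll <- (Pda - Pll) / (p$Ra_ll * s$m_ll * r_m)
  q_rl <- (Pda - Prl) / (p$Ra_rl * s$m_rl * r_m)
  qo_ub <- (Pub - Pvc) / p$Rv_ub
  qo_kid <- (Pkid - Pvc) / p$Rv_kid
  qo_sp <- (Psp - Pvc) / p$Rv_sp
  qo_ll <- max(0, (Pll - max(Pvc, Pmus_ll)) / p$Rv_ll)
  qo_rl <- max(0, (Prl - max(Pvc, Pmus_rl)) / p$Rv_rl)
  Qvcra <- (Pvc - Pra) / p$R_vc
  Qrap <- (Ppa - Ppu) / p$R_ap
  Qpv <- (Ppu - Pla) / p$R_pv

  ## ---- VAD ----
  if (p$vad_on > 0) {
    H <- p$vad_kw * p$in_omega^2 - p$vad_kq1 * s$Qvad -
      p$vad_kq2 * s$Qvad * abs(s$Qvad)
    dQvad <- (Plv - Paa + H - p$vad_Rc * s$Qvad) / p$vad_Lc
    Qvad <- s$Qvad
  } else {
    H <- 0; dQvad <- 0; Qvad <- 0
  }

  ## ---- gas exchange ----
  qp <- max(0, Qrap)
  CcO2 <- o2_content(s$PAO2, p$hb, p$p50, p$hill_n)
  CcCO2 <- co2_content(s$PACO2, p$co2_c0, p$co2_slope)
  qo_pos <- pmax(0, c(qo_ub, qo_kid, qo_sp, qo_ll, qo_rl))
  wsum <- sum(qo_pos)
  cv_o2 <- c(s$CvO2_ub, s$CvO2_kid, s$CvO2_sp, s$CvO2_ll, s$CvO2_rl)
  cv_co2 <- c(s$CvCO2_ub, s$CvCO2_kid, s$CvCO2_sp, s$CvCO2_ll, s$CvCO2_rl)
  if (wsum > 1e-9) {
    CmixO2 <- sum(qo_pos * cv_o2) / wsum
    CmixCO2 <- sum(qo_pos * cv_co2) / wsum
  } else {
    CmixO2 <- mean(cv_o2)
    CmixCO2 <- mean(cv_co2)
  }
  VO2_lung <- qp * 0.6 * (CcO2 - CmixO2)
  VCO2_lung <- qp * 0.6 * (CmixCO2 - CcCO2)
  dPAO2 <- (VA * (p$pio2 - s$PAO2) - 0.863 * VO2_lung) / (p$valv * 60)
  dPACO2 <- (0.863 * VCO2_lung - VA * s$PACO2) / (p$valv * 60)
  dCaO2 <- 0.01 * qp * (CcO2 - s$CaO2) / p$vart
  dCaCO2 <- 0.01 * qp * (CcCO2 - s$CaCO2) / p$vart
  vo2_i <- c(p$fr_ub, p$fr_kid, p$fr_sp, p$fr_ll, p$fr_rl) * vo2_base +
    c(p$fi_ub, p$fi_kid, p$fi_sp, p$fi_ll, p$fi_rl) * vo2_inc
  qin_pos <- pmax(0, c(q_ub, q_kid, q_sp, q_ll, q_rl))
  dCvO2 <- (0.01 * qin_pos * (s$CaO2 - cv_o2) - vo2_i / 60) / p$vtis
  dCvCO2 <- (rq * vo2_i / 60 - 0.01 * qin_pos * (cv_co2 - s$CaCO2)) / p$vtis

  ## ---- ventilation control ----
  vco2_ff <- rq * vo2_tot
  PaCO2 <- co2_partial_pressure(s$CaCO2, p$co2_c0, p$co2_slope)
  Ve_cmd <- max(2, p$ve0 + p$k_ff * (vco2_ff - p$vco2_ref) +
                  p$g_co2 * (PaCO2 - p$paco2_ref) +
                  p$g_o2 * max(0, p$pao2_thr - s$PAO2))
  dVe <- (Ve_cmd - s$Ve) / p$tau_ve

  ## ---- baroreflex dynamics ----
  sigma <- tanh((Pset_eff - s$Pbar) / p$kb)
  dPbar <- (Paa - s$Pbar) / p$tau_p
  dxhr <- (sigma - s$xhr) / p$tau_hr
  dxsym <- (sigma - s$xsym) / p$tau_sym

  ## ---- metabolic control dynamics ----
  floors <- c(p$met_floor_ub, p$met_floor_kid, p$met_floor_sp,
              p$met_floor_ll, p$met_floor_rl)
  refs <- c(p$met_ref_ub, p$met_ref_kid, p$met_ref_sp,
            p$met_ref_ll, p$met_ref_rl)
  m_now <- c(s$m_ub, s$m_kid, s$m_sp, s$m_ll, s$m_rl)
  m_stat <- floors + (1 - floors) *
    exp(-(pmax(0, refs - cv_o2) / p$met_width)^2)
  dm <- (m_stat - m_now) / p$tau_met

  deriv <- stats::setNames(numeric(length(cvr_state_names())),
                           cvr_state_names())
  deriv["Vlv"] <- Qmv - Qav - Qvad
  deriv["Vrv"] <- Qtv - Qpuv
  deriv["Vla"] <- Qpv - Qmv
  deriv["Vra"] <- Qvcra - Qtv
  deriv["Vaa"] <- Qav + Qvad - s$Qda
  deriv["Vda"] <- s$Qda - (q_ub + q_kid + q_sp + q_ll + q_rl)
  deriv["Vub"] <- q_ub - qo_ub
  deriv["Vkid"] <- q_kid - qo_kid
  deriv["Vsp"] <- q_sp - qo_sp
  deriv["Vll"] <- q_ll - qo_ll
  deriv["Vrl"] <- q_rl - qo_rl
  deriv["Vvc"] <- qo_ub + qo_kid + qo_sp + qo_ll + qo_rl - Qvcra
  deriv["Vpa"] <- Qpuv - Qrap
  deriv["Vpu"] <- Qrap - Qpv
  deriv["Qda"] <- (Paa - Pda - p$R_da * s$Qda) / p$L_da
  deriv["Qvad"] <- dQvad
  deriv["theta"] <- hr / 60
  deriv["hrc"] <- 0
  deriv["cycle"] <- 0
  deriv["Pbar"] <- dPbar
  deriv["xhr"] <- dxhr
  deriv["xsym"] <- dxsym
  deriv[c("m_ub", "m_kid", "m_sp", "m_ll", "m_rl")] <- dm
  deriv["Ve"] <- dVe
  deriv["ph_resp"] <- f / 60
  deriv["PAO2"] <- dPAO2
  deriv["PACO2"] <- dPACO2
  deriv["CaO2"] <- dCaO2
  deriv["CaCO2"] <- dCaCO2
  deriv[c("CvO2_ub", "CvO2_kid", "CvO2_sp", "CvO2_ll", "CvO2_rl")] <- dCvO2
  deriv[c("CvCO2_ub", "CvCO2_kid", "CvCO2_sp", "CvCO2_ll", "CvCO2_rl")] <-
    dCvCO2
  deriv["Pwb"] <- (Pla - s$Pwb) / p$tau_wedge

  derived <- c(Plv = Plv, Prv = Prv, Pla = Pla, Pra = Pra, Paa = Paa,
               Pda = Pda, Pub = Pub, Pkid = Pkid, Psp = Psp, Pll = Pll,
               Prl = Prl, Pvc = Pvc, Ppa = Ppa, Ppu = Ppu,
               Qav = Qav, Qmv = Qmv, Qtv = Qtv, Qpuv = Qpuv,
               Qrap = Qrap, Qpv = Qpv, Qvad_d = Qvad,
               HR = hr, vc = vc, Pintr = Pintr,
               VO2_dem = vo2_tot, VCO2_ff = vco2_ff,
               avO2 = s$CaO2 - CmixO2, PaCO2 = PaCO2, f_resp = f,
               Pset_eff = Pset_eff, Pmus_ll = Pmus_ll, Pmus_rl = Pmus_rl,
               CmixO2 = CmixO2, Cap = Cap_now, H_vad = H,
               Ve_cmd = Ve_cmd)
  list(deriv = deriv, derived = derived)
}

#' Derived-channel names reported by the integrator
#' @return Character vector of derived output channel names.
#' @export
cvr_derived_names <- function() {
  c("Plv", "Prv", "Pla", "Pra", "Paa", "Pda", "Pub", "Pkid", "Psp", "Pll",
    "Prl", "Pvc", "Ppa", "Ppu", "Qav", "Qmv", "Qtv", "Qpuv", "Qrap", "Qpv",
    "Qvad_d", "HR", "vc", "Pintr", "VO2_dem", "VCO2_ff", "avO2", "PaCO2",
    "f_resp", "Pset_eff", "Pmus_ll", "Pmus_rl", "CmixO2", "Cap", "H_vad",
    "Ve_cmd")
}
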