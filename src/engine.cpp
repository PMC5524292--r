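// Fixed-step RK4 integrator for the closed-loop cardiorespiratory model.
// The equations here mirror the R reference implementation in
// R/derivatives.R (network_derivatives) exactly; the test suite checks the
// two against each other. Heart rate is sampled from the baroreflex at the
// start of each cardiac cycle and held constant within it, so cycles are
// well-defined for averaging even while the controls move.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const int NS = 44;   // number of states
static const int ND = 36;   // number of derived channels

// state indices
enum {
  iVlv, iVrv, iVla, iVra, iVaa, iVda, iVub, iVkid, iVsp, iVll, iVrl,
  iVvc, iVpa, iVpu, iQda, iQvad, iTheta, iHrc, iCycle, iPbar, iXhr,
  iXsym, iMub, iMkid, iMsp, iMll, iMrl, iVe, iPhResp, iPAO2, iPACO2,
  iCaO2, iCaCO2, iCvO2ub, iCvO2kid, iCvO2sp, iCvO2ll, iCvO2rl,
  iCvCO2ub, iCvCO2kid, iCvCO2sp, iCvCO2ll, iCvCO2rl, iPwb
};

struct Pars {
  double hr0, ks, relax_frac;
  double lv_Es, lv_V0, lv_a, lv_b;
  double rv_Es, rv_V0, rv_a, rv_b;
  double la_C, la_Vu, la_kick, ra_C, ra_Vu, ra_kick, kick_center, kick_width;
  double R_mv, R_av, R_tv, R_puv;
  double C_aa, Vu_aa, C_da, Vu_da, R_da, L_da;
  double Ra[5], Rv[5], C[5], Vu[5], k3[5];
  double vn_pressure;
  double C_vc, Vu_vc, k3_vc, R_vc;
  double C_pa_base, Vu_pa, R_ap, C_pv, Vu_pv, R_pv;
  double cap_thresh, cap_slope, cap_floor, tau_wedge;
  double ppl_base, k_pl;
  double Pset, kb, resetting_gain, g_hr, hr_max, hr_min, g_es_lv, g_es_rv, g_r, g_vu;
  double tau_p, tau_hr, tau_sym;
  double met_ref[5], met_floor[5], met_width, tau_met;
  double mp_gain, mp_cadence;
  double weight, vo2_rest, hb, p50, hill_n, co2_c0, co2_slope;
  double fr[5], fi[5];
  double valv, vart, vtis, pio2;
  double ve0, vco2_ref, k_ff, g_co2, paco2_ref, g_o2, pao2_thr;
  double f0, k_f, vd, tau_ve;
  double vad_on, vad_kw, vad_kq1, vad_kq2, vad_Rc, vad_Lc;
  double in_vo2_a, in_vo2_b, in_t0, in_ramp, in_rq_a, in_rq_b, in_omega;
  double suction_V;
};

static double gp(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop("missing parameter: %s", nm);
  return as<double>(l[nm]);
}

static void fill_pars(const List& l, Pars& p) {
  p.hr0 = gp(l, "hr0"); p.ks = gp(l, "ks"); p.relax_frac = gp(l, "relax_frac");
  p.lv_Es = gp(l, "lv_Es"); p.lv_V0 = gp(l, "lv_V0");
  p.lv_a = gp(l, "lv_a"); p.lv_b = gp(l, "lv_b");
  p.rv_Es = gp(l, "rv_Es"); p.rv_V0 = gp(l, "rv_V0");
  p.rv_a = gp(l, "rv_a"); p.rv_b = gp(l, "rv_b");
  p.la_C = gp(l, "la_C"); p.la_Vu = gp(l, "la_Vu"); p.la_kick = gp(l, "la_kick");
  p.ra_C = gp(l, "ra_C"); p.ra_Vu = gp(l, "ra_Vu"); p.ra_kick = gp(l, "ra_kick");
  p.kick_center = gp(l, "kick_center"); p.kick_width = gp(l, "kick_width");
  p.R_mv = gp(l, "R_mv"); p.R_av = gp(l, "R_av");
  p.R_tv = gp(l, "R_tv"); p.R_puv = gp(l, "R_puv");
  p.C_aa = gp(l, "C_aa"); p.Vu_aa = gp(l, "Vu_aa");
  p.C_da = gp(l, "C_da"); p.Vu_da = gp(l, "Vu_da");
  p.R_da = gp(l, "R_da"); p.L_da = gp(l, "L_da");
  const char* reg[5] = {"ub", "kid", "sp", "ll", "rl"};
  char buf[32];
  for (int i = 0; i < 5; i++) {
    snprintf(buf, 32, "Ra_%s", reg[i]); p.Ra[i] = gp(l, buf);
    snprintf(buf, 32, "Rv_%s", reg[i]); p.Rv[i] = gp(l, buf);
    snprintf(buf, 32, "C_%s", reg[i]); p.C[i] = gp(l, buf);
    snprintf(buf, 32, "Vu_%s", reg[i]); p.Vu[i] = gp(l, buf);
    snprintf(buf, 32, "k3_%s", reg[i]); p.k3[i] = gp(l, buf);
    snprintf(buf, 32, "met_ref_%s", reg[i]); p.met_ref[i] = gp(l, buf);
    snprintf(buf, 32, "met_floor_%s", reg[i]); p.met_floor[i] = gp(l, buf);
    snprintf(buf, 32, "fr_%s", reg[i]); p.fr[i] = gp(l, buf);
    snprintf(buf, 32, "fi_%s", reg[i]); p.fi[i] = gp(l, buf);
  }
  p.vn_pressure = gp(l, "vn_pressure");
  p.C_vc = gp(l, "C_vc"); p.Vu_vc = gp(l, "Vu_vc");
  p.k3_vc = gp(l, "k3_vc"); p.R_vc = gp(l, "R_vc");
  p.C_pa_base = gp(l, "C_pa_base"); p.Vu_pa = gp(l, "Vu_pa");
  p.R_ap = gp(l, "R_ap"); p.C_pv = gp(l, "C_pv");
  p.Vu_pv = gp(l, "Vu_pv"); p.R_pv = gp(l, "R_pv");
  p.cap_thresh = gp(l, "cap_thresh"); p.cap_slope = gp(l, "cap_slope");
  p.cap_floor = gp(l, "cap_floor"); p.tau_wedge = gp(l, "tau_wedge");
  p.ppl_base = gp(l, "ppl_base"); p.k_pl = gp(l, "k_pl");
  p.Pset = gp(l, "Pset"); p.kb = gp(l, "kb");
  p.resetting_gain = gp(l, "resetting_gain");
  p.g_hr = gp(l, "g_hr"); p.hr_max = gp(l, "hr_max"); p.hr_min = gp(l, "hr_min");
  p.g_es_lv = gp(l, "g_es_lv"); p.g_es_rv = gp(l, "g_es_rv"); p.g_r = gp(l, "g_r"); p.g_vu = gp(l, "g_vu");
  p.tau_p = gp(l, "tau_p"); p.tau_hr = gp(l, "tau_hr"); p.tau_sym = gp(l, "tau_sym");
  p.met_width = gp(l, "met_width"); p.tau_met = gp(l, "tau_met");
  p.mp_gain = gp(l, "mp_gain"); p.mp_cadence = gp(l, "mp_cadence");
  p.weight = gp(l, "weight"); p.vo2_rest = gp(l, "vo2_rest");
  p.hb = gp(l, "hb"); p.p50 = gp(l, "p50"); p.hill_n = gp(l, "hill_n");
  p.co2_c0 = gp(l, "co2_c0"); p.co2_slope = gp(l, "co2_slope");
  p.valv = gp(l, "valv"); p.vart = gp(l, "vart"); p.vtis = gp(l, "vtis");
  p.pio2 = gp(l, "pio2");
  p.ve0 = gp(l, "ve0"); p.vco2_ref = gp(l, "vco2_ref"); p.k_ff = gp(l, "k_ff");
  p.g_co2 = gp(l, "g_co2"); p.paco2_ref = gp(l, "paco2_ref");
  p.g_o2 = gp(l, "g_o2"); p.pao2_thr = gp(l, "pao2_thr");
  p.f0 = gp(l, "f0"); p.k_f = gp(l, "k_f"); p.vd = gp(l, "vd");
  p.tau_ve = gp(l, "tau_ve");
  p.vad_on = gp(l, "vad_on"); p.vad_kw = gp(l, "vad_kw");
  p.vad_kq1 = gp(l, "vad_kq1"); p.vad_kq2 = gp(l, "vad_kq2");
  p.vad_Rc = gp(l, "vad_Rc"); p.vad_Lc = gp(l, "vad_Lc");
  p.in_vo2_a = gp(l, "in_vo2_a"); p.in_vo2_b = gp(l, "in_vo2_b");
  p.in_t0 = gp(l, "in_t0"); p.in_ramp = gp(l, "in_ramp");
  p.in_rq_a = gp(l, "in_rq_a"); p.in_rq_b = gp(l, "in_rq_b");
  p.in_omega = gp(l, "in_omega");
  p.suction_V = gp(l, "suction_V");
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}
static inline double pos(double x) { return x > 0 ? x : 0; }

static void rhs(double t, const double* y, const Pars& p,
                double* dy, double* drv) {
  // protocol inputs
  double frac = (p.in_ramp > 0)
    ? clampd((t - p.in_t0) / p.in_ramp, 0.0, 1.0)
    : (t >= p.in_t0 ? 1.0 : 0.0);
  double vo2_perkg = p.in_vo2_a + (p.in_vo2_b - p.in_vo2_a) * frac;
  double rq = p.in_rq_a + (p.in_rq_b - p.in_rq_a) * frac;
  double vo2_tot = vo2_perkg * p.weight;
  double vo2_base = p.vo2_rest * p.weight;
  double vo2_inc = pos(vo2_tot - vo2_base);
  double delta_vo2 = pos(vo2_perkg - p.vo2_rest);

  // cardiac timing
  double hr = y[iHrc];
  double RR = 60.0 / hr;
  double Tsys = p.ks * std::sqrt(RR);
  double Trel = p.relax_frac * Tsys;
  double th = y[iTheta] - std::floor(y[iTheta]); // phase wrapped to [0, 1)
  double tc = th * RR;
  double vcf;
  if (tc <= Tsys) {
    double sn = std::sin(M_PI * tc / (2.0 * Tsys)); vcf = sn * sn;
  } else if (tc <= Tsys + Trel) {
    double cs = std::cos(M_PI * (tc - Tsys) / (2.0 * Trel)); vcf = cs * cs;
  } else vcf = 0.0;
  double sk = p.kick_width / 2.0;
  double gk = std::exp(-std::pow((th - p.kick_center) / sk, 2.0));
  double ea_la = p.la_kick * gk;
  double ea_ra = p.ra_kick * gk;

  // ventilation pattern and intrathoracic pressure
  double f = p.f0 + p.k_f * pos(y[iVe] - p.ve0);
  double Vt = y[iVe] / f;
  double VA = y[iVe] - f * p.vd; if (VA < 0.5) VA = 0.5;
  double Vlung = Vt / 2.0 * (1.0 - std::cos(2.0 * M_PI * y[iPhResp]));
  double Pintr = p.ppl_base - p.k_pl * Vlung;

  // control effectors
  double Pset_eff = p.Pset + p.resetting_gain * delta_vo2;
  double es_lv = 1.0 + p.g_es_lv * y[iXsym]; if (es_lv < 0.3) es_lv = 0.3;
  double es_rv = 1.0 + p.g_es_rv * y[iXsym]; if (es_rv < 0.3) es_rv = 0.3;
  double r_m = 1.0 + p.g_r * y[iXsym]; if (r_m < 0.4) r_m = 0.4;
  double vu_m = 1.0 - p.g_vu * y[iXsym];

  // chamber pressures
  double Plv = vcf * p.lv_Es * es_lv * (y[iVlv] - p.lv_V0)
    + (1.0 - vcf) * p.lv_a * std::exp(p.lv_b * y[iVlv]) + Pintr;
  double Prv = vcf * p.rv_Es * es_rv * (y[iVrv] - p.rv_V0)
    + (1.0 - vcf) * p.rv_a * std::exp(p.rv_b * y[iVrv]) + Pintr;
  double Pla = (y[iVla] - p.la_Vu) / p.la_C
    + ea_la * (y[iVla] - p.la_Vu) + Pintr;
  double Pra = (y[iVra] - p.ra_Vu) / p.ra_C
    + ea_ra * (y[iVra] - p.ra_Vu) + Pintr;

  // vascular pressures
  double Paa = (y[iVaa] - p.Vu_aa) / p.C_aa + Pintr;
  double Pda = (y[iVda] - p.Vu_da) / p.C_da;
  double amp_mp = p.mp_gain * delta_vo2;
  double sl = std::sin(2.0 * M_PI * p.mp_cadence * t);
  double sr = std::sin(2.0 * M_PI * (p.mp_cadence * t + 0.5));
  double Pmus_ll = amp_mp * pos(sl) * pos(sl);
  double Pmus_rl = amp_mp * pos(sr) * pos(sr);
  double Pd[5], Pext[5] = {0, 0, 0, Pmus_ll, Pmus_rl};
  const double Vdist[5] = {y[iVub], y[iVkid], y[iVsp], y[iVll], y[iVrl]};
  for (int i = 0; i < 5; i++) {
    double Vu_eff = p.Vu[i] * vu_m;
    double dv = Vdist[i] - Vu_eff;
    double Vn = p.C[i] * p.vn_pressure;
    Pd[i] = dv / p.C[i] + p.k3[i] * std::pow(dv / Vn, 3.0) + Pext[i];
  }
  double Vu_vc_eff = p.Vu_vc * vu_m;
  double dvvc = y[iVvc] - Vu_vc_eff;
  double Vn_vc = p.C_vc * p.vn_pressure;
  double Pvc = dvvc / p.C_vc + p.k3_vc * std::pow(dvvc / Vn_vc, 3.0);
  double cap_f = 1.0 - p.cap_slope * pos(y[iPwb] - p.cap_thresh);
  if (cap_f < p.cap_floor) cap_f = p.cap_floor;
  double Cap_now = p.C_pa_base * cap_f;
  double Ppa = (y[iVpa] - p.Vu_pa) / Cap_now + Pintr;
  double Ppu = (y[iVpu] - p.Vu_pv) / p.C_pv + Pintr;

  // flows
  double Qmv = pos(Pla - Plv) / p.R_mv;
  double Qav = pos(Plv - Paa) / p.R_av;
  double Qtv = pos(Pra - Prv) / p.R_tv;
  double Qpuv = pos(Prv - Ppa) / p.R_puv;
  double qin[5], qout[5];
  for (int i = 0; i < 5; i++) {
    double m = (i == 0 ? y[iMub] : i == 1 ? y[iMkid] : i == 2 ? y[iMsp]
                : i == 3 ? y[iMll] : y[iMrl]);
    qin[i] = (Pda - Pd[i]) / (p.Ra[i] * m * r_m);
  }
  qout[0] = (Pd[0] - Pvc) / p.Rv[0];
  qout[1] = (Pd[1] - Pvc) / p.Rv[1];
  qout[2] = (Pd[2] - Pvc) / p.Rv[2];
  double dsl = Pvc > Pmus_ll ? Pvc : Pmus_ll;
  double dsr = Pvc > Pmus_rl ? Pvc : Pmus_rl;
  qout[3] = pos((Pd[3] - dsl) / p.Rv[3]);
  qout[4] = pos((Pd[4] - dsr) / p.Rv[4]);
  double Qvcra = (Pvc - Pra) / p.R_vc;
  double Qrap = (Ppa - Ppu) / p.R_ap;
  double Qpv = (Ppu - Pla) / p.R_pv;

  // VAD
  double Qvad, dQvad, H;
  if (p.vad_on > 0) {
    Qvad = y[iQvad];
    H = p.vad_kw * p.in_omega * p.in_omega - p.vad_kq1 * Qvad
      - p.vad_kq2 * Qvad * std::fabs(Qvad);
    dQvad = (Plv - Paa + H - p.vad_Rc * Qvad) / p.vad_Lc;
  } else { Qvad = 0.0; dQvad = 0.0; H = 0.0; }

  // gas exchange
  double qp = pos(Qrap);
  double pn = std::pow(y[iPAO2], p.hill_n);
  double sat = pn / (pn + std::pow(p.p50, p.hill_n));
  double CcO2 = 1.34 * p.hb * sat + 0.003 * y[iPAO2];
  double CcCO2 = p.co2_c0 + p.co2_slope * y[iPACO2];
  const double cv_o2[5] = {y[iCvO2ub], y[iCvO2kid], y[iCvO2sp],
                           y[iCvO2ll], y[iCvO2rl]};
  const double cv_co2[5] = {y[iCvCO2ub], y[iCvCO2kid], y[iCvCO2sp],
                            y[iCvCO2ll], y[iCvCO2rl]};
  double wsum = 0.0, so2 = 0.0, sco2 = 0.0;
  for (int i = 0; i < 5; i++) {
    double w = pos(qout[i]);
    wsum += w; so2 += w * cv_o2[i]; sco2 += w * cv_co2[i];
  }
  double CmixO2, CmixCO2;
  if (wsum > 1e-9) { CmixO2 = so2 / wsum; CmixCO2 = sco2 / wsum; }
  else {
    CmixO2 = (cv_o2[0] + cv_o2[1] + cv_o2[2] + cv_o2[3] + cv_o2[4]) / 5.0;
    CmixCO2 = (cv_co2[0] + cv_co2[1] + cv_co2[2] + cv_co2[3] + cv_co2[4]) / 5.0;
  }
  double VO2_lung = qp * 0.6 * (CcO2 - CmixO2);
  double VCO2_lung = qp * 0.6 * (CmixCO2 - CcCO2);
  double dPAO2 = (VA * (p.pio2 - y[iPAO2]) - 0.863 * VO2_lung) / (p.valv * 60.0);
  double dPACO2 = (0.863 * VCO2_lung - VA * y[iPACO2]) / (p.valv * 60.0);
  double dCaO2 = 0.01 * qp * (CcO2 - y[iCaO2]) / p.vart;
  double dCaCO2 = 0.01 * qp * (CcCO2 - y[iCaCO2]) / p.vart;
  double vo2_i[5], dCvO2[5], dCvCO2[5];
  for (int i = 0; i < 5; i++) {
    vo2_i[i] = p.fr[i] * vo2_base + p.fi[i] * vo2_inc;
    double qi = pos(qin[i]);
    dCvO2[i] = (0.01 * qi * (y[iCaO2] - cv_o2[i]) - vo2_i[i] / 60.0) / p.vtis;
    dCvCO2[i] = (rq * vo2_i[i] / 60.0 - 0.01 * qi * (cv_co2[i] - y[iCaCO2]))
      / p.vtis;
  }

  // ventilation control
  double vco2_ff = rq * vo2_tot;
  double PaCO2 = (y[iCaCO2] - p.co2_c0) / p.co2_slope;
  double Ve_cmd = p.ve0 + p.k_ff * (vco2_ff - p.vco2_ref)
    + p.g_co2 * (PaCO2 - p.paco2_ref)
    + p.g_o2 * pos(p.pao2_thr - y[iPAO2]);
  if (Ve_cmd < 2.0) Ve_cmd = 2.0;
  double dVe = (Ve_cmd - y[iVe]) / p.tau_ve;

  // baroreflex
  double sigma = std::tanh((Pset_eff - y[iPbar]) / p.kb);

  // metabolic control
  double dm[5];
  for (int i = 0; i < 5; i++) {
    double deficit = pos(p.met_ref[i] - cv_o2[i]);
    double m_stat = p.met_floor[i] + (1.0 - p.met_floor[i])
      * std::exp(-std::pow(deficit / p.met_width, 2.0));
    double m_now = (i == 0 ? y[iMub] : i == 1 ? y[iMkid] : i == 2 ? y[iMsp]
                    : i == 3 ? y[iMll] : y[iMrl]);
    dm[i] = (m_stat - m_now) / p.tau_met;
  }

  dy[iVlv] = Qmv - Qav - Qvad;
  dy[iVrv] = Qtv - Qpuv;
  dy[iVla] = Qpv - Qmv;
  dy[iVra] = Qvcra - Qtv;
  dy[iVaa] = Qav + Qvad - y[iQda];
  dy[iVda] = y[iQda] - (qin[0] + qin[1] + qin[2] + qin[3] + qin[4]);
  dy[iVub] = qin[0] - qout[0];
  dy[iVkid] = qin[1] - qout[1];
  dy[iVsp] = qin[2] - qout[2];
  dy[iVll] = qin[3] - qout[3];
  dy[iVrl] = qin[4] - qout[4];
  dy[iVvc] = qout[0] + qout[1] + qout[2] + qout[3] + qout[4] - Qvcra;
  dy[iVpa] = Qpuv - Qrap;
  dy[iVpu] = Qrap - Qpv;
  dy[iQda] = (Paa - Pda - p.R_da * y[iQda]) / p.L_da;
  dy[iQvad] = dQvad;
  dy[iTheta] = hr / 60.0;
  dy[iHrc] = 0.0;
  dy[iCycle] = 0.0;
  dy[iPbar] = (Paa - y[iPbar]) / p.tau_p;
  dy[iXhr] = (sigma - y[iXhr]) / p.tau_hr;
  dy[iXsym] = (sigma - y[iXsym]) / p.tau_sym;
  dy[iMub] = dm[0]; dy[iMkid] = dm[1]; dy[iMsp] = dm[2];
  dy[iMll] = dm[3]; dy[iMrl] = dm[4];
  dy[iVe] = dVe;
  dy[iPhResp] = f / 60.0;
  dy[iPAO2] = dPAO2;
  dy[iPACO2] = dPACO2;
  dy[iCaO2] = dCaO2;
  dy[iCaCO2] = dCaCO2;
  dy[iCvO2ub] = dCvO2[0]; dy[iCvO2kid] = dCvO2[1]; dy[iCvO2sp] = dCvO2[2];
  dy[iCvO2ll] = dCvO2[3]; dy[iCvO2rl] = dCvO2[4];
  dy[iCvCO2ub] = dCvCO2[0]; dy[iCvCO2kid] = dCvCO2[1]; dy[iCvCO2sp] = dCvCO2[2];
  dy[iCvCO2ll] = dCvCO2[3]; dy[iCvCO2rl] = dCvCO2[4];
  dy[iPwb] = (Pla - y[iPwb]) / p.tau_wedge;

  if (drv) {
    drv[0] = Plv; drv[1] = Prv; drv[2] = Pla; drv[3] = Pra; drv[4] = Paa;
    drv[5] = Pda; drv[6] = Pd[0]; drv[7] = Pd[1]; drv[8] = Pd[2];
    drv[9] = Pd[3]; drv[10] = Pd[4]; drv[11] = Pvc; drv[12] = Ppa;
    drv[13] = Ppu; drv[14] = Qav; drv[15] = Qmv; drv[16] = Qtv;
    drv[17] = Qpuv; drv[18] = Qrap; drv[19] = Qpv; drv[20] = Qvad;
    drv[21] = hr; drv[22] = vcf; drv[23] = Pintr; drv[24] = vo2_tot;
    drv[25] = vco2_ff; drv[26] = y[iCaO2] - CmixO2; drv[27] = PaCO2;
    drv[28] = f; drv[29] = Pset_eff; drv[30] = Pmus_ll; drv[31] = Pmus_rl;
    drv[32] = CmixO2; drv[33] = Cap_now; drv[34] = H; drv[35] = Ve_cmd;
  }
}

// [[Rcpp::export]]
List engine_rhs(double t, NumericVector state, List params) {
  if (state.size() != NS) stop("state must have %d elements", NS);
  Pars p; fill_pars(params, p);
  NumericVector dy(NS), drv(ND);
  rhs(t, REAL(state), p, REAL(dy), REAL(drv));
  return List::create(_["deriv"] = dy, _["derived"] = drv);
}

// [[Rcpp::export]]
List engine_run(NumericVector state0, List params, double t0,
                double duration, double dt, double dt_out) {
  if (state0.size() != NS) stop("state must have %d elements", NS);
  if (dt <= 0 || dt_out < dt) stop("need dt > 0 and dt_out >= dt");
  Pars p; fill_pars(params, p);

  const long m = (long)std::llround(dt_out / dt);
  const long nstep = (long)std::llround(duration / dt);
  const long nrow = nstep / m + 1;
  NumericMatrix out(nrow, 1 + NS + ND);

  double y[NS], k1[NS], k2[NS], k3[NS], k4[NS], tmp[NS], drv[ND];
  std::memcpy(y, REAL(state0), NS * sizeof(double));
  double t = t0;
  long row = 0;
  long n_suction = 0, n_o2clamp = 0;

  for (long step = 0; step <= nstep; step++) {
    if (step % m == 0) {
      rhs(t, y, p, k1, drv);
      out(row, 0) = t;
      for (int i = 0; i < NS; i++) out(row, 1 + i) = y[i];
      for (int i = 0; i < ND; i++) out(row, 1 + NS + i) = drv[i];
      row++;
    }
    if (step == nstep) break;

    rhs(t, y, p, k1, 0);
    for (int i = 0; i < NS; i++) tmp[i] = y[i] + 0.5 * dt * k1[i];
    rhs(t + 0.5 * dt, tmp, p, k2, 0);
    for (int i = 0; i < NS; i++) tmp[i] = y[i] + 0.5 * dt * k2[i];
    rhs(t + 0.5 * dt, tmp, p, k3, 0);
    for (int i = 0; i < NS; i++) tmp[i] = y[i] + dt * k3[i];
    rhs(t + dt, tmp, p, k4, 0);
    for (int i = 0; i < NS; i++)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t = t0 + (step + 1) * dt;

    // cycle wrap: sample the commanded heart rate for the new cycle
    if (y[iTheta] >= 1.0) {
      y[iTheta] -= 1.0;
      y[iCycle] += 1.0;
      double cmd = p.hr0 * (1.0 + p.g_hr * y[iXhr]);
      y[iHrc] = clampd(cmd, p.hr_min, p.hr_max);
    }
    // venous O2 floors at zero (supply limitation)
    for (int i = iCvO2ub; i <= iCvO2rl; i++) {
      if (y[i] < 0.0) { y[i] = 0.0; n_o2clamp++; }
    }
    if (y[iVlv] < p.suction_V) n_suction++;

    if ((step & 0x3FFF) == 0) {
      if (!std::isfinite(y[iVlv]) || !std::isfinite(y[iVaa])
          || !std::isfinite(y[iCaO2])) {
        stop("integration failure: non-finite state at t = %f", t);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < NS; i++) {
    if (!std::isfinite(y[i]))
      stop("integration failure: non-finite state component %d", i + 1);
  }

  NumericVector fin(NS);
  std::memcpy(REAL(fin), y, NS * sizeof(double));
  return List::create(
    _["out"] = out, _["final_state"] = fin, _["final_time"] = t,
    _["n_suction"] = (double)n_suction, _["n_o2_clamp"] = (double)n_o2clamp);
}
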