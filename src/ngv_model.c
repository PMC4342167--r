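/* Compiled right-hand side of the 33-state neuron-glia-vasculature model,
 * used through deSolve's compiled-code interface. The parameter vector is
 * assembled in R (see .build_parms) in the exact order of the enum below:
 * model parameters, then scenario scalars, then the 33-entry clamp mask.
 * An independent R transcription of the same equations lives in R/fluxes.R
 * and is compared against this code in the test suite.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* parameter indices (0-based) */
enum {
  iV_e, iV_cap, iV_g, iV_n, ixi, iSmVn, iSmVg, iRTF, iFaraday, ipsi_g, iNa_e,
  iKt_GLC_en, iKt_GLC_eg, iKt_GLC_cg, iKt_GLC_ce,
  iKt_LAC_ne, iKt_LAC_ge, iKt_LAC_gc, iKt_LAC_ec,
  iK_I_ATP, inH, iK_g, iK_O2, iHbOP, inh, iK_O2_mito,
  iC_m, ig_L, ig_Na, ig_K, ig_Ca, ig_mAHP, iK_D, itau_Ca, iCa_0, iE_K, iE_Ca,
  iphi_n, iphi_h, itau_v, ialpha_v, iO2_a, iGLC_a,
  igNa_n, igNa_g, igKpas, ik_pump_n, ik_pump_g, iJpump0_g, iK_m_pump,
  iCtot, iNtot, iAtot, iq_AK, iK_m_mito, iF_0, iVv_0, ik1, ik2, ik3, iNa0_n,
  ikLDHp_n, ikLDHp_g, iM_cyto_n, iM_cyto_g, iM_mito_n, iM_mito_g,
  iK_m_ADP_n, iK_m_ADP_g, iK_m_NADH_n, iK_m_NADH_g,
  ikCKp_n, ikCKp_g, iK_m_NAD_n, iK_m_NAD_g,
  iTmax_GLC_en, iTmax_GLC_ce, iTmax_GLC_eg, iTmax_GLC_cg,
  iTmax_LAC_gc, iTmax_LAC_ne, iTmax_LAC_ge, iTmax_LAC_ec,
  ikHKPFK_n, ikHKPFK_g, ikLDHm_n, ikLDHm_g, iPScapVn, iPScapVg,
  iVmax_out_n, iVmax_out_g, iVmax_in_n, iVmax_in_g,
  ikPGK_n, ikPGK_g, ikPK_n, ikPK_g, iJATPases_n, iJATPases_g,
  ikCKm_n, ikCKm_g, iTNADH_n, iTNADH_g, iLAC_a,
  /* scenario block */
  istim_t0, istim_tend, if0, ifinf, itauf, iNexc, igbar, idglut, iEAMPA,
  iflow_kind, iflow_t1, iflow_plateau, iflow_amp,
  iflow_tau_a, iflow_tau_b, iflow_tau_rec,
  iclamp0 /* 33 clamp-mask entries follow */
};
#define NPAR (iclamp0 + 33)

/* state indices */
enum {
  sNa_n, sNa_g, sGLC_n, sGLC_g, sGAP_n, sGAP_g, sPEP_n, sPEP_g,
  sPYR_n, sPYR_g, sLAC_n, sLAC_g, sNADHc_n, sNADHc_g, sNADHm_n, sNADHm_g,
  sATP_n, sATP_g, sPCr_n, sPCr_g, sO2_n, sO2_g, sO2_c, sGLC_c, sLAC_c,
  sGLC_e, sLAC_e, sVv, sdHb, spsi, sh, sn, sCa
};
#define NSTATE 33

static double PARMS[NPAR];

void ngv_initmod(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, PARMS);
}

static double carrier(double src, double dst, double Tmax, double Kt)
{
  return Tmax * (src / (src + Kt) - dst / (dst + Kt));
}

static double fexc_of_t(double t, const double *p)
{
  if (t < p[istim_t0] || t > p[istim_tend]) return 0.0;
  return p[ifinf] + (p[if0] - p[ifinf]) * exp(-(t - p[istim_t0]) / p[itauf]);
}

static double flow_of_t(double t, const double *p)
{
  double F0 = p[iF_0];
  if (p[iflow_kind] < 0.5) return F0;            /* constant */
  double t1 = p[istim_t0] + p[iflow_t1];
  double tend = p[istim_tend];
  if (t < t1) return F0;
  double shape_end = F0 * (p[iflow_plateau] + p[iflow_amp] *
    (exp(-(tend - t1) / p[iflow_tau_a]) - exp(-(tend - t1) / p[iflow_tau_b])));
  if (t <= tend)
    return F0 * (p[iflow_plateau] + p[iflow_amp] *
      (exp(-(t - t1) / p[iflow_tau_a]) - exp(-(t - t1) / p[iflow_tau_b])));
  return F0 + (shape_end - F0) * exp(-(t - tend) / p[iflow_tau_rec]);
}

static void ngv_core(double t, const double *p, const double *y, double *dy)
{
  const double Ntot = p[iNtot], A = p[iAtot], q = p[iq_AK];
  const double Far = p[iFaraday];

  /* adenylate closure */
  double u_n = q * q + 4.0 * q * (A / y[sATP_n] - 1.0);
  double u_g = q * q + 4.0 * q * (A / y[sATP_g] - 1.0);
  double ADP_n = y[sATP_n] / 2.0 * (-q + sqrt(u_n));
  double ADP_g = y[sATP_g] / 2.0 * (-q + sqrt(u_g));
  double dAdA_n = -1.0 + q / 2.0 - sqrt(u_n) / 2.0 + q * A / (y[sATP_n] * sqrt(u_n));
  double dAdA_g = -1.0 + q / 2.0 - sqrt(u_g) / 2.0 + q * A / (y[sATP_g] * sqrt(u_g));

  /* sodium pump and leak */
  double Jleak_n = p[iSmVn] / Far * p[igNa_n] *
    (p[iRTF] * log(p[iNa_e] / y[sNa_n]) - y[spsi]);
  double Jleak_g = p[iSmVg] / Far * p[igNa_g] *
    (p[iRTF] * log(p[iNa_e] / y[sNa_g]) - p[ipsi_g]);
  double Jpump_n = p[iSmVn] * p[ik_pump_n] * y[sATP_n] * y[sNa_n] /
    (1.0 + y[sATP_n] / p[iK_m_pump]);
  double Jpump_g = p[iSmVg] * p[ik_pump_g] * y[sATP_g] * y[sNa_g] /
    (1.0 + y[sATP_g] / p[iK_m_pump]);

  /* glucose transport */
  double JGLC_en = carrier(y[sGLC_e], y[sGLC_n], p[iTmax_GLC_en], p[iKt_GLC_en]);
  double JGLC_eg = carrier(y[sGLC_e], y[sGLC_g], p[iTmax_GLC_eg], p[iKt_GLC_eg]);
  double JGLC_cg = carrier(y[sGLC_c], y[sGLC_g], p[iTmax_GLC_cg], p[iKt_GLC_cg]);
  double JGLC_ce = carrier(y[sGLC_c], y[sGLC_e], p[iTmax_GLC_ce], p[iKt_GLC_ce]);

  /* glycolysis */
  double inh_n = 1.0 + pow(y[sATP_n] / p[iK_I_ATP], p[inH]);
  double inh_g = 1.0 + pow(y[sATP_g] / p[iK_I_ATP], p[inH]);
  double JHK_n = p[ikHKPFK_n] * y[sATP_n] * y[sGLC_n] / (y[sGLC_n] + p[iK_g]) / inh_n;
  double JHK_g = p[ikHKPFK_g] * y[sATP_g] * y[sGLC_g] / (y[sGLC_g] + p[iK_g]) / inh_g;
  double JPGK_n = p[ikPGK_n] * y[sGAP_n] * ADP_n * (Ntot - y[sNADHc_n]) / y[sNADHc_n];
  double JPGK_g = p[ikPGK_g] * y[sGAP_g] * ADP_g * (Ntot - y[sNADHc_g]) / y[sNADHc_g];
  double JPK_n = p[ikPK_n] * y[sPEP_n] * ADP_n;
  double JPK_g = p[ikPK_g] * y[sPEP_g] * ADP_g;

  /* lactate dehydrogenase */
  double JLDH_n = p[ikLDHp_n] * y[sPYR_n] * y[sNADHc_n] -
    p[ikLDHm_n] * y[sLAC_n] * (Ntot - y[sNADHc_n]);
  double JLDH_g = p[ikLDHp_g] * y[sPYR_g] * y[sNADHc_g] -
    p[ikLDHm_g] * y[sLAC_g] * (Ntot - y[sNADHc_g]);

  /* lactate transport */
  double JLAC_ne = carrier(y[sLAC_n], y[sLAC_e], p[iTmax_LAC_ne], p[iKt_LAC_ne]);
  double JLAC_ge = carrier(y[sLAC_g], y[sLAC_e], p[iTmax_LAC_ge], p[iKt_LAC_ge]);
  double JLAC_gc = carrier(y[sLAC_g], y[sLAC_c], p[iTmax_LAC_gc], p[iKt_LAC_gc]);
  double JLAC_ec = carrier(y[sLAC_e], y[sLAC_c], p[iTmax_LAC_ec], p[iKt_LAC_ec]);

  /* mitochondria */
  double NADm_n = Ntot - y[sNADHm_n], NADm_g = Ntot - y[sNADHm_g];
  double Jmi_n = p[iVmax_in_n] * y[sPYR_n] / (y[sPYR_n] + p[iK_m_mito]) *
    NADm_n / (NADm_n + p[iK_m_NAD_n]);
  double Jmi_g = p[iVmax_in_g] * y[sPYR_g] / (y[sPYR_g] + p[iK_m_mito]) *
    NADm_g / (NADm_g + p[iK_m_NAD_g]);
  double Jmo_n = p[iVmax_out_n] * y[sO2_n] / (y[sO2_n] + p[iK_O2_mito]) *
    ADP_n / (ADP_n + p[iK_m_ADP_n]) * y[sNADHm_n] / (y[sNADHm_n] + p[iK_m_NADH_n]);
  double Jmo_g = p[iVmax_out_g] * y[sO2_g] / (y[sO2_g] + p[iK_O2_mito]) *
    ADP_g / (ADP_g + p[iK_m_ADP_g]) * y[sNADHm_g] / (y[sNADHm_g] + p[iK_m_NADH_g]);

  /* NADH shuttles */
  double Rm_n = y[sNADHc_n] / (Ntot - y[sNADHc_n]);
  double Rm_g = y[sNADHc_g] / (Ntot - y[sNADHc_g]);
  double Rp_n = (Ntot - y[sNADHm_n]) / y[sNADHm_n];
  double Rp_g = (Ntot - y[sNADHm_g]) / y[sNADHm_g];
  double Jsh_n = p[iTNADH_n] * Rm_n / (Rm_n + p[iM_cyto_n]) * Rp_n / (Rp_n + p[iM_mito_n]);
  double Jsh_g = p[iTNADH_g] * Rm_g / (Rm_g + p[iM_cyto_g]) * Rp_g / (Rp_g + p[iM_mito_g]);

  /* creatine kinase */
  double JCK_n = p[ikCKp_n] * ADP_n * y[sPCr_n] -
    p[ikCKm_n] * y[sATP_n] * (p[iCtot] - y[sPCr_n]);
  double JCK_g = p[ikCKp_g] * ADP_g * y[sPCr_g] -
    p[ikCKm_g] * y[sATP_g] * (p[iCtot] - y[sPCr_g]);

  /* oxygen exchange with the capillary */
  double O2eq = p[iK_O2] * pow(p[iHbOP] / y[sO2_c] - 1.0, -1.0 / p[inh]);
  double JO2mc_n = p[iPScapVn] * (O2eq - y[sO2_n]);
  double JO2mc_g = p[iPScapVg] * (O2eq - y[sO2_g]);

  /* capillary inflow-driven exchange */
  double Fin = flow_of_t(t, p);
  double kcap = 2.0 * Fin / p[iV_cap];
  double JO2c = kcap * (p[iO2_a] - y[sO2_c]);
  double JGLCc = kcap * (p[iGLC_a] - y[sGLC_c]);
  double JLACc = kcap * (p[iLAC_a] - y[sLAC_c]);
  double O2c_bar = 2.0 * y[sO2_c] - p[iO2_a];

  /* Hodgkin-Huxley currents */
  double psi = y[spsi];
  double xm = psi + 33.0;
  double am = fabs(xm) < 1e-6 ? 1.0 : 0.1 * xm / (1.0 - exp(-0.1 * xm));
  double bm = 4.0 * exp(-(psi + 58.0) / 12.0);
  double ah = 0.07 * exp(-(psi + 50.0) / 10.0);
  double bh = 1.0 / (exp(-0.1 * (psi + 20.0)) + 1.0);
  double xn = psi + 34.0;
  double an = fabs(xn) < 1e-6 ? 0.1 : 0.01 * xn / (1.0 - exp(-0.1 * xn));
  double bn = 0.125 * exp(-(psi + 44.0) / 25.0);
  double minf = am / (am + bm);
  double hinf = ah / (ah + bh), ninf = an / (an + bn);
  double tauh = 1e-3 / (ah + bh), taun = 1e-3 / (an + bn);
  double mCa = 1.0 / (1.0 + exp(-(psi + 20.0) / 9.0));

  double E_Na = p[iRTF] * log(p[iNa_e] / y[sNa_n]);
  double E_L = (p[igKpas] * p[iE_K] + p[igNa_n] * E_Na) / (p[igKpas] + p[igNa_n]);
  double I_L = p[ig_L] * (psi - E_L);
  double I_Na = p[ig_Na] * minf * minf * minf * y[sh] * (psi - E_Na);
  double I_K = p[ig_K] * pow(y[sn], 4.0) * (psi - p[iE_K]);
  double I_Ca = p[ig_Ca] * mCa * mCa * (psi - p[iE_Ca]);
  double I_mAHP = p[ig_mAHP] * y[sCa] / (y[sCa] + p[iK_D]) * (psi - p[iE_K]);
  double I_pump = Far * p[ik_pump_n] * y[sATP_n] * (y[sNa_n] - p[iNa0_n]) /
    (1.0 + y[sATP_n] / p[iK_m_pump]);

  /* external drives */
  double fexc = fexc_of_t(t, p);
  double gexc = p[iNexc] * p[igbar] * fexc;
  double Isyn = gexc * (p[iEAMPA] - psi);
  int stim_on = (fexc > 0.0);
  double Jstim_n = stim_on ? p[iSmVn] / Far * (2.0 / 3.0 * Isyn - I_Na) : 0.0;
  double Jstim_g = 3.0 * p[idglut] * p[iNexc] * fexc;

  /* venous balloon: resolve F_out against dVv/dt = F_in - F_out */
  double v = y[sVv] / p[iVv_0];
  double a = p[iF_0] * p[itau_v] / p[iVv_0] / sqrt(v);
  double Fout = (p[iF_0] * pow(v, 1.0 / p[ialpha_v]) + a * Fin) / (1.0 + a);

  /* volume ratios */
  double r_en = p[iV_e] / p[iV_n], r_eg = p[iV_e] / p[iV_g];
  double r_ce = p[iV_cap] / p[iV_e];
  double r_cg = p[iV_cap] / p[iV_g], r_cn = p[iV_cap] / p[iV_n];
  double xi = p[ixi];

  dy[sNa_n] = Jleak_n - 3.0 * Jpump_n + Jstim_n;
  dy[sNa_g] = Jleak_g - 3.0 * Jpump_g + Jstim_g;
  dy[sGLC_n] = JGLC_en - JHK_n;
  dy[sGLC_g] = JGLC_cg + JGLC_eg - JHK_g;
  dy[sGAP_n] = 2.0 * JHK_n - JPGK_n;
  dy[sGAP_g] = 2.0 * JHK_g - JPGK_g;
  dy[sPEP_n] = JPGK_n - JPK_n;
  dy[sPEP_g] = JPGK_g - JPK_g;
  dy[sPYR_n] = JPK_n - JLDH_n - Jmi_n;
  dy[sPYR_g] = JPK_g - JLDH_g - Jmi_g;
  dy[sLAC_n] = JLDH_n - JLAC_ne;
  dy[sLAC_g] = JLDH_g - JLAC_ge - JLAC_gc;
  dy[sNADHc_n] = (JPGK_n - JLDH_n - Jsh_n) / (1.0 - xi);
  dy[sNADHc_g] = (JPGK_g - JLDH_g - Jsh_g) / (1.0 - xi);
  dy[sNADHm_n] = (4.0 * Jmi_n - Jmo_n + Jsh_n) / xi;
  dy[sNADHm_g] = (4.0 * Jmi_g - Jmo_g + Jsh_g) / xi;
  dy[sATP_n] = (-2.0 * JHK_n + JPGK_n + JPK_n - p[iJATPases_n] - Jpump_n +
                3.6 * Jmo_n + JCK_n) / (1.0 - dAdA_n);
  dy[sATP_g] = (-2.0 * JHK_g + JPGK_g + JPK_g - p[iJATPases_g] -
                1.75 * Jpump_g + 0.75 * p[iJpump0_g] +
                3.6 * Jmo_g + JCK_g) / (1.0 - dAdA_g);
  dy[sPCr_n] = -JCK_n;
  dy[sPCr_g] = -JCK_g;
  dy[sO2_n] = JO2mc_n - 0.6 * Jmo_n;
  dy[sO2_g] = JO2mc_g - 0.6 * Jmo_g;
  dy[sO2_c] = JO2c - JO2mc_n / r_cn - JO2mc_g / r_cg;
  dy[sGLC_c] = JGLCc - JGLC_ce / r_ce - JGLC_cg / r_cg;
  dy[sLAC_c] = JLACc + JLAC_ec / r_ce + JLAC_gc / r_cg;
  dy[sGLC_e] = JGLC_ce - JGLC_eg / r_eg - JGLC_en / r_en;
  dy[sLAC_e] = JLAC_ne / r_en + JLAC_ge / r_eg - JLAC_ec;
  dy[sVv] = Fin - Fout;
  dy[sdHb] = Fin * (p[iO2_a] - O2c_bar) - Fout * y[sdHb] / y[sVv];
  dy[spsi] = (-I_L - I_Na - I_K - I_Ca - I_mAHP - I_pump + Isyn) / p[iC_m];
  dy[sh] = p[iphi_h] * (hinf - y[sh]) / tauh;
  dy[sn] = p[iphi_n] * (ninf - y[sn]) / taun;
  dy[sCa] = -p[iSmVn] / Far * I_Ca - (y[sCa] - p[iCa_0]) / p[itau_Ca];

  for (int i = 0; i < NSTATE; i++)
    if (p[iclamp0 + i] > 0.5) dy[i] = 0.0;
}

void ngv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  ngv_core(*t, PARMS, y, ydot);
}

/* direct .Call entry point for cross-checking against the R transcription */
SEXP ngv_rhs_call(SEXP t, SEXP y, SEXP parms)
{
  if (LENGTH(parms) != NPAR) error("parms must have length %d", NPAR);
  if (LENGTH(y) != NSTATE) error("y must have length %d", NSTATE);
  SEXP out = PROTECT(allocVector(REALSXP, NSTATE));
  ngv_core(REAL(t)[0], REAL(parms), REAL(y), REAL(out));
  UNPROTECT(1);
  return out;
}

static const R_CallMethodDef callMethods[] = {
  {"ngv_rhs_call", (DL_FUNC) &ngv_rhs_call, 3},
  {NULL, NULL, 0}
};

void R_init_ngvmet(DllInfo *info)
{
  R_registerRoutines(info, NULL, callMethods, NULL, NULL);
  R_useDynamicSymbols(info, TRUE);
}
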