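/* Compiled right-hand sides for the photoadaptation ODE models,
 * in the deSolve compiled-code convention (initializer + derivs).
 *
 * Species order (full model):
 *  0 m_wc1  1 m_frq  2 m_vvd
 *  3 WCC_d  4 WCC_a  5 WCC_aa  6 WCC_p
 *  7 FRQ_c  8 FRQ_n  9 FRQ_p
 * 10 VVD_d 11 VVD_a 12 VVD_aa 13 HET
 *
 * Parameter order must match .PARAM_NAMES in R/parameters.R, with the
 * current (piecewise-constant) light intensity appended as entry 45.
 * The R reference implementation (stoichiometry x fluxes) is the
 * specification; the test suite checks this code against it.
 */

#include <R.h>
#include <math.h>

#define NPAR_FULL 49
static double p[NPAR_FULL];

void vvd_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR_FULL;
    odeparms(&n, p);
}

static double hill(double x, double K, double h)
{
    double xh;
    if (x <= 0.0) return 0.0;
    xh = pow(x, h);
    return xh / (pow(K, h) + xh);
}

void vvd_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double ka_wcc = p[0], ka_vvd = p[1], kd_wcc = p[2], kd_vvd = p[3];
    const double kdim_wcc = p[4], kundim_wcc = p[5], kpad_wcc = p[6];
    const double kdim_vvd = p[7], kundim_vvd = p[8], kpad_vvd = p[9];
    const double l1 = p[10], lm1 = p[11], l5 = p[12];
    const double bas_wc1 = p[13], vmax_wc1 = p[14], K_wc1 = p[15];
    const double vmax_frq = p[16], K_frq = p[17], vc_frq = p[18], K_cbox = p[19];
    const double vmax_vvd = p[20], K_vvd = p[21], bas_vvd = p[22];
    const double hill_lre = p[23], hill_cbox = p[24];
    const double dm_wc1 = p[25], dm_frq = p[26], dm_vvd = p[27];
    const double ktl_wc1 = p[28], ktl_frq = p[29], ktl_vvd = p[30];
    const double dg_wcc_d = p[31], dg_wcc_a = p[32], dg_wcc_aa = p[33];
    const double dg_wcc_p = p[34], dg_het = p[35];
    const double dg_vvd_d = p[36], dg_vvd_a = p[37], dg_vvd_aa = p[38];
    const double dg_frq_c = p[39], dg_frq_n = p[40], dg_frq_p = p[41];
    const double kin_frq = p[42], kph = p[43], K_ph = p[44];
    const double kdp = p[45], K_dp = p[46], kpf = p[47];
    const double I = p[48];

    const double m_wc1 = y[0], m_frq = y[1], m_vvd = y[2];
    const double WCC_d = y[3], WCC_a = y[4], WCC_aa = y[5], WCC_p = y[6];
    const double FRQ_c = y[7], FRQ_n = y[8], FRQ_p = y[9];
    const double VVD_d = y[10], VVD_a = y[11], VVD_aa = y[12], HET = y[13];

    /* photocycle and dimerization */
    const double v_act_w  = ka_wcc * I * WCC_d;
    const double v_dec_w  = kd_wcc * WCC_a;
    const double v_act_v  = ka_vvd * I * VVD_d;
    const double v_dec_v  = kd_vvd * VVD_a;
    const double v_dim_w  = kdim_wcc * WCC_a * WCC_a;
    const double v_und_w  = kundim_wcc * WCC_aa;
    const double v_pad_w  = kpad_wcc * WCC_aa;
    const double v_dim_v  = kdim_vvd * VVD_a * VVD_a;
    const double v_und_v  = kundim_vvd * VVD_aa;
    const double v_pad_v  = kpad_vvd * VVD_aa;
    const double v_het_on = l1 * WCC_a * VVD_a;
    const double v_het_off = lm1 * HET;
    const double v_l5_w   = l5 * HET;   /* adduct decays in WCC -> WCC_d + VVD_a */
    const double v_l5_v   = l5 * HET;   /* adduct decays in VVD -> WCC_a + VVD_d */

    /* transcription */
    const double v_tx_wc1 = bas_wc1 + vmax_wc1 * hill(WCC_aa, K_wc1, hill_lre);
    const double v_tx_frq = vmax_frq * hill(WCC_aa, K_frq, hill_lre)
                          + vc_frq * hill(WCC_d, K_cbox, hill_cbox);
    const double v_tx_vvd = bas_vvd + vmax_vvd * hill(WCC_aa, K_vvd, hill_lre);

    /* phosphorylation module */
    const double v_in  = kin_frq * FRQ_c;
    const double v_ph  = kph * FRQ_n * WCC_d / (K_ph + WCC_d);
    const double v_dp  = kdp * WCC_p / (1.0 + WCC_p / K_dp);
    const double v_pf  = kpf * FRQ_n;

    ydot[0] = v_tx_wc1 - dm_wc1 * m_wc1;
    ydot[1] = v_tx_frq - dm_frq * m_frq;
    ydot[2] = v_tx_vvd - dm_vvd * m_vvd;

    ydot[3] = -v_act_w + v_dec_w + v_pad_w + v_l5_w + ktl_wc1 * m_wc1
              - dg_wcc_d * WCC_d - v_ph + v_dp;
    ydot[4] = v_act_w - v_dec_w - 2.0 * v_dim_w + 2.0 * v_und_w + v_pad_w
              - v_het_on + v_het_off + v_l5_v - dg_wcc_a * WCC_a;
    ydot[5] = v_dim_w - v_und_w - v_pad_w - dg_wcc_aa * WCC_aa;
    ydot[6] = v_ph - v_dp - dg_wcc_p * WCC_p;

    ydot[7] = ktl_frq * m_frq - v_in - dg_frq_c * FRQ_c;
    ydot[8] = v_in - v_pf - dg_frq_n * FRQ_n;
    ydot[9] = v_pf - dg_frq_p * FRQ_p;

    ydot[10] = -v_act_v + v_dec_v + v_pad_v + v_l5_v + ktl_vvd * m_vvd
               - dg_vvd_d * VVD_d;
    ydot[11] = v_act_v - v_dec_v - 2.0 * v_dim_v + 2.0 * v_und_v + v_pad_v
               - v_het_on + v_het_off + v_l5_w - dg_vvd_a * VVD_a;
    ydot[12] = v_dim_v - v_und_v - v_pad_v - dg_vvd_aa * VVD_aa;
    ydot[13] = v_het_on - v_het_off - v_l5_w - v_l5_v - dg_het * HET;
}

/* ------------------------------------------------------------------ *
 * Simplified WCC-VVD model: 4 state variables
 *  0 WCC_d (light-activatable pool, W)
 *  1 WCC_a (light-activated, A)
 *  2 VVD   (inhibitor, V)
 *  3 CPLX  (WCC_a-VVD complex, C)
 * Parameters:
 *  0 ka   light activation (per min per intensity unit)
 *  1 r    photoadduct decay of free WCC_a back to WCC_d
 *  2 pv   VVD production rate driven by WCC_a
 *  3 kon  complex association
 *  4 kc   complex photoadduct decay, returning WCC_d (+ dark VVD)
 *  5 sw   constitutive WCC synthesis
 *  6 dW, 7 dA, 8 dV, 9 dC  degradation rates
 * 10 I    light intensity
 * ------------------------------------------------------------------ */

#define NPAR_SIMP 11
static double ps[NPAR_SIMP];

void simp_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR_SIMP;
    odeparms(&n, ps);
}

void simp_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double ka = ps[0], r = ps[1], pv = ps[2], kon = ps[3], kc = ps[4];
    const double sw = ps[5], dW = ps[6], dA = ps[7], dV = ps[8], dC = ps[9];
    const double I = ps[10];
    const double W = y[0], A = y[1], V = y[2], C = y[3];

    const double v_act = ka * I * W;
    const double v_dec = r * A;
    const double v_on  = kon * A * V;
    const double v_kc  = kc * C;

    ydot[0] = sw - v_act + v_dec + v_kc - dW * W;
    ydot[1] = v_act - v_dec - v_on - dA * A;
    ydot[2] = pv * A - v_on + v_kc - dV * V;
    ydot[3] = v_on - v_kc - dC * C;
}

/* Direct evaluators callable from R via .C(); used by the test suite to
 * compare the compiled right-hand sides against the R reference
 * implementations without solver truncation error. */

void vvd_rhs_eval(double *y, double *pars, double *ydot)
{
    int i, neq = 14, ip = 0;
    double t = 0.0, yout = 0.0;
    for (i = 0; i < NPAR_FULL; i++) p[i] = pars[i];
    vvd_derivs(&neq, &t, y, ydot, &yout, &ip);
}

void simp_rhs_eval(double *y, double *pars, double *ydot)
{
    int i, neq = 4, ip = 0;
    double t = 0.0, yout = 0.0;
    for (i = 0; i < NPAR_SIMP; i++) ps[i] = pars[i];
    simp_derivs(&neq, &t, y, ydot, &yout, &ip);
}
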