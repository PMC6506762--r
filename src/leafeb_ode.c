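/* Compiled right-hand side of the reference-differenced energy-balance
 * ODE for use with deSolve.  One state per reference: the same target
 * object is predicted simultaneously against up to two references (black
 * and white) sharing all parameters, which is how the joint likelihood
 * constrains the boundary-layer conductance.  Driver signals arrive as
 * deSolve forcing functions, each tabulated on its own grid; parameters
 * follow the layout built by build_parms() in R/energy_balance.R. */

#include <R.h>
#include <math.h>

static double p[29];
#define K1       p[0]
#define ALPHA1   p[1]
#define EPS1     p[2]
#define GBH1     p[3]
#define LAT_SC   p[4]   /* latent multiplier; 0 disables the latent term */
#define BL_SIDES p[5]   /* boundary layers aggregated into g_bw */
#define RATIO_WH p[6]
#define GS_MODE  p[7]   /* 0: fixed conductance, 1: dark/light/dark model */
#define GS_FIX   p[8]
#define GS_MIN   p[9]   /* clamp on modelled gs before the series chain */
#define T_ON     p[10]
#define T_OFF    p[11]
#define G1       p[12]
#define G2       p[13]
#define G3       p[14]
#define PHI_I    p[15]
#define TAU_I    p[16]
#define PHI_D    p[17]
#define TAU_D    p[18]
#define S_L      p[19]
#define NREFS    p[20]
/* per-reference properties: ref r (0-based) at 21 + 4r */
#define K2(r)    p[21 + 4 * (r)]
#define ALPHA2(r) p[22 + 4 * (r)]
#define EPS2(r)  p[23 + 4 * (r)]
#define GBH2(r)  p[24 + 4 * (r)]

static double forc[12];
#define IS1   forc[0]
#define TAIRF forc[1]
#define RHOF  forc[2]
#define CSF   forc[3]
#define EAF   forc[4]
#define PATMF forc[5]
/* per-reference drivers: ref r at 6 + 3r */
#define IS2(r)  forc[6 + 3 * (r)]
#define T2(r)   forc[7 + 3 * (r)]
#define DT2(r)  forc[8 + 3 * (r)]

static const double THETA = 5.670374419e-8;  /* W m-2 K-4 */
static const double RGAS  = 8.31446;         /* m3 Pa K-1 mol-1 */

void initmod_diff(void (* odeparms)(int *, double *))
{
    int n = 29;
    odeparms(&n, p);
}

void initforc_diff(void (* odeforcs)(int *, double *))
{
    int n = 12;
    odeforcs(&n, forc);
}

/* Buck (1981) saturation vapour pressure over water, Pa (T in K) */
static double buck_es(double tk)
{
    double tc = tk - 273.15;
    return 611.21 * exp((18.678 - tc / 234.5) * tc / (257.14 + tc));
}

/* rescaled Gompertz step response; tl is time since the phase start */
static double gomp(double tl, double g0, double G, double tau, double phi,
                   double sl)
{
    double e0 = exp(-exp(phi / tau));
    double a;
    if (1.0 - e0 < 1e-12)
        a = 1.0 - exp(-tl / tau);   /* phi -> -inf analytic limit */
    else
        a = (exp(-exp((phi - tl) / tau)) - e0) / (1.0 - e0);
    double g = (G + sl * tl - g0) * a + g0;
    return g > 0.0 ? g : 0.0;
}

/* dark/light/dark schedule with continuity across the switches; the
 * (lag, time constant) pair follows the direction of the response */
static double gs_sched(double t)
{
    double g0, G, tl, sl, tau, phi;
    if (t < T_ON) return G1;
    if (t < T_OFF) {
        g0 = G1; G = G2; tl = t - T_ON; sl = S_L;
    } else {
        double gend = gomp(T_OFF - T_ON, G1, G2,
                           (G2 >= G1) ? TAU_I : TAU_D,
                           (G2 >= G1) ? PHI_I : PHI_D, S_L);
        g0 = gend; G = G3; tl = t - T_OFF; sl = 0.0;
    }
    tau = (G >= g0) ? TAU_I : TAU_D;
    phi = (G >= g0) ? PHI_I : PHI_D;
    return gomp(tl, g0, G, tau, phi, sl);
}

void derivs_diff(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double gs;
    int nref = (int) NREFS;

    if (GS_MODE < 0.5) gs = GS_FIX;
    else {
        gs = gs_sched(*t);
        if (gs < GS_MIN) gs = GS_MIN;
    }

    double gbw = 0.0, gtw = 0.0;
    if (LAT_SC > 0.0 && gs > 0.0) {
        gbw = BL_SIDES * RATIO_WH * GBH1 * PATMF / (RGAS * TAIRF);
        if (gbw > 0.0) gtw = 1.0 / (1.0 / gbw + 1.0 / gs);
    }

    for (int r = 0; r < nref; r++) {
        double t1 = y[r];
        double le = 0.0;
        if (gtw > 0.0) {
            double e = 0.622 * RHOF / PATMF * (RGAS * t1 / PATMF) * gtw *
                       (buck_es(t1) - EAF);
            if (e < 0.0) e = 0.0;   /* no condensation */
            le = LAT_SC * (2.501e6 - 2361.0 * (t1 - 273.15)) * e;
        }
        ydot[r] = (K2(r) * DT2(r) + (ALPHA1 * IS1 - ALPHA2(r) * IS2(r))
                   + 2.0 * THETA * (EPS2(r) * pow(T2(r), 4.0)
                                    - EPS1 * pow(t1, 4.0))
                   + 2.0 * RHOF * CSF * (GBH2(r) * (T2(r) - TAIRF)
                                         - GBH1 * (t1 - TAIRF))
                   - le) / K1;
    }

    if (ip[0] >= 1) yout[0] = gs;
}
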