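/* Compiled right-hand side of the lupus-nephritis interaction model,
 * following the deSolve compiled-model convention (initfunc + derivs +
 * optional root function).  Must agree with the R reference implementation
 * lupus_rhs() to near machine precision; the test suite enforces this.
 *
 * State: x1..x9, y1..y_n (immune-complex chain, n = n_ic), c1..c4.
 * Time in days.
 */

#include <R.h>

#define N_PARMS 33

static double parms[N_PARMS];

#define p_gamma   parms[0]
#define p_delta   parms[1]
#define p_beta    parms[2]
#define p_alpha   parms[3]
#define p_lambda  parms[4]
#define p_q       parms[5]
#define p_eta     parms[6]
#define p_omega   parms[7]
#define p_K1      parms[8]
#define p_K2      parms[9]
#define p_K3      parms[10]
#define p_z1      parms[11]
#define p_z2      parms[12]
#define p_z3      parms[13]
#define p_z4      parms[14]
#define p_z5      parms[15]
#define p_theta   parms[16]
#define p_mu1     parms[17]
#define p_nu1     parms[18]
#define p_mu2     parms[19]
#define p_nu2     parms[20]
#define p_nic     parms[21]
#define p_q0      parms[22]
#define p_q1      parms[23]
#define p_q2      parms[24]
#define p_poly_on  parms[25]   /* days; poly_on > poly_off disables */
#define p_poly_off parms[26]
#define p_dep_on   parms[27]
#define p_dep_off  parms[28]
#define p_m_tilc   parms[29]   /* capacity multiplier while depletion active */
#define p_m_vnk    parms[30]   /* migration multiplier while depletion active */
#define p_xon      parms[31]   /* telegraph forcing (0 or 1) */
#define p_esrd     parms[32]   /* damage threshold for the root function */

void lupus_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double hill3(double x, double K)
{
    double x3 = x * x * x;
    return x3 / (K * K * K + x3);
}

static double cap1(double s)
{
    return s > 1.0 ? 1.0 : s;
}

void lupus_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int n = (int) p_nic;
    double *x = y;            /* x[0..8] = x1..x9 */
    double *ch = y + 9;       /* chain y1..yn */
    double *cc = y + 9 + n;   /* c1..c4 */
    double tt = *t;
    int i;

    double stim = (tt >= p_poly_on && tt <= p_poly_off) ? p_q1 : 0.0;
    double m_t = (tt >= p_dep_on && tt <= p_dep_off) ? p_m_tilc : 1.0;
    double m_v = (tt >= p_dep_on && tt <= p_dep_off) ? p_m_vnk : 1.0;

    double cifn = p_q0 + stim +
        p_q2 * (p_z4 * hill3(x[8], p_K2) + p_z1 * hill3(x[7], p_K2));
    if (cifn > 1.0) cifn = 1.0;

    double act = p_alpha * cap1(hill3(cifn, p_K1) + p_z2 * hill3(x[7], p_K2));
    double pool = x[0] + x[1];

    ydot[0] = p_gamma * (1.0 - pool / (p_omega * m_t)) * pool -
              act * x[0] - p_delta * x[0];
    ydot[1] = act * x[0] - p_delta * x[1];
    ydot[2] = p_beta * cap1(hill3(x[1], p_K2) + p_z3 * hill3(x[8], p_K2)) +
              p_gamma * hill3(cc[1], p_K2) * x[2] - p_delta * x[2];
    ydot[3] = (p_beta + p_gamma * hill3(cc[0], p_K2) * x[3]) *
              (1.0 - x[3] / p_omega) - p_delta * x[3];
    ydot[4] = p_beta * hill3(x[5], p_K3) * m_v - p_delta * x[4];
    ydot[5] = p_beta * cap1(p_z5 * hill3(x[8], p_K2) + p_theta * hill3(cifn, p_K1)) +
              p_gamma * hill3(cc[3], p_K2) * x[5] - p_delta * x[5];
    ydot[6] = (p_beta + p_gamma * hill3(cc[2], p_K2) * x[6]) *
              (1.0 - x[6] / p_omega) - p_delta * x[6];
    ydot[7] = p_mu1 * (x[2] + x[4] + x[5]) - p_nu1 * x[7];

    /* immune-complex chain driven by damage */
    ydot[9] = p_mu2 * (x[7] - ch[0]);
    for (i = 1; i < n; i++)
        ydot[9 + i] = p_mu2 * (ch[i - 1] - ch[i]);
    ydot[8] = p_mu2 * (p_xon + ch[n - 1]) - p_nu2 * x[8];

    ydot[9 + n]     = p_q * x[2] - p_lambda * hill3(cc[0], p_K2) * x[3] - p_eta * cc[0];
    ydot[9 + n + 1] = p_q * x[3] - p_lambda * hill3(cc[1], p_K2) * x[2] - p_eta * cc[1];
    ydot[9 + n + 2] = p_q * x[5] - p_lambda * hill3(cc[2], p_K2) * x[6] - p_eta * cc[2];
    ydot[9 + n + 3] = p_q * x[6] - p_lambda * hill3(cc[3], p_K2) * x[5] - p_eta * cc[3];
}

/* Root: damage reaches the end-stage threshold. */
void lupus_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    gout[0] = y[7] - p_esrd;
}
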