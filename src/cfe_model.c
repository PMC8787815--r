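/* Compiled right-hand side of the resource-limited cell-free expression
 * model, in the form deSolve expects for compiled ODE/DDE models.
 *
 * States (y):   0 RNA (nM), 1 TsR, 2 TlR, 3 P_dark (nM), 4 P_mat (nM)
 * Outputs:      0 v_tx (nM/h), 1 v_tl (nM/h)
 *
 * Parameters (parms), set from R via cfe_init:
 *   0 k_r, 1 K_r, 2 delta_r, 3 k_p, 4 K_p, 5 k_mat, 6 delta_TsR,
 *   7 delta_TlR, 8 K_l, 9 a, 10 b, 11 tau_d, 12 dna0, 13 rna0,
 *   14 tx_mm, 15 tl_mm, 16 tsr_deg, 17 tlr_mm, 18 use_lag
 *
 * The lagged transcript concentration RNA(t - tau_d) is obtained from
 * deSolve's stored dense history (lagvalue); the pre-start history is the
 * constant RNA(s) = rna0 for s <= 0.  When use_lag is 0 the plain ODE
 * path is taken with lagged RNA = RNA(t).
 *
 * States are clamped at 0 inside rate expressions so that a solver
 * excursion to a tiny negative value cannot generate spurious negative
 * fluxes; any residual clamping on output is handled (and warned about)
 * on the R side.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double parms[19];

#define k_r        parms[0]
#define K_r        parms[1]
#define delta_r    parms[2]
#define k_p        parms[3]
#define K_p        parms[4]
#define k_mat      parms[5]
#define delta_TsR  parms[6]
#define delta_TlR  parms[7]
#define K_l        parms[8]
#define cons_a     parms[9]
#define cons_b     parms[10]
#define tau_d      parms[11]
#define dna0       parms[12]
#define rna0       parms[13]
#define tx_mm      parms[14]
#define tl_mm      parms[15]
#define tsr_deg    parms[16]
#define tlr_mm     parms[17]
#define use_lag    parms[18]

static void lagvalue(double T, int *nr, int N, double *ytau) {
  static void (*fun)(double, int *, int, double *) = NULL;
  if (fun == NULL)
    fun = (void (*)(double, int *, int, double *))
      R_GetCCallable("deSolve", "lagvalue");
  fun(T, nr, N, ytau);
}

void cfe_init(void (*odeparms)(int *, double *)) {
  int n = 19;
  odeparms(&n, parms);
}

void cfe_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  if (ip[0] < 2) error("nout should be at least 2");

  double RNA = y[0] > 0 ? y[0] : 0;
  double TsR = y[1] > 0 ? y[1] : 0;
  double TlR = y[2] > 0 ? y[2] : 0;
  double Pd  = y[3] > 0 ? y[3] : 0;

  /* lagged transcript concentration for the translation flux */
  double lag = RNA;
  if (use_lag > 0.5) {
    double T = *t - tau_d;
    if (T <= 0) {
      lag = rna0;
    } else {
      int nr[1] = {0};
      double ytau[1] = {rna0};
      lagvalue(T, nr, 1, ytau);
      lag = ytau[0];
    }
    if (lag < 0) lag = 0;
  }

  double v_tx, v_tl;
  if (dna0 <= 0) {
    v_tx = 0;
  } else if (tx_mm > 0.5) {
    v_tx = k_r * TsR * dna0 / (K_r + dna0);
  } else {
    v_tx = k_r * TsR * dna0;
  }

  if (lag <= 0) {
    v_tl = 0;
  } else if (tl_mm > 0.5) {
    v_tl = k_p * TlR * lag / (K_p + lag);
  } else {
    v_tl = k_p * TlR * lag;
  }

  double d_tsr = tsr_deg > 0.5 ? delta_TsR * TsR : 0;
  double d_tlr;
  if (TlR <= 0) {
    d_tlr = 0;
  } else if (tlr_mm > 0.5) {
    d_tlr = delta_TlR * TlR / (K_l + TlR);
  } else {
    d_tlr = delta_TlR * TlR;
  }

  ydot[0] = v_tx - delta_r * RNA;     /* RNA     */
  ydot[1] = -cons_a * v_tx - d_tsr;   /* TsR     */
  ydot[2] = -cons_b * v_tl - d_tlr;   /* TlR     */
  ydot[3] = v_tl - k_mat * Pd;        /* P_dark  */
  ydot[4] = k_mat * Pd;               /* P_mat   */

  yout[0] = v_tx;
  yout[1] = v_tl;
}
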