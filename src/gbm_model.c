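/* Compiled right-hand side of the GBM-immune ODE system for deSolve.
 *
 * State: y = (C, T, M) = (tumor cells, activated T cells, MDSCs).
 * Parameters (13, order fixed; see R/params.R param_names()):
 *   lambda_C, C_max, eta, a_T, s_T, rho, eps_C, r, d_T, s_M, alpha, q, d_M
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[13];

#define LAMBDA_C parms[0]
#define C_MAX    parms[1]
#define ETA      parms[2]
#define A_T      parms[3]
#define S_T      parms[4]
#define RHO      parms[5]
#define EPS_C    parms[6]
#define R_SUP    parms[7]
#define D_T      parms[8]
#define S_M      parms[9]
#define ALPHA    parms[10]
#define Q_M      parms[11]
#define D_M      parms[12]

void gbm_initmod(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

/* Rates are evaluated at the non-negative part of the state.  Exact
 * solutions started non-negative stay non-negative, but an adaptive
 * integrator can undershoot zero by up to its absolute tolerance during
 * steep extinction transients; evaluating the interactions at max(y, 0)
 * freezes such excursions instead of amplifying them (a negative tumor
 * count would otherwise feed back through the logistic and checkpoint
 * terms and diverge). */
void gbm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double C = y[0] > 0.0 ? y[0] : 0.0;
    double T = y[1] > 0.0 ? y[1] : 0.0;
    double M = y[2] > 0.0 ? y[2] : 0.0;
    double checkpoint = 1.0 + RHO * T * (T + EPS_C * C);

    ydot[0] = LAMBDA_C * C * (1.0 - C / C_MAX) - ETA * T * C;
    ydot[1] = (A_T + S_T * T * C) / checkpoint - R_SUP * T * M - D_T * T;
    ydot[2] = S_M * C + ALPHA * C / (Q_M + C) - D_M * M;
}

static const R_CMethodDef cMethods[] = {
    {"gbm_initmod", (DL_FUNC) &gbm_initmod, 1},
    {"gbm_derivs",  (DL_FUNC) &gbm_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_gbmimmune(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
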