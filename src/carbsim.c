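/* Minimal glucose-insulin model with two-compartment subcutaneous insulin
 * and two-compartment gut absorption, for use as a deSolve compiled model.
 *
 * States (order fixed, mirrored in R/simulator.R):
 *   y[0] G    plasma glucose, mg/dL
 *   y[1] X    remote insulin action, U
 *   y[2] Isc1 subcutaneous insulin depot, U
 *   y[3] Isc2 second subcutaneous compartment, U
 *   y[4] Ipl  circulating insulin, U
 *   y[5] Q1   first gut compartment, mg
 *   y[6] Q2   second gut compartment, mg
 *
 * Model inputs (scalars + per-meal event blocks) are passed through a
 * package-global buffer set by cc_set_inputs() immediately before each
 * solver call, which keeps the event machinery independent of deSolve's
 * fixed-length parameter copying.
 */

#include <R.h>
#include <Rinternals.h>
#include <string.h>
#include <math.h>

static double *cc_par = NULL;
static int cc_npar = 0;

/* layout of cc_par */
enum { P1, SI, P2, GB, VG, TAUI, TAUM, FBIO, ICLEAR, IB, UBASAL,
       MODE, ICR, ISF, GT, IOB, NEV, EV0 };

SEXP cc_set_inputs(SEXP x)
{
    int n = LENGTH(x);
    if (n < EV0)
        error("input vector too short (%d < %d)", n, EV0);
    cc_par = (double *) R_Realloc(cc_par, n, double);
    memcpy(cc_par, REAL(x), n * sizeof(double));
    cc_npar = n;
    return R_NilValue;
}

void cc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *p = cc_par;
    double ra = y[6] / p[TAUM];                       /* mg/min to plasma */
    ydot[0] = -p[P1] * (y[0] - p[GB]) - p[SI] * y[1] + ra / p[VG];
    ydot[1] = p[P2] * ((y[4] - p[IB]) - y[1]);
    ydot[2] = p[UBASAL] - y[2] / p[TAUI];
    ydot[3] = (y[2] - y[3]) / p[TAUI];
    ydot[4] = y[3] / p[TAUI] - p[ICLEAR] * y[4];
    ydot[5] = -y[5] / p[TAUM];
    ydot[6] = (y[5] - y[6]) / p[TAUM];
}

/* Impulse events.  mode 0: event block is (time, mg to gut, U to depot),
 * applied verbatim.  mode 1 (closed bolus loop for the trial): block is
 * (time, grams true, counting error); the bolus is computed from the
 * current simulated glucose with the same arithmetic as compute_bolus().
 */
void cc_event(int *n, double *t, double *y)
{
    const double *p = cc_par;
    int nev = (int) p[NEV];
    for (int k = 0; k < nev; k++) {
        const double *e = p + EV0 + 3 * k;
        if (fabs(e[0] - *t) > 1e-7)
            continue;
        if (p[MODE] < 0.5) {
            y[5] += e[1];
            y[2] += e[2];
        } else {
            double che = e[1] - e[2];
            if (che < 0.0) che = 0.0;
            double b = che / p[ICR] + (y[0] - p[GT]) / p[ISF] - p[IOB];
            if (b < 0.0) b = 0.0;
            y[2] += b;
            y[5] += p[FBIO] * e[1] * 1000.0;
        }
    }
}
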