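/* Right-hand side of the coupled growth/resource ODEs, in the form deSolve
 * expects from a compiled model (initializer + derivative function).
 *
 * States: y[0] = N  (population, fold-change units, N(0) = 1)
 *         y[1] = r  (resource, normalized units, r(0) = 1)
 *         y[2] = c  (cumulative gross births, fold-change units; OD proxy)
 *
 * Parameters (in order): lambda_max, d, B, K_r, K_qs, H, r0.
 * K_qs = Inf disables the density factor (resource-only model).
 */
#include <R.h>
#include <math.h>

static double parms[7];
#define LAMBDA parms[0]
#define DEATH  parms[1]
#define BCONS  parms[2]
#define KR     parms[3]
#define KQS    parms[4]
#define HEXP   parms[5]
#define R0     parms[6]

void qsgrowth_initmod(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void qsgrowth_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double N = y[0] > 0.0 ? y[0] : 0.0;
    double r = y[1] > 0.0 ? y[1] : 0.0;
    double res, dens, g;

    if (r <= 0.0) {
        res = 0.0;
    } else {
        /* Monod/Hill factor normalized to 1 at r = r0 */
        double rh  = pow(r,  HEXP);
        double krh = pow(KR, HEXP);
        double r0h = pow(R0, HEXP);
        res = ((r0h + krh) / r0h) * (rh / (rh + krh));
    }
    dens = R_FINITE(KQS) ? KQS / (N + KQS) : 1.0;
    g = LAMBDA * res * dens;

    ydot[0] = y[0] * (g - DEATH);
    ydot[1] = -BCONS * g * N;
    ydot[2] = g * N;
}
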