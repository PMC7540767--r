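/* Right-hand side of the bacteria-phage dynamics for use with deSolve.
 *
 * State layout: y = (b_1..b_n, p_1..p_n).
 * Parameter vector layout (fixed length, padded with zeros so the deSolve
 * init hook can request a known count):
 *   parms[0] eta, [1] beta, [2] delta, [3] alpha, [4] C,
 *   parms[5] steady_tol (<= 0 disables the steady-state root),
 *   parms[6] num_floor  (<= 0 disables the extinction-floor root),
 *   parms[7] imm (constant refuge influx added to every derivative),
 *   parms[8] n (number of strains),
 *   parms[9 .. 8+n]          gamma_i,
 *   parms[9+n .. 8+2n]       omega_i,
 *   parms[9+2n .. 8+4n]      mask over y (1 = watch for floor crossing).
 */
#include <R.h>
#include <math.h>

#define RM_MAXN 4096
#define RM_NPAR (9 + 4 * RM_MAXN)

static double parms[RM_NPAR];

void rm_initmod(void (*odeparms)(int *, double *))
{
    int N = RM_NPAR;
    odeparms(&N, parms);
}

static void rm_rhs(int n, const double *y, double *ydot)
{
    const double eta = parms[0], beta = parms[1], delta = parms[2];
    const double alpha = parms[3], C = parms[4];
    const double imm = parms[7];
    const double *gam = parms + 9;
    const double *om = parms + 9 + n;
    double B = 0.0, P = 0.0;
    int i;

    /* negative values are solver noise of size ~atol around an extinct
     * density; every interaction term is proportional to the density, so
     * evaluating the rhs at max(y, 0) stays continuous and turns a
     * negative excursion into pure restoring influx instead of letting
     * the logistic term blow it up */
    for (i = 0; i < n; i++) {
        B += (y[i] > 0.0) ? y[i] : 0.0;
        P += (y[n + i] > 0.0) ? y[n + i] : 0.0;
    }
    const double crowd = 1.0 - B / C;
    for (i = 0; i < n; i++) {
        const double b = (y[i] > 0.0) ? y[i] : 0.0;
        const double p = (y[n + i] > 0.0) ? y[n + i] : 0.0;
        const double pm = P - p; /* phage not methylated for host i */
        ydot[i] = gam[i] * b * crowd - eta * b * p - eta * om[i] * b * pm
                  - alpha * b + imm;
        ydot[n + i] = eta * beta * b * (p + om[i] * pm) - eta * p * B
                      - delta * p + imm;
    }
}

void rm_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip)
{
    rm_rhs((int) parms[8], y, ydot);
}

/* Two root functions:
 * gout[0] fires when the largest relative rate of change drops below
 *   steady_tol (densities below one individual are scaled absolutely so
 *   strains decaying to extinction do not hold up termination).
 * gout[1] fires when any watched density crosses the numerical extinction
 *   floor from above, so the integrator can be stopped and the density
 *   zeroed before it underflows towards denormals and stalls the solver. */
void rm_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    const int n = (int) parms[8];
    const double steady_tol = parms[5];
    const double num_floor = parms[6];
    const double *mask = parms + 9 + 2 * n;
    double ydot[2 * RM_MAXN];
    int i;

    if (steady_tol > 0.0) {
        double m = 0.0;
        rm_rhs(n, y, ydot);
        for (i = 0; i < 2 * n; i++) {
            double s = fabs(y[i]);
            if (s < 1.0) s = 1.0;
            const double r = fabs(ydot[i]) / s;
            if (r > m) m = r;
        }
        gout[0] = m - steady_tol;
    } else {
        gout[0] = 1.0;
    }

    if (num_floor > 0.0) {
        double mn = R_PosInf;
        for (i = 0; i < 2 * n; i++) {
            if (mask[i] > 0.0 && y[i] < mn) mn = y[i];
        }
        gout[1] = (mn == R_PosInf) ? 1.0 : mn - num_floor;
    } else {
        gout[1] = 1.0;
    }
}
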