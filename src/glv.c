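/* Generalized Lotka-Volterra derivatives for deSolve's compiled-model
 * interface: dx_i/dt = x_i (r_i + sum_j a_ij x_j).
 *
 * Parameters are passed as one double vector c(blowup_cap, r, A, alive)
 * with A column-major, retrieved via deSolve's get_deSolve_gparms so the
 * length can depend on the number of taxa. The root function fires when
 * any abundance reaches blowup_cap, so diverging (finite-time blowup)
 * trajectories stop before the step size collapses. The alive mask pins
 * absent taxa (x = 0) exactly: without it, rounding noise of order 1e-15
 * seeds them and the positive growth rate amplifies the artifact to O(1). */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static SEXP gparms = NULL;

void glv_initmod(void (*odeparms)(int *, double *))
{
    static SEXP (*get_gparms)(void) = NULL;
    if (get_gparms == NULL)
        get_gparms = (SEXP (*)(void))
            R_GetCCallable("deSolve", "get_deSolve_gparms");
    gparms = get_gparms();
}

void glv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int n = *neq;
    double *p = REAL(gparms);
    double *r = p + 1;
    double *A = p + 1 + n;
    double *alive = p + 1 + n + (size_t) n * n;

    /* negative abundances are numerical overshoot of the extinction
     * manifold x = 0; treating them as zero keeps the true dynamics
     * unchanged and prevents spurious divergence to -infinity */
    for (int i = 0; i < n; i++)
        ydot[i] = r[i];
    for (int j = 0; j < n; j++) {
        double xj = (alive[j] != 0.0 && y[j] > 0.0) ? y[j] : 0.0;
        if (xj != 0.0) {
            double *Aj = A + (size_t) n * j;
            for (int i = 0; i < n; i++)
                ydot[i] += Aj[i] * xj;
        }
    }
    for (int i = 0; i < n; i++)
        ydot[i] *= (alive[i] != 0.0 && y[i] > 0.0) ? y[i] : 0.0;
}

void glv_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    int n = *neq;
    double cap = REAL(gparms)[0];
    double m = fabs(y[0]);
    for (int i = 1; i < n; i++)
        if (fabs(y[i]) > m) m = fabs(y[i]);
    gout[0] = cap - m;
}
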