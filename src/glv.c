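/* Right-hand side of the 4-species generalized Lotka-Volterra system,
 * in the deSolve compiled-code convention.
 *
 * parms layout (length 20): k[0..3] growth rates, then the 4x4 interaction
 * matrix alpha in R column-major order, alpha[i,j] = effect of species j on
 * the per-capita growth of species i.  Antibiotic kill windows are handled
 * by the R layer, which substitutes k_kill for the nAB growth rate on the
 * affected segments, so the C side is a plain autonomous gLV.
 */
#include <R.h>

static double parms[20];

void glv_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms);
}

void glv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    for (int i = 0; i < 4; i++) {
        double g = parms[i];
        for (int j = 0; j < 4; j++)
            g += parms[4 + 4 * j + i] * y[j];
        ydot[i] = y[i] * g;
    }
}
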