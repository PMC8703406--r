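/* Compiled right-hand sides for the extremal systems, in the calling
 * convention of deSolve's compiled-code interface.  State layouts match
 * the R-level *_rhs() functions:
 *
 *   normal  (8): x, y, theta, k, h1, h2, h3, h4
 *   natural (7): x, y, theta, k, alpha, h3, h4
 *   reduced (4): alpha, h3, h4, k
 *
 * The curvature k sits at index 3 in every layout, so one root function
 * serves all three systems for the k = 0 section.
 */

#include <R.h>
#include <math.h>

/* no model parameters; deSolve still wants an initializer symbol */
void ngeo_init(void (*odeparms)(int *, double *))
{
}

void ngeo_normal(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double th = y[2], k = y[3];
    double h1 = y[4], h2 = y[5], h3 = y[6], h4 = y[7];

    ydot[0] = h1 * cos(th);
    ydot[1] = h1 * sin(th);
    ydot[2] = h1 * k;
    ydot[3] = h2;
    ydot[4] = -h2 * h3;
    ydot[5] = h1 * h3;
    ydot[6] = h1 * h4;
    ydot[7] = -k * h1 * (k * h3 + h1);
}

void ngeo_natural(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double th = y[2], k = y[3];
    double al = y[4], h3 = y[5], h4 = y[6];
    double ca = cos(al);

    ydot[0] = ca * cos(th);
    ydot[1] = ca * sin(th);
    ydot[2] = k * ca;
    ydot[3] = sin(al);
    ydot[4] = h3;
    ydot[5] = h4 * ca;
    ydot[6] = -k * ca * (k * h3 + ca);
}

void ngeo_reduced(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double al = y[0], h3 = y[1], h4 = y[2], k = y[3];
    double ca = cos(al);

    ydot[0] = h3;
    ydot[1] = h4 * ca;
    ydot[2] = -k * ca * (k * h3 + ca);
    ydot[3] = sin(al);
}

void ngeo_root_k(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    gout[0] = y[3];
}
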