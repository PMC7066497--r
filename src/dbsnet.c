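/* Compiled right-hand side of the seven-population Wilson-Cowan network,
 * in the form deSolve expects (initializer + derivative function).
 *
 * Parameter vector layout (see R/simulate.R, .pack_parms):
 *   [0..10]  w1..w11        connection weight magnitudes
 *   [11]     ext            external drive to DCN (a.u.)
 *   [12..18] tau            per-population time constants (seconds)
 *   [19..24] theta_e, b_e, theta_i, b_i, k_e, k_i
 *   [25]     dbs target     0 = none, otherwise 1-based population index
 *   [26]     dbs amplitude  (a.u., peak of the square wave)
 *   [27]     dbs frequency  (Hz)
 *   [28]     dbs n_max      highest odd harmonic of the series
 *   [29]     dbs onset      (seconds)
 *   [30]     dbs ideal flag 0 = truncated Fourier series, 1 = ideal square
 *
 * State order (fixed everywhere): Cx, Th, nRT, DCN, GPe, GPi, STN.
 */

#include <R.h>
#include <math.h>

#define N_PARMS 31

static double parms[N_PARMS];

void dbsnet_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* sigmoid response: 1/(1+exp(-b(x-theta))) - 1/(1+exp(b*theta)) */
static double zfun(double x, double theta, double b)
{
    return 1.0 / (1.0 + exp(-b * (x - theta))) - 1.0 / (1.0 + exp(b * theta));
}

/* Truncated odd-harmonic square-wave series
 *   A * (4/pi) * sum_{n=1,3,...,n_max} sin(2 pi n f t) / n
 * evaluated with the Chebyshev-like recurrence
 *   sin((n+2)x) = 2 cos(2x) sin(nx) - sin((n-2)x)
 * so each harmonic costs two flops instead of a sin() call. */
static double dbs_forcing(double t)
{
    int target = (int) parms[25];
    double A = parms[26];

    if (target == 0 || A == 0.0)
        return 0.0;

    double f = parms[27];
    int nmax = (int) parms[28];
    double onset = parms[29];
    int ideal = (int) parms[30];

    if (t < onset)
        return 0.0;

    double x = 2.0 * M_PI * f * (t - onset);

    if (ideal) {
        /* sign of sin(x): +A on the first half-period, -A on the second */
        double ph = fmod(f * (t - onset), 1.0);
        if (ph == 0.0 || ph == 0.5)
            return 0.0;
        return (ph < 0.5) ? A : -A;
    }

    double s1 = sin(x), c2 = cos(2.0 * x);
    double sprev = -s1;         /* sin(-x) */
    double scur = s1;
    double total = s1;          /* n = 1 term */
    for (int n = 3; n <= nmax; n += 2) {
        double snext = 2.0 * c2 * scur - sprev;
        sprev = scur;
        scur = snext;
        total += snext / n;
    }
    return A * (4.0 / M_PI) * total;
}

void dbsnet_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *w = parms;        /* w[0] = w1, ..., w[10] = w11 */
    double ext = parms[11];
    const double *tau = parms + 12;
    double theta_e = parms[19], b_e = parms[20];
    double theta_i = parms[21], b_i = parms[22];
    double k_e = parms[23], k_i = parms[24];
    int target = (int) parms[25];

    /* y: 0 Cx, 1 Th, 2 nRT, 3 DCN, 4 GPe, 5 GPi, 6 STN */
    double a[7];
    a[0] = w[0] * y[1];                                          /* Cx  */
    a[1] = w[1] * y[0] - w[2] * y[2] + w[3] * y[3] - w[4] * y[5];/* Th  */
    a[2] = w[5] * y[0];                                          /* nRT */
    a[3] = ext;                                                  /* DCN */
    a[4] = w[6] * y[6] - w[7] * y[4];                            /* GPe */
    a[5] = w[8] * y[6];                                          /* GPi */
    a[6] = w[9] * y[0] - w[10] * y[4];                           /* STN */

    if (target > 0)
        a[target - 1] += dbs_forcing(*t);

    /* excitatory populations: Cx, Th, DCN, STN; inhibitory: nRT, GPe, GPi */
    static const int is_exc[7] = {1, 1, 0, 1, 0, 0, 1};
    for (int i = 0; i < 7; i++) {
        double k = is_exc[i] ? k_e : k_i;
        double z = is_exc[i] ? zfun(a[i], theta_e, b_e)
                             : zfun(a[i], theta_i, b_i);
        ydot[i] = (-y[i] + (k - y[i]) * z) / tau[i];
    }
}
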