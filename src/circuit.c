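/* Gene-circuit ODE right-hand side for deSolve's compiled-model interface.
 *
 * State: y = (m_1..m_G, p_1..p_G), mRNA then protein per gene.
 * Dynamics per gene g:
 *   dm_g/dt = promoter_g * prod_{r: target(r)=g} H_r(p_reg(r)) - mdeg_g * m_g
 *   dp_g/dt = ribo_g * m_g - delta_p * p_g
 * with the Hill response H = P^h/(K^h + P^h) for activation and
 * K^h/(K^h + P^h) for inhibition.
 *
 * Parameters arrive as a flat double vector padded to CIRCUIT_PARMS_LEN:
 *   [0] G (number of live genes)
 *   [1] R (number of live reactions)
 *   [2] delta_p (shared protein degradation rate)
 *   [3 .. 3+3G)   per gene: promoter, ribosomal, mdeg
 *   [3+3G .. )    per reaction: regulator idx (0-based), target idx,
 *                 sign (+1 activation / -1 inhibition), K, h
 */
#include <R.h>
#include <math.h>

#define CIRCUIT_PARMS_LEN 256

static double parms[CIRCUIT_PARMS_LEN];

void circuit_init(void (*odeparms)(int *, double *))
{
    int n = CIRCUIT_PARMS_LEN;
    odeparms(&n, parms);
}

void circuit_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int G = (int) parms[0];
    int R = (int) parms[1];
    double delta_p = parms[2];
    const double *gene = parms + 3;       /* 3 per gene */
    const double *reac = parms + 3 + 3 * G; /* 5 per reaction */
    int g, r;

    for (g = 0; g < G; g++) {
        double promoter = gene[3 * g];
        double ribo     = gene[3 * g + 1];
        double mdeg     = gene[3 * g + 2];
        double m = y[g];
        double p = y[G + g];
        double trans = promoter;
        for (r = 0; r < R; r++) {
            if ((int) reac[5 * r + 1] == g) {
                int reg = (int) reac[5 * r];
                double sign = reac[5 * r + 2];
                double K = reac[5 * r + 3];
                double h = reac[5 * r + 4];
                double preg = y[G + reg];
                if (preg < 0.0) preg = 0.0;
                double ph = pow(preg, h);
                double kh = pow(K, h);
                double denom = kh + ph;
                double H = (denom > 0.0) ? ((sign > 0.0) ? ph / denom
                                                         : kh / denom)
                                         : ((sign > 0.0) ? 0.0 : 1.0);
                trans *= H;
            }
        }
        ydot[g] = trans - mdeg * m;
        ydot[G + g] = ribo * m - delta_p * p;
    }
}
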