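/* Compiled rate laws for the NFBLB three-node network, in the layout
 * deSolve expects for compiled models.
 *
 * parms layout (15): k_IA, K_IA, k_BA, K_BA, k_AB, K_AB, k_FBB, K_FBB,
 *                    k_AC, K_AC, k_FCC, K_FCC, I, F_B, F_C
 */
#include <R.h>

static double parms[15];

void nfblb_init(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

void nfblb_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double A = y[0], B = y[1], C = y[2];
    const double k_IA = parms[0],  K_IA = parms[1];
    const double k_BA = parms[2],  K_BA = parms[3];
    const double k_AB = parms[4],  K_AB = parms[5];
    const double k_FBB = parms[6], K_FBB = parms[7];
    const double k_AC = parms[8],  K_AC = parms[9];
    const double k_FCC = parms[10], K_FCC = parms[11];
    const double I = parms[12], FB = parms[13], FC = parms[14];

    ydot[0] = I * k_IA * (1.0 - A) / ((1.0 - A) + K_IA)
            - B * k_BA * A / (A + K_BA);
    ydot[1] = A * k_AB * (1.0 - B) / ((1.0 - B) + K_AB)
            - FB * k_FBB * B / (B + K_FBB);
    ydot[2] = A * k_AC * (1.0 - C) / ((1.0 - C) + K_AC)
            - FC * k_FCC * C / (C + K_FCC);
}
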