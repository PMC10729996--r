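/* Compiled right-hand side of the 9-reaction / 8-component iron-trafficking
 * ODE system, in the form expected by deSolve's compiled-model interface.
 *
 * State vector y (local concentrations, uM):
 *   y[0] FC, y[1] CIA, y[2] F2, y[3] F3, y[4] FM, y[5] FS, y[6] MP, y[7] O2
 *
 * Parameter vector (length 65):
 *   [0..8]   k_cyt, k_mit, k_vac, k_cia, k_isu, k_mp, k_O2, k_res, k_23
 *   [9..15]  K_cyt(IRON), K_mit(FC), K_vac(FC), K_cia(FC), K_23(F2),
 *            K_isu(FM), K_res(O2)
 *   [16]     [O2]_sp   [17] alpha_cell   [18] [IRON]   [19] [OXYGEN]
 *   [20..22] f_cyt, f_mit, f_vac
 *   [23..64] 7 regulator blocks of 6 (reactions cyt, mit, vac, cia, mp,
 *            O2, 23): active, sensor index (1..8), n, SP, k_reg, k_unreg
 */

#include <math.h>

#define NPAR 65

static double parms[NPAR];

void ferrosim_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

/* overflow-safe soft Heaviside valve, Eq of the logistic regulator */
static double soft_heaviside(double kreg, double kunreg, double n,
                             double sp, double sen)
{
    double x = n * (sp - sen);
    if (x > 700.0)  return kunreg;          /* valve fully closed */
    if (x < -700.0) return kreg + kunreg;   /* valve fully open   */
    return kreg / (1.0 + exp(x)) + kunreg;
}

void ferrosim_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double k[9];
    int i;
    /* map of regulator block -> index into k[] */
    static const int reg_k[7] = {0, 1, 2, 3, 5, 6, 8};

    for (i = 0; i < 9; i++) k[i] = parms[i];

    for (i = 0; i < 7; i++) {
        const double *b = parms + 23 + 6 * i;
        if (b[0] > 0.5) {
            int sen = (int) b[1] - 1;
            k[reg_k[i]] = soft_heaviside(b[4], b[5], b[2], b[3], y[sen]);
        }
    }

    {
        const double Kcyt = parms[9],  Kmit = parms[10], Kvac = parms[11];
        const double Kcia = parms[12], K23 = parms[13],  Kisu = parms[14];
        const double Kres = parms[15];
        const double sp = parms[16], alpha = parms[17];
        const double IRON = parms[18], OXYGEN = parms[19];
        const double fc = parms[20], fm = parms[21], fv = parms[22];

        /* rate laws evaluate on clipped (nonnegative) concentrations;
         * the integrator may transiently produce tiny negatives */
        double FC = y[0] > 0 ? y[0] : 0, F2 = y[2] > 0 ? y[2] : 0;
        double FM = y[4] > 0 ? y[4] : 0, FS = y[5] > 0 ? y[5] : 0;
        double O2 = y[7] > 0 ? y[7] : 0;

        double Rcyt = k[0] * IRON / (Kcyt + IRON);
        double Rmit = k[1] * FC / (Kmit + FC);
        double Rvac = k[2] * FC / (Kvac + FC);
        double Rcia = k[3] * FC / (Kcia + FC);
        double Risu = k[4] * FM / (Kisu + FM) * (sp / (sp + O2));
        double Rmp  = k[5] * FM * O2;
        double RO2  = k[6] * (OXYGEN - y[7]);   /* signed net exchange */
        double Rres = k[7] * FS * O2 / (Kres + O2);
        double R23  = k[8] * F2 / (K23 + F2) * OXYGEN;

        ydot[0] = Rcyt - Rvac - Rmit - Rcia - alpha * y[0];
        ydot[1] = Rcia - alpha * y[1];
        ydot[2] = (fc / fv) * Rvac - R23 - alpha * y[2];
        ydot[3] = R23 - alpha * y[3];
        ydot[4] = (fc / fm) * Rmit - Risu - Rmp - alpha * y[4];
        ydot[5] = Risu - alpha * y[5];
        ydot[6] = Rmp - alpha * y[6];
        ydot[7] = RO2 - Rmp - Rres - alpha * y[7];
    }
}
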