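/* Right-hand side of the discretised five-field invasion model, in the
 * layout deSolve's compiled-function interface expects.
 *
 * State vector: interleaved per grid point, (S, T_A, T_M, L, M) at x_0,
 * then at x_1, ... This keeps the Jacobian banded (bandwidth <= 8), which
 * lsode exploits with an internally generated banded Jacobian.
 *
 * Transport uses the variable-diffusion central stencil
 *   d/dx(D du/dx)|_r ~ [(D_{r-1}+D_r) u_{r-1}
 *                       - (D_{r-1}+2D_r+D_{r+1}) u_r
 *                       + (D_r+D_{r+1}) u_{r+1}] / (2 h^2)
 * with D = Delta_T (1-M) for the tumour fields and D = 1 for acid.
 * Zero-flux boundaries are realised by ghost-point reflection of both u
 * and D (u_{-1}=u_1, D_{-1}=D_1, and symmetrically on the right), which
 * preserves the stencil's discrete conservation property.
 *
 * A linear restoring term -lambda*u is added wherever a field has gone
 * negative, steering it back to zero without breaking the smoothness the
 * implicit integrator relies on.
 *
 * The logistic source of each cell field (S, T_A, T_M) is suppressed where
 * that field lies below a small extinction floor. Without this, integrator
 * noise at the absolute-tolerance level seeds vanishingly small "atto"
 * populations in regions the fields cannot physically reach (e.g. beyond a
 * D = 0 intact-matrix wall), and those seeds grow exponentially once acid
 * has cleared the stroma there. The floor (default 1e-6, far below any
 * front-detection threshold) must exceed the absolute tolerance.
 */

#include <R.h>

static double parms[12];

#define NPTS   ((int) parms[0])
#define HSP    parms[1]
#define DELTA  parms[2]
#define RHO_T  parms[3]
#define DELTAT parms[4]
#define RHO_L  parms[5]
#define KAPPA  parms[6]
#define C_S    parms[7]
#define C_MA   parms[8]
#define C_AM   parms[9]
#define LAMBDA parms[10]
#define FLOOR_ parms[11]

void invasion_init(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

/* C1 smoothstep gate: 0 below the floor, 1 above twice the floor. A hard
 * indicator would make Newton's method thrash on the creeping front. */
static double growth_gate(double u)
{
    if (FLOOR_ <= 0.0) return 1.0;
    if (u <= FLOOR_) return 0.0;
    if (u >= 2.0 * FLOOR_) return 1.0;
    const double s = u / FLOOR_ - 1.0;
    return s * s * (3.0 - 2.0 * s);
}

void invasion_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const int n = NPTS;
    const double h2inv = 1.0 / (HSP * HSP);

    for (int r = 0; r < n; r++) {
        const int i = 5 * r;
        /* ghost-point reflection at the domain ends */
        const int lm = (r == 0) ? 5 : 5 * (r - 1);
        const int rp = (r == n - 1) ? 5 * (n - 2) : 5 * (r + 1);

        const double S  = y[i],     TA = y[i + 1], TM = y[i + 2];
        const double L  = y[i + 3], M  = y[i + 4];

        const double Dc = 1.0 - M;
        const double Dl = 1.0 - y[lm + 4];
        const double Dr = 1.0 - y[rp + 4];

        const double diffTA = ((Dl + Dc) * y[lm + 1]
                               - (Dl + 2.0 * Dc + Dr) * TA
                               + (Dc + Dr) * y[rp + 1]) * 0.5 * h2inv;
        const double diffTM = ((Dl + Dc) * y[lm + 2]
                               - (Dl + 2.0 * Dc + Dr) * TM
                               + (Dc + Dr) * y[rp + 2]) * 0.5 * h2inv;
        const double diffL  = (y[lm + 3] - 2.0 * L + y[rp + 3]) * h2inv;

        const double gS  = growth_gate(S);
        const double gTA = growth_gate(TA);
        const double gTM = growth_gate(TM);

        ydot[i]     = gS * S * (1.0 - S) - DELTA * S * L;
        ydot[i + 1] = gTA * RHO_T * TA * (1.0 - C_S * S - TA - C_MA * TM)
                      + DELTAT * diffTA;
        ydot[i + 2] = gTM * RHO_T * TM * (1.0 - C_S * S - C_AM * TA - TM)
                      + DELTAT * diffTM;
        ydot[i + 3] = RHO_L * (TA - L) + diffL;
        ydot[i + 4] = -KAPPA * TM * M;

        for (int k = 0; k < 5; k++)
            if (y[i + k] < 0.0)
                ydot[i + k] -= LAMBDA * y[i + k];
    }
}
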