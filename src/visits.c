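/* Compiled right-hand side of the three-tier visit system for deSolve.
 *
 * Parameter order matches param_names() on the R side:
 * r_f r_s r_t m_f m_s m_t c_f c_s c_t alpha beta eta
 */
#include <R.h>

static double parms[12];

#define R_F   parms[0]
#define R_S   parms[1]
#define R_T   parms[2]
#define M_F   parms[3]
#define M_S   parms[4]
#define M_T   parms[5]
#define C_F   parms[6]
#define C_S   parms[7]
#define C_T   parms[8]
#define ALPHA parms[9]
#define BETA  parms[10]
#define ETA   parms[11]

void tierdyn_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void tierdyn_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    /* solver iterates may undershoot zero by ~atol; evaluate the field at
       the clipped state, as the R reference implementation does */
    double x = y[0] > 0 ? y[0] : 0;
    double yy = y[1] > 0 ? y[1] : 0;
    double z = y[2] > 0 ? y[2] : 0;

    ydot[0] = x * (R_F - (R_F / M_F) * x - ALPHA - ETA - C_F);
    ydot[1] = yy * (R_S - (R_S / M_S) * yy - BETA - C_S) + ALPHA * x;
    ydot[2] = z * (R_T - (R_T / M_T) * z - C_T) + ETA * x + BETA * yy;
}
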