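/* Six-state kinetic model of aerated batch yeast fermentation on
 * sucrose/glucose/fructose + urea, with smooth Leaky-ReLU-style gating.
 *
 * This file mirrors the reference R implementation (R/kinetics.R); the R
 * functions define the model semantics, this C version is what the ODE
 * solver and the sensitivity system call in hot loops.
 *
 * Parameter vector layout (length 33), kept in lockstep with
 * .ferm_parms_vector() on the R side:
 *  [0..21] kinetic parameters:
 *    0 mu_max_Et  1 mu_max_G  2 mu_max_R  3 mu_max_postG
 *    4 m_G        5 m_R       6 alpha_S
 *    7 K_G        8 K_R       9 K_R_postG 10 K_S  11 K_Et
 *   12 K_i_Et    13 K_inh_AF
 *   14 Y_AF_S    15 Y_Et_G   16 Y_Et_R   17 Y_Et_X
 *   18 Y_cEt_X   19 Y_G_X    20 Y_R_X    21 Y_X_Ur
 *  [22] gamma  [23] epsilon  [24] threshold
 *  [25] F_i  [26] G_i  [27] R_i  [28] S_i  [29] U_i  [30] dVdt
 *  [31] flag: fructose ethanol-yield denominator (0 = Y_Et_G as printed,
 *       1 = Y_Et_R)
 *  [32] flag: ethanol production gate argument (0 = R, 1 = G + R)
 *
 * State layout (length 7): X, G, R, S, U, Et, V.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 7
#define N_KIN 22
#define N_PARMS 33

static double leaky_gate(double z, double gamma, double eps)
{
    double num = (z > gamma * z) ? z : gamma * z;
    return num / sqrt(z * z + eps);
}

/* rates[0..8]  = r_X, r_G, r_R, r_S, r_gG, r_gR, r_Ur, r_Et, r_Et_c
 * rates[9..12] = mu_G, mu_R, mu_Et, mu_X  */
static void ferm_core(const double *y, const double *p,
                      double *dy, double *rates)
{
    double X = y[0], G = y[1], R = y[2], S = y[3], U = y[4], Et = y[5],
        V = y[6];
    double gamma = p[22], eps = p[23], thr = p[24];
    double Fi = p[25], dVdt = p[30];

    /* catabolite-repression blend of fructose parameters (pure function
     * of instantaneous G; "appear" gate on glucose depletion) */
    double s_post = leaky_gate(thr - G, gamma, eps);
    double mu_max_R_eff = p[2] + s_post * (p[3] - p[2]);
    double K_R_eff = p[8] + s_post * (p[9] - p[8]);

    double inh_Et = p[12] / (p[12] + Et);           /* K_i_Et */
    double mu_G = p[1] * G / (p[7] + G) * inh_Et;
    double mu_R = mu_max_R_eff * R / (K_R_eff + R) * inh_Et;
    double AF = G + R;
    double mu_Et = p[0] * Et / (p[11] + Et) * p[13] / (p[13] + AF);
    double mu_X = mu_G + mu_R + mu_Et;

    double eth_den = (p[31] > 0.5) ? p[16] : p[15]; /* Y_Et_R vs Y_Et_G */
    double gate_G = leaky_gate(G - thr, gamma, eps);
    double gate_R = leaky_gate(R - thr, gamma, eps);
    double gate_U = leaky_gate(U - thr, gamma, eps);
    double gate_Et = (p[32] > 0.5) ? leaky_gate(AF - thr, gamma, eps)
                                   : gate_R;

    double r_X = mu_X * X;
    double r_S = p[6] * S / (S + p[10]) * X;
    double r_G = (p[19] * mu_G * X + p[4] * X +
                  mu_X * X * p[17] / p[15]) * gate_G;
    double r_R = (p[20] * mu_R * X + p[5] * X +
                  mu_X * X * p[17] / eth_den) * gate_R;
    double r_Ur = mu_X / p[21] * X * gate_U;
    double r_Et = p[17] * mu_X * X * gate_Et;
    double r_Et_c = p[18] * mu_Et * X;

    /* hard clamp: no consumption once a pool is at or below zero */
    if (G <= 0.0) r_G = 0.0;
    if (R <= 0.0) r_R = 0.0;
    if (S <= 0.0) r_S = 0.0;
    if (U <= 0.0) r_Ur = 0.0;
    if (Et <= 0.0) r_Et_c = 0.0;

    double r_gG = r_S * p[14];
    double r_gR = r_S * p[14];

    dy[0] = (r_X * V - X * dVdt) / V;
    dy[1] = (Fi * p[26] + V * (r_gG - r_G) - G * dVdt) / V;
    dy[2] = (Fi * p[27] + V * (r_gR - r_R) - R * dVdt) / V;
    dy[3] = (Fi * p[28] - V * r_S - S * dVdt) / V;
    dy[4] = (Fi * p[29] - V * r_Ur - U * dVdt) / V;
    dy[5] = (V * (r_Et - r_Et_c) - Et * dVdt) / V;
    dy[6] = dVdt;

    if (rates) {
        rates[0] = r_X;  rates[1] = r_G;  rates[2] = r_R;
        rates[3] = r_S;  rates[4] = r_gG; rates[5] = r_gR;
        rates[6] = r_Ur; rates[7] = r_Et; rates[8] = r_Et_c;
        rates[9] = mu_G; rates[10] = mu_R; rates[11] = mu_Et;
        rates[12] = mu_X;
    }
}

/* ---- deSolve compiled-model interface ---- */

static double parms_c[N_PARMS];

void hybridferm_initparms(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms_c);
}

void hybridferm_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    (void) neq; (void) t; (void) yout; (void) ip;
    ferm_core(y, parms_c, ydot, NULL);
}

/* ---- .Call interface for direct evaluation from R ---- */

SEXP C_ferm_rhs(SEXP y_, SEXP p_)
{
    if (LENGTH(y_) != N_STATE || LENGTH(p_) != N_PARMS)
        error("ferm_rhs: bad state/parameter vector length");
    SEXP out = PROTECT(allocVector(REALSXP, N_STATE + 13));
    double rates[13];
    ferm_core(REAL(y_), REAL(p_), REAL(out), rates);
    for (int i = 0; i < 13; i++) REAL(out)[N_STATE + i] = rates[i];
    UNPROTECT(1);
    return out;
}

/* Central-difference Jacobians of the smooth RHS:
 * returns list(Jx = dfdy [7 x 7], Jp = dfdtheta [7 x 22]). */
SEXP C_ferm_jac(SEXP y_, SEXP p_)
{
    if (LENGTH(y_) != N_STATE || LENGTH(p_) != N_PARMS)
        error("ferm_jac: bad state/parameter vector length");
    const double rel = 6e-6;    /* ~ cbrt(eps) for central differences */
    double y[N_STATE], p[N_PARMS];
    double fp[N_STATE], fm[N_STATE];
    for (int i = 0; i < N_STATE; i++) y[i] = REAL(y_)[i];
    for (int i = 0; i < N_PARMS; i++) p[i] = REAL(p_)[i];

    SEXP Jx = PROTECT(allocMatrix(REALSXP, N_STATE, N_STATE));
    SEXP Jp = PROTECT(allocMatrix(REALSXP, N_STATE, N_KIN));

    for (int j = 0; j < N_STATE; j++) {
        double save = y[j];
        double h = rel * (fabs(save) > 1.0 ? fabs(save) : 1.0);
        y[j] = save + h; ferm_core(y, p, fp, NULL);
        y[j] = save - h; ferm_core(y, p, fm, NULL);
        y[j] = save;
        for (int i = 0; i < N_STATE; i++)
            REAL(Jx)[i + N_STATE * j] = (fp[i] - fm[i]) / (2.0 * h);
    }
    for (int j = 0; j < N_KIN; j++) {
        double save = p[j];
        double h = rel * (fabs(save) > 1e-6 ? fabs(save) : 1e-6);
        p[j] = save + h; ferm_core(y, p, fp, NULL);
        p[j] = save - h; ferm_core(y, p, fm, NULL);
        p[j] = save;
        for (int i = 0; i < N_STATE; i++)
            REAL(Jp)[i + N_STATE * j] = (fp[i] - fm[i]) / (2.0 * h);
    }

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, Jx);
    SET_VECTOR_ELT(out, 1, Jp);
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, mkChar("Jx"));
    SET_STRING_ELT(nm, 1, mkChar("Jp"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_ferm_rhs", (DL_FUNC) &C_ferm_rhs, 2},
    {"C_ferm_jac", (DL_FUNC) &C_ferm_jac, 2},
    {NULL, NULL, 0}
};

void R_init_hybridferm(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
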