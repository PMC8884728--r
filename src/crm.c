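/* Compiled right-hand side for the batch consumer-resource model:
 *   dN_a/dt =  N_a * sum_i C_ai R_i
 *   dR_i/dt = -R_i * sum_a C_ai N_a
 * Parameters (passed from R): [nN, nR, epsilon, vec(C) column-major].
 * The root function stops integration when total resources fall to
 * epsilon.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double *crm_parms = NULL;
static int crm_nparms = 0;

void crm_initmod(void (*odeparms)(int *, double *)) {
  DL_FUNC get_deSolve_gparms = R_GetCCallable("deSolve", "get_deSolve_gparms");
  SEXP gparms = ((SEXP (*)(void)) get_deSolve_gparms)();
  crm_nparms = LENGTH(gparms);
  crm_parms = REAL(gparms);
}

void crm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  int nN = (int) crm_parms[0];
  int nR = (int) crm_parms[1];
  const double *C = crm_parms + 3; /* nN x nR, column-major */
  const double *N = y;
  const double *R = y + nN;

  for (int a = 0; a < nN; a++) {
    double growth = 0.0;
    for (int i = 0; i < nR; i++) growth += C[a + (size_t) i * nN] * R[i];
    ydot[a] = N[a] * growth;
  }
  for (int i = 0; i < nR; i++) {
    double uptake = 0.0;
    const double *col = C + (size_t) i * nN;
    for (int a = 0; a < nN; a++) uptake += col[a] * N[a];
    ydot[nN + i] = -R[i] * uptake;
  }
}

void crm_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip) {
  int nN = (int) crm_parms[0];
  int nR = (int) crm_parms[1];
  double eps = crm_parms[2];
  double total = 0.0;
  for (int i = 0; i < nR; i++) total += y[nN + i];
  gout[0] = total - eps;
}
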