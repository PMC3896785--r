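#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void nfblb_init(void (*odeparms)(int *, double *));
void nfblb_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"nfblb_init",   (DL_FUNC) &nfblb_init,   1},
    {"nfblb_derivs", (DL_FUNC) &nfblb_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_kinmotif(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE); /* deSolve looks routines up by name */
}
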