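#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ifndyn_initmod(void (*odeparms)(int *, double *));
void ifndyn_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);
void ifndyn_rhs_eval(double *t, double *y, double *pp, double *ydot);

static const R_CMethodDef CEntries[] = {
    {"ifndyn_initmod", (DL_FUNC) &ifndyn_initmod, 1},
    {"ifndyn_derivs",  (DL_FUNC) &ifndyn_derivs,  6},
    {"ifndyn_rhs_eval", (DL_FUNC) &ifndyn_rhs_eval, 4},
    {NULL, NULL, 0}
};

void R_init_ifndyn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
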