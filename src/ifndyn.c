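/* Right-hand side of the IFNalpha JAK/STAT signal transduction model.
 *
 * States (41), natural scale (molecules/cell; promoter occupancy in a.u.):
 *  0 Rec        1 aRecIFN    2 STAT1c   3 STAT1n   4 STAT2c   5 STAT2n
 *  6 IRF9c      7 IRF9n      8 pSTAT1dimc  9 pSTAT1dimn
 * 10 pSTAT1pSTAT2c  11 pSTAT1pSTAT2n  12 ISGF3c  13 ISGF3n
 * 14 OccGASbs  15 OccGISREbs
 * 16-22 mRNAs: STAT1, STAT2, IRF9, IRF2, USP18, SOCS1, SOCS3
 * 23 USP18  24 SOCS1  25 SOCS3  26 IRF2
 * 27-40 translation delay-chain intermediates (2 per gene, same gene order)
 *
 * Parameters (73) are documented in R/parameters.R (ifndyn_c_parm_names).
 * Receptor-variant structure is selected by switch parameters (0/1), so a
 * single compiled RHS serves all four receptor-degradation variants.
 */
#include <R.h>

#define NPAR 73
static double p[NPAR];

void ifndyn_initmod(void (*odeparms)(int *, double *))
{
    int N = NPAR;
    odeparms(&N, p);
}

static void rhs_core(double t, const double *y, double *ydot,
                     const double *p)
{
    const double IFN        = p[0];
    const double BindIFN    = p[1],  degRec   = p[2],  recycRec = p[3];
    const double KiSOCS     = p[4];
    const double VdegSOCS1  = p[5],  KmdegSOCS1 = p[6];
    const double VdegCoop   = p[7],  KmdegCoop  = p[8];
    const double actSTAT1   = p[9],  actSTAT12  = p[10];
    const double KmactSTAT1 = p[11], KmactSTAT2 = p[12];
    const double KiUSP18    = p[13], formISGF3  = p[14];
    const double impComplex = p[15], impMono = p[16], impIRF9 = p[17],
                 expMono    = p[18];
    const double dissSTAT   = p[19], dissISGF3 = p[20];
    const double bindGAS    = p[21], KmGAS = p[22], offGAS = p[23];
    const double bindISREhet = p[24], bindISREisgf3 = p[25], KmISRE = p[26],
                 offISRE    = p[27];
    const double degSTAT1   = p[28], degSTAT2 = p[29], degIRF9 = p[30];
    const double *synmRNA   = p + 31;   /* 7 induced transcription Vmax */
    const double KiIRF2     = p[38];
    const double *degmRNA   = p + 39;   /* 7 mRNA degradation rates */
    const double *syn       = p + 46;   /* 7 translation / chain rates */
    const double synthOE    = p[53];
    const double VdegUSP18  = p[54], KmdegUSP18 = p[55];
    const double synthRec   = p[56];
    const double *basal     = p + 57;   /* 7 basal transcription rates */
    const double degUSP18   = p[64], degSOCS1 = p[65], degSOCS3 = p[66],
                 degIRF2    = p[67];
    const double swS1   = p[68], swU18 = p[69], swCoop = p[70];
    const double kd     = p[71], swOE  = p[72];

    const double Rec = y[0], aRec = y[1];
    const double S1c = y[2], S1n = y[3], S2c = y[4], S2n = y[5];
    const double I9c = y[6], I9n = y[7];
    const double dimc = y[8], dimn = y[9], hetc = y[10], hetn = y[11];
    const double isgc = y[12], isgn = y[13];
    const double occG = y[14], occI = y[15];
    const double USP18 = y[23], SOCS1 = y[24], SOCS3 = y[25], IRF2 = y[26];

    /* feedback inhibition factors */
    const double fU = 1.0 / (1.0 + USP18 / KiUSP18);
    const double fS = 1.0 / (1.0 + (SOCS1 + SOCS3) / KiSOCS);

    /* receptor module */
    const double vact = BindIFN * IFN * Rec * fS;
    const double vdegS1  = swS1  * VdegSOCS1 * SOCS1 / (KmdegSOCS1 + SOCS1) * aRec;
    const double vdegU18 = swU18 * VdegUSP18 * USP18 / (KmdegUSP18 + USP18) * aRec;
    const double vdegCo  = swCoop * VdegCoop *
        (SOCS1 / (KmdegCoop + SOCS1)) * (USP18 / (KmdegCoop + USP18)) * aRec;

    /* lumped phosphorylation/dimerization at the active receptor; STAT1 and
     * STAT2 compete for receptor docking (shared Michaelis denominator) */
    const double den  = 1.0 + S1c / KmactSTAT1 + S2c / KmactSTAT2;
    const double vdim = actSTAT1  * aRec * S1c * S1c * fU / den;
    const double vhet = actSTAT12 * aRec * S1c * S2c * fU / den;
    const double visg = formISGF3 * hetc * I9c;

    ydot[0] = synthRec - degRec * Rec - vact + recycRec * aRec;
    ydot[1] = vact - recycRec * aRec - vdegS1 - vdegU18 - vdegCo;

    ydot[2] = syn[0] * y[28] - degSTAT1 * S1c - 2.0 * vdim - vhet
              - impMono * S1c + expMono * S1n;
    ydot[3] = impMono * S1c - expMono * S1n
              + 2.0 * dissSTAT * dimn + dissSTAT * hetn + dissISGF3 * isgn;
    ydot[4] = syn[1] * y[30] - degSTAT2 * S2c - vhet
              - impMono * S2c + expMono * S2n;
    ydot[5] = impMono * S2c - expMono * S2n
              + dissSTAT * hetn + dissISGF3 * isgn;
    ydot[6] = syn[2] * y[32] - degIRF9 * I9c - visg
              - impIRF9 * I9c + expMono * I9n;
    ydot[7] = impIRF9 * I9c - expMono * I9n + dissISGF3 * isgn;

    ydot[8]  = vdim - impComplex * dimc;
    ydot[9]  = impComplex * dimc - dissSTAT * dimn;
    ydot[10] = vhet - visg - impComplex * hetc;
    ydot[11] = impComplex * hetc - dissSTAT * hetn;
    ydot[12] = visg - impComplex * isgc;
    ydot[13] = impComplex * isgc - dissISGF3 * isgn;

    ydot[14] = bindGAS * dimn / (KmGAS + dimn) - offGAS * occG;
    ydot[15] = bindISREhet * hetn / (KmISRE + hetn)
             + bindISREisgf3 * isgn / (KmISRE + isgn) - offISRE * occI;

    /* transcription: combined GAS+ISRE occupancy drives the feedback genes,
     * GAS occupancy drives SOCS3; IRF2 represses SOCS1 transcription */
    ydot[16] = basal[0] + synmRNA[0] * occI - degmRNA[0] * y[16];
    ydot[17] = basal[1] + synmRNA[1] * occI - degmRNA[1] * y[17];
    ydot[18] = basal[2] + synmRNA[2] * occI - degmRNA[2] * y[18];
    ydot[19] = basal[3] + synmRNA[3] * occI - degmRNA[3] * y[19];
    /* USP18 transcription requires cooperative occupancy of its ISRE/GAS
     * element array (third-order in combined occupancy) */
    ydot[20] = kd * (basal[4] + swOE * synthOE + synmRNA[4] * occI * occI * occI)
               - degmRNA[4] * y[20];
    ydot[21] = basal[5] + synmRNA[5] * occI / (1.0 + IRF2 / KiIRF2)
               - degmRNA[5] * y[21];
    ydot[22] = basal[6] + synmRNA[6] * occG - degmRNA[6] * y[22];

    /* feedback proteins, fed by the end of their delay chain */
    ydot[23] = syn[4] * y[36] - degUSP18 * USP18;
    ydot[24] = syn[5] * y[38] - degSOCS1 * SOCS1;
    ydot[25] = syn[6] * y[40] - degSOCS3 * SOCS3;
    ydot[26] = syn[3] * y[34] - degIRF2 * IRF2;

    /* linear translation delay chains: entry at syn_g * mRNA, steps at syn_g */
    {
        int g;
        /* gene order: STAT1 STAT2 IRF9 IRF2 USP18 SOCS1 SOCS3 */
        for (g = 0; g < 7; g++) {
            const int m = 16 + g, c1 = 27 + 2 * g, c2 = c1 + 1;
            ydot[c1] = syn[g] * (y[m] - y[c1]);
            ydot[c2] = syn[g] * (y[c1] - y[c2]);
        }
    }
}

void ifndyn_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    rhs_core(*t, y, ydot, p);
}

/* direct RHS evaluation with an explicit parameter vector (.C interface),
 * used by the forward-sensitivity machinery */
void ifndyn_rhs_eval(double *t, double *y, double *pp, double *ydot)
{
    rhs_core(*t, y, ydot, pp);
}
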