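/* Compiled right-hand side of the Crohn's disease immune-network ODE.
 *
 * Used by deSolve (dllname = "cdqsp", initfunc = "cd_initmod",
 * func = "cd_derivs", initforc = "cd_initforc").
 *
 * Parameter vector: the 91 mechanistic parameters in the order of
 * cd_param_names(), followed by per-target antibody dissociation constants
 * Kd (nM) and cytokine molecular weights (g/mol) for TNFa, IL-6, IL-12,
 * IL-23.
 *
 * Forcings: binding-site concentration B(t) (nM = stoichiometry x antibody
 * nM, summed over drugs) for TNFa, IL-6, IL-12, IL-23, in that order.
 * The free fraction of each targetable cytokine is the quasi-equilibrium
 * solution of  L^2 + (Kd + B - T) L - Kd T = 0  with T the total cytokine
 * in nM; wherever that cytokine appears as a modifier its concentration is
 * multiplied by the free fraction.
 */

#include <R.h>
#include <math.h>

#define NPARMS 101
static double parms[NPARMS];
static double forcs[4];

#define s_Th0          parms[0]
#define kdeg_Th0       parms[1]
#define kdif_Th1       parms[2]
#define Km_IL12_Th1    parms[3]
#define kdeg_Th1       parms[4]
#define kdif_Th17      parms[5]
#define Km_IL23_Th17   parms[6]
#define a_IL6_Th17     parms[7]
#define Km_IL6_Th17    parms[8]
#define kdeg_Th17      parms[9]
#define s_Treg         parms[10]
#define kdeg_Treg      parms[11]
#define Km_Treg        parms[12]
#define s_NK1          parms[13]
#define kact_NK1       parms[14]
#define Km_IL12_NK1    parms[15]
#define kdeg_NK1       parms[16]
#define s_iDC          parms[17]
#define kdeg_iDC       parms[18]
#define kact_DC        parms[19]
#define Km_TNF_DC      parms[20]
#define a_IL6_DC       parms[21]
#define Km_IL6_DC      parms[22]
#define kdeg_eDC       parms[23]
#define s_M0           parms[24]
#define kdeg_M0        parms[25]
#define kact_M         parms[26]
#define Km_TNF_M       parms[27]
#define a_IFN_M        parms[28]
#define Km_IFN_M       parms[29]
#define kdeg_M1        parms[30]
#define s_Neu          parms[31]
#define kdeg_Neu       parms[32]
#define kact_Neu       parms[33]
#define Km_TNF_Neu     parms[34]
#define a_IL17_Neu     parms[35]
#define Km_IL17_Neu    parms[36]
#define kdeg_Neua      parms[37]
#define b_TNF          parms[38]
#define p_TNF          parms[39]
#define w_M1_TNF       parms[40]
#define w_Neu_TNF      parms[41]
#define kdeg_TNF       parms[42]
#define b_IL6          parms[43]
#define p_IL6          parms[44]
#define w_M1_IL6       parms[45]
#define w_Neu_IL6      parms[46]
#define c0_IL6         parms[47]
#define Km_TNF_IL6     parms[48]
#define a_IL17_IL6     parms[49]
#define Km_IL17_IL6    parms[50]
#define kdeg_IL6       parms[51]
#define b_IL8          parms[52]
#define p_IL8          parms[53]
#define w_M1_IL8       parms[54]
#define w_Neu_IL8      parms[55]
#define kdeg_IL8       parms[56]
#define b_IL12         parms[57]
#define p_IL12         parms[58]
#define w_M1_IL12      parms[59]
#define w_Neu_IL12     parms[60]
#define kdeg_IL12      parms[61]
#define b_IL17         parms[62]
#define p_IL17         parms[63]
#define kdeg_IL17      parms[64]
#define b_IL22         parms[65]
#define p_IL22         parms[66]
#define kdeg_IL22      parms[67]
#define b_IL23         parms[68]
#define p_IL23         parms[69]
#define w_M1_IL23      parms[70]
#define w_Neu_IL23     parms[71]
#define kdeg_IL23      parms[72]
#define b_IFN          parms[73]
#define p_IFN          parms[74]
#define w_NK_IFN       parms[75]
#define kdeg_IFN       parms[76]
#define b_GM           parms[77]
#define p_GM           parms[78]
#define w_M1_GM        parms[79]
#define w_Neu_GM       parms[80]
#define kdeg_GM        parms[81]
#define b_CRP          parms[82]
#define p_CRP          parms[83]
#define Km_IL6_CRP     parms[84]
#define kdeg_CRP       parms[85]
#define b_FCP          parms[86]
#define p_FCP          parms[87]
#define Km_Neua_FCP    parms[88]
#define Km_IL8_FCP     parms[89]
#define c0_FCP         parms[90]
#define kdeg_FCP       parms[91]
#define n_hill         parms[92]
#define Kd_TNF         parms[93]
#define Kd_IL6         parms[94]
#define Kd_IL12        parms[95]
#define Kd_IL23        parms[96]
#define mw_TNF         parms[97]
#define mw_IL6         parms[98]
#define mw_IL12        parms[99]
#define mw_IL23        parms[100]

#define B_TNF  forcs[0]
#define B_IL6  forcs[1]
#define B_IL12 forcs[2]
#define B_IL23 forcs[3]

#define iTh0          0
#define iTh1          1
#define iTh17         2
#define iTreg         3
#define iNK1          4
#define iiDC          5
#define ieDC          6
#define iM0           7
#define iM1           8
#define iNeu          9
#define iNeu_a        10
#define iTNFa         11
#define iIL6          12
#define iIL8          13
#define iIL12         14
#define iIL17         15
#define iIL22         16
#define iIL23         17
#define iIFNg         18
#define iGMCSF        19
#define iCRP          20
#define iFCP          21

void cd_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void cd_initforc(void (*odeforcs)(int *, double *))
{
    int n = 4;
    odeforcs(&n, forcs);
}

static double hillA(double x, double Km, double n)
{
    double xn, kn;
    if (x <= 0.0) return 0.0;
    if (n == 1.0) return x / (Km + x);
    xn = pow(x, n);
    kn = pow(Km, n);
    return xn / (kn + xn);
}

/* quasi-equilibrium free fraction of a cytokine at total conc (pg/mL),
 * binding sites B (nM), dissociation constant Kd (nM), MW (g/mol) */
static double free_frac(double conc_pgml, double B, double Kd, double mw)
{
    double T, bq, L;
    if (B <= 0.0 || conc_pgml <= 0.0) return 1.0;
    T = conc_pgml / mw;          /* pg/mL -> nM */
    bq = Kd + B - T;
    L = 0.5 * (-bq + sqrt(bq * bq + 4.0 * Kd * T));
    if (L < 0.0) L = 0.0;
    if (L > T) L = T;
    return L / T;
}

void cd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double ffT, ff6, ff12, ff23;
    double TNF_e, IL6_e, IL12_e, IL23_e;
    double Itreg, d1, d17, A_DC, A_M, A_N, f6, fF, n;
    double trg;

    n = n_hill;

    ffT  = free_frac(y[iTNFa], B_TNF, Kd_TNF, mw_TNF);
    ff6  = free_frac(y[iIL6], B_IL6, Kd_IL6, mw_IL6);
    ff12 = free_frac(y[iIL12], B_IL12, Kd_IL12, mw_IL12);
    ff23 = free_frac(y[iIL23], B_IL23, Kd_IL23, mw_IL23);

    TNF_e  = ffT * y[iTNFa];
    IL6_e  = ff6 * y[iIL6];
    IL12_e = ff12 * y[iIL12];
    IL23_e = ff23 * y[iIL23];

    trg = (y[iTreg] > 0.0) ? ((n == 1.0) ? y[iTreg] : pow(y[iTreg], n)) : 0.0;
    Itreg = ((n == 1.0) ? Km_Treg : pow(Km_Treg, n)) /
            (((n == 1.0) ? Km_Treg : pow(Km_Treg, n)) + trg);

    d1 = kdif_Th1 * hillA(IL12_e, Km_IL12_Th1, n) * Itreg;
    d17 = kdif_Th17 * (hillA(IL23_e, Km_IL23_Th17, n) +
                       a_IL6_Th17 * hillA(IL6_e, Km_IL6_Th17, n)) * Itreg;
    A_DC = hillA(TNF_e, Km_TNF_DC, n) + a_IL6_DC * hillA(IL6_e, Km_IL6_DC, n);
    A_M = hillA(TNF_e, Km_TNF_M, n) + a_IFN_M * hillA(y[iIFNg], Km_IFN_M, n);
    A_N = hillA(TNF_e, Km_TNF_Neu, n) +
          a_IL17_Neu * hillA(y[iIL17], Km_IL17_Neu, n);

    /* homeostatic naive pool: differentiation does not deplete Th0 */
    ydot[iTh0] = s_Th0 - kdeg_Th0 * y[iTh0];
    ydot[iTh1] = d1 * y[iTh0] - kdeg_Th1 * y[iTh1];
    ydot[iTh17] = d17 * y[iTh0] - kdeg_Th17 * y[iTh17];
    ydot[iTreg] = s_Treg - kdeg_Treg * y[iTreg];
    ydot[iNK1] = s_NK1 + kact_NK1 * hillA(IL12_e, Km_IL12_NK1, n) -
                 kdeg_NK1 * y[iNK1];
    ydot[iiDC] = s_iDC - (kdeg_iDC + kact_DC * A_DC) * y[iiDC];
    ydot[ieDC] = kact_DC * A_DC * y[iiDC] - kdeg_eDC * y[ieDC];
    ydot[iM0] = s_M0 - (kdeg_M0 + kact_M * A_M) * y[iM0];
    ydot[iM1] = kact_M * A_M * y[iM0] - kdeg_M1 * y[iM1];
    ydot[iNeu] = s_Neu - (kdeg_Neu + kact_Neu * A_N) * y[iNeu];
    ydot[iNeu_a] = kact_Neu * A_N * y[iNeu] - kdeg_Neua * y[iNeu_a];

    ydot[iTNFa] = b_TNF +
        p_TNF * (y[ieDC] + w_M1_TNF * y[iM1] + w_Neu_TNF * y[iNeu_a]) -
        kdeg_TNF * y[iTNFa];
    f6 = c0_IL6 + (1.0 - c0_IL6) *
         (hillA(TNF_e, Km_TNF_IL6, n) +
          a_IL17_IL6 * hillA(y[iIL17], Km_IL17_IL6, n)) / (1.0 + a_IL17_IL6);
    ydot[iIL6] = b_IL6 +
        p_IL6 * (y[ieDC] + w_M1_IL6 * y[iM1] + w_Neu_IL6 * y[iNeu_a]) * f6 -
        kdeg_IL6 * y[iIL6];
    ydot[iIL8] = b_IL8 +
        p_IL8 * (y[ieDC] + w_M1_IL8 * y[iM1] + w_Neu_IL8 * y[iNeu_a]) -
        kdeg_IL8 * y[iIL8];
    ydot[iIL12] = b_IL12 +
        p_IL12 * (y[ieDC] + w_M1_IL12 * y[iM1] + w_Neu_IL12 * y[iNeu_a]) -
        kdeg_IL12 * y[iIL12];
    ydot[iIL17] = b_IL17 + p_IL17 * y[iTh17] - kdeg_IL17 * y[iIL17];
    ydot[iIL22] = b_IL22 + p_IL22 * y[iTh17] - kdeg_IL22 * y[iIL22];
    ydot[iIL23] = b_IL23 +
        p_IL23 * (y[ieDC] + w_M1_IL23 * y[iM1] + w_Neu_IL23 * y[iNeu_a]) -
        kdeg_IL23 * y[iIL23];
    ydot[iIFNg] = b_IFN + p_IFN * (y[iTh1] + w_NK_IFN * y[iNK1]) -
        kdeg_IFN * y[iIFNg];
    ydot[iGMCSF] = b_GM +
        p_GM * (y[ieDC] + w_M1_GM * y[iM1] + w_Neu_GM * y[iNeu_a]) -
        kdeg_GM * y[iGMCSF];
    ydot[iCRP] = b_CRP + p_CRP * hillA(IL6_e, Km_IL6_CRP, n) -
        kdeg_CRP * y[iCRP];
    fF = c0_FCP + (1.0 - c0_FCP) * hillA(y[iIL8], Km_IL8_FCP, n);
    ydot[iFCP] = b_FCP + p_FCP * hillA(y[iNeu_a], Km_Neua_FCP, n) * fF -
        kdeg_FCP * y[iFCP];

    if (*ip >= 4) {
        yout[0] = ffT;
        yout[1] = ff6;
        yout[2] = ff12;
        yout[3] = ff23;
    }
}
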