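/* Compiled mass-action derivative of the AtoSC two-component system model,
 * in the deSolve compiled-model convention.  Parameter and species order
 * must match .tcs_param_names / .tcs_species on the R side.
 *
 * parms: k_ap k_ad k_b1 k_d1 k_pt k_b2 k_d2 k_ph k_b3 k_d3
 *        k_bnd k_unbnd k_lgexp k_pmgexp k_trl k_mat d_m d_g
 *        S_tot C_tot P_tot
 * y:     S Sp C Cp SpC SCp SC P PCp M Gi Gm
 */

static double parms[21];

void tcs_initmod(void (*odeparms)(int *, double *))
{
    int n = 21;
    odeparms(&n, parms);
}

void tcs_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double k_ap = parms[0],  k_ad = parms[1];
    const double k_b1 = parms[2],  k_d1 = parms[3],  k_pt = parms[4];
    const double k_b2 = parms[5],  k_d2 = parms[6],  k_ph = parms[7];
    const double k_b3 = parms[8],  k_d3 = parms[9];
    const double k_bnd = parms[10], k_unbnd = parms[11];
    const double k_lgexp = parms[12], k_pmgexp = parms[13];
    const double k_trl = parms[14], k_mat = parms[15];
    const double d_m = parms[16], d_g = parms[17];

    const double S = y[0], Sp = y[1], C = y[2], Cp = y[3];
    const double SpC = y[4], SCp = y[5], SC = y[6];
    const double P = y[7], PCp = y[8], M = y[9], Gi = y[10], Gm = y[11];

    const double v_ap  = k_ap * S;
    const double v_ad  = k_ad * Sp;
    const double v_b1  = k_b1 * Sp * C;
    const double v_d1  = k_d1 * SpC;
    const double v_pt  = k_pt * SpC;
    const double v_b2  = k_b2 * S * Cp;
    const double v_d2  = k_d2 * SCp;
    const double v_ph  = k_ph * SCp;
    const double v_b3  = k_b3 * S * C;
    const double v_d3  = k_d3 * SC;
    const double v_bnd = k_bnd * Cp * P;
    const double v_unb = k_unbnd * PCp;

    ydot[0]  = -v_ap + v_ad + v_pt - v_b2 + v_d2 + v_ph - v_b3 + v_d3; /* S   */
    ydot[1]  =  v_ap - v_ad - v_b1 + v_d1;                             /* Sp  */
    ydot[2]  = -v_b1 + v_d1 + v_ph - v_b3 + v_d3;                      /* C   */
    ydot[3]  =  v_pt - v_b2 + v_d2 - v_bnd + v_unb;                    /* Cp  */
    ydot[4]  =  v_b1 - v_d1 - v_pt;                                    /* SpC */
    ydot[5]  =  v_b2 - v_d2 - v_ph;                                    /* SCp */
    ydot[6]  =  v_b3 - v_d3;                                           /* SC  */
    ydot[7]  = -v_bnd + v_unb;                                         /* P   */
    ydot[8]  =  v_bnd - v_unb;                                         /* PCp */
    ydot[9]  =  k_lgexp * P + k_pmgexp * PCp - d_m * M;                /* M   */
    ydot[10] =  k_trl * M - k_mat * Gi - d_g * Gi;                     /* Gi  */
    ydot[11] =  k_mat * Gi - d_g * Gm;                                 /* Gm  */
}
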