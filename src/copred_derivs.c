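/* Right-hand side of the dual-predation ODE model family.
 *
 * State order (10 compartments, densities per ml):
 *   0 N_S  sensitive prey
 *   1 N_P  plastic Bdellovibrio-resistant prey
 *   2 N_R  phage-resistant prey
 *   3 N_D  doubly resistant prey
 *   4 P    free attack-phase Bdellovibrio
 *   5 B    bdelloplasts
 *   6 V    free phage
 *   7 I    phage-infected prey
 *   8 M    medium (prey-cell equivalents)
 *   9 C    resistance-inducing signal
 *
 * Parameter vector (passed via initfunc, length 24):
 *   0 mu_max  1 K_M  2 a_P  3 K_P  4 a_V  5 K_V  6 k_B  7 beta_P
 *   8 k_I  9 beta_V  10 eps_B  11 eps_I  12 d_P  13 sigma_C  14 k_sig
 *   15 r_I  16 r_back  17 m
 * variant flags:
 *   18 prey_types (1..4)
 *   19 conversion (1 = I, 2 = IG, 3 = S, 4 = SG)
 *   20 signal_source (1 = B_only, 2 = V_only, 3 = both)
 *   21 resistance_origin (1 = preexisting, 2 = de_novo, 3 = both)
 *   22 p_saturation (1 = Pi, 2 = Pii)
 *   23 v_saturation (1 = Vi, 2 = Vii)
 *
 * States are clamped at zero inside the flux evaluation so that small
 * negative excursions of the integrator cannot feed back into the dynamics.
 */

static double parms[24];

void copred_init(void (*odeparms)(int *, double *))
{
    int n = 24;
    odeparms(&n, parms);
}

void copred_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double mu_max = parms[0], K_M = parms[1], a_P = parms[2],
        K_P = parms[3], a_V = parms[4], K_V = parms[5], k_B = parms[6],
        beta_P = parms[7], k_I = parms[8], beta_V = parms[9],
        eps_B = parms[10], eps_I = parms[11], d_P = parms[12],
        sigma_C = parms[13], k_sig = parms[14], r_I = parms[15],
        r_back = parms[16], m = parms[17];
    const int prey_types = (int) parms[18];
    const int conversion = (int) parms[19];
    const int signal_source = (int) parms[20];
    const int resistance_origin = (int) parms[21];
    const int p_sat = (int) parms[22];
    const int v_sat = (int) parms[23];

    const int has_NR = prey_types >= 2;
    const int has_NP = prey_types >= 3;
    const int has_ND = prey_types >= 4;
    const int signal_conv = has_NP && conversion >= 3;     /* S or SG */
    const int growth_back = has_NP && (conversion == 2 || conversion == 4);
    const double m_eff = (has_NR && resistance_origin >= 2) ? m : 0.0;

    double NS = y[0] > 0 ? y[0] : 0;
    double NP = (has_NP && y[1] > 0) ? y[1] : 0;
    double NR = (has_NR && y[2] > 0) ? y[2] : 0;
    double ND = (has_ND && y[3] > 0) ? y[3] : 0;
    double P  = y[4] > 0 ? y[4] : 0;
    double Bd = y[5] > 0 ? y[5] : 0;
    double V  = y[6] > 0 ? y[6] : 0;
    double I  = y[7] > 0 ? y[7] : 0;
    double M  = y[8] > 0 ? y[8] : 0;
    double C  = (signal_conv && y[9] > 0) ? y[9] : 0;

    double dNS = 0, dNP = 0, dNR = 0, dND = 0, dC = 0;

    /* (i) growth on medium, Monod uptake, unit yield */
    const double phi = (M > 0) ? mu_max * M / (K_M + M) : 0.0;
    const double g_NS = phi * NS, g_NP = phi * NP;
    const double g_NR = phi * NR, g_ND = phi * ND;
    const double mf_NS = m_eff * g_NS;                 /* N_S births -> N_R */
    const double mf_NP = has_ND ? m_eff * g_NP : 0.0;  /* N_P births -> N_D */

    dNS += g_NS - mf_NS;
    if (has_NR) dNR += g_NR + mf_NS;
    if (has_NP) {
        if (growth_back) {
            /* plastic resistance is not inherited: N_P offspring are N_S */
            dNS += g_NP - mf_NP;
        } else {
            dNP += g_NP - mf_NP;
        }
    }
    if (has_ND) {
        dND += mf_NP;
        if (growth_back) dNR += g_ND; else dND += g_ND;
    }

    /* (ii) Bdellovibrio attack on susceptible prey (N_S, N_R) */
    const double S_P = NS + NR;
    double attp_NS, attp_NR;
    if (p_sat == 2) {
        const double den = K_P + S_P;
        attp_NS = (den > 0) ? a_P * P * NS / den : 0.0;
        attp_NR = (den > 0) ? a_P * P * NR / den : 0.0;
    } else {
        attp_NS = a_P * P * NS;
        attp_NR = a_P * P * NR;
    }
    const double A_P = attp_NS + attp_NR;
    dNS -= attp_NS;
    if (has_NR) dNR -= attp_NR;

    /* (iii) phage attack on susceptible prey (N_S, N_P) */
    const double S_V = NS + NP;
    double attv_NS, attv_NP;
    if (v_sat == 2) {
        const double den = K_V + S_V;
        attv_NS = (den > 0) ? a_V * V * NS / den : 0.0;
        attv_NP = (den > 0) ? a_V * V * NP / den : 0.0;
    } else {
        attv_NS = a_V * V * NS;
        attv_NP = a_V * V * NP;
    }
    const double A_V = attv_NS + attv_NP;
    dNS -= attv_NS;
    if (has_NP) dNP -= attv_NP;

    /* conversion between N_S and N_P (and N_R <-> N_D under N4) */
    if (has_NP) {
        double conv_NS, conv_NR;
        if (signal_conv) {
            conv_NS = k_sig * C * NS;
            conv_NR = has_ND ? k_sig * C * NR : 0.0;
        } else {
            conv_NS = r_I * NS;
            conv_NR = has_ND ? r_I * NR : 0.0;
        }
        dNS -= conv_NS;
        dNP += conv_NS;
        if (has_ND) {
            dNR -= conv_NR;
            dND += conv_NR;
        }
        if (!growth_back) {            /* intrinsic back conversion */
            const double back_NP = r_back * NP;
            dNP -= back_NP;
            dNS += back_NP;
            if (has_ND) {
                const double back_ND = r_back * ND;
                dND -= back_ND;
                dNR += back_ND;
            }
        }
    }

    /* signal production proportional to the source predator's attack flux */
    if (signal_conv) {
        double src = 0;
        if (signal_source == 1) src = A_P;
        else if (signal_source == 2) src = A_V;
        else src = A_P + A_V;
        dC = sigma_C * src;
    }

    ydot[0] = dNS;
    ydot[1] = has_NP ? dNP : 0.0;
    ydot[2] = has_NR ? dNR : 0.0;
    ydot[3] = has_ND ? dND : 0.0;
    /* (iv)+(vi) bdelloplast progression and lysis; (viii) P mortality */
    ydot[4] = beta_P * k_B * Bd - A_P - d_P * P;
    ydot[5] = A_P - k_B * Bd;
    /* (v)+(vii) infected-cell maturation and lysis */
    ydot[6] = beta_V * k_I * I - A_V;
    ydot[7] = A_V - k_I * I;
    /* medium: consumed by gross growth, replenished by lysis residues */
    ydot[8] = -(g_NS + g_NP + g_NR + g_ND)
        + eps_B * k_B * Bd + eps_I * k_I * I;
    ydot[9] = signal_conv ? dC : 0.0;
}
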