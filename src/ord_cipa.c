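/* Human endocardial ventricular action-potential model (O'Hara-Rudy 2011)
 * with the optimised conductance rescaling of five currents (IKr x1.013,
 * IKs x1.87, IK1 x1.698, ICaL x1.007, INaL x2.661; Dutta et al. 2017) and
 * the hERG/IKr component replaced by the CiPA dynamic Markov model
 * (Li et al. 2017): six channel states IC1, IC2, C1, C2, O, IO plus
 * drug-bound states IObound, Obound, Cbound.
 *
 * Compiled-model interface for deSolve: parms are set via ord_init(),
 * derivatives via ord_derivs(). State vector (48):
 *   0 v, 1 nai, 2 nass, 3 ki, 4 kss, 5 cai, 6 cass, 7 cansr, 8 cajsr,
 *   9 m, 10 hf, 11 hs, 12 j, 13 hsp, 14 jp, 15 mL, 16 hL, 17 hLp,
 *   18 a, 19 iF, 20 iS, 21 ap, 22 iFp, 23 iSp,
 *   24 d, 25 ff, 26 fs, 27 fcaf, 28 fcas, 29 jca, 30 nca, 31 ffp, 32 fcafp,
 *   33 xs1, 34 xs2, 35 xk1, 36 Jrelnp, 37 Jrelp, 38 CaMKt,
 *   39 IC1, 40 IC2, 41 C1, 42 C2, 43 O, 44 IO, 45 IObound, 46 Obound,
 *   47 Cbound
 * Output variables (8): IKr, INaL, ICaL, IKs, IK1, Ito, INa, Istim.
 * Parameters (11): mode (0 = CS, 1 = SD), D (nM), Kmax, Ku, n, halfmax
 * (= EC50^n), Vhalf_trap, Kt, cs_scale, stim_amp (A/F), stim_dur (ms).
 * The stimulus is applied for t in [0, stim_dur) of each integration
 * window; the R driver integrates beat by beat from the stimulus onset.
 */

#include <R.h>
#include <math.h>

static double parms[11];
#define p_mode     parms[0]
#define p_D        parms[1]
#define p_Kmax     parms[2]
#define p_Ku       parms[3]
#define p_n        parms[4]
#define p_halfmax  parms[5]
#define p_Vhalf    parms[6]
#define p_Kt       parms[7]
#define p_scale    parms[8]
#define p_stimamp  parms[9]
#define p_stimdur  parms[10]

void ord_init(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

/* safe x / (exp(x) - 1) style factors */
static double expm1_ratio(double x)
{   /* returns x / (exp(x) - 1), finite at x = 0 */
    if (fabs(x) < 1e-7) return 1.0 - x / 2.0;
    return x / (exp(x) - 1.0);
}

void ord_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    /* physical constants and cell geometry */
    const double nao = 140.0, cao = 1.8, ko = 5.4;
    const double R = 8314.0, T = 310.0, F = 96485.0;
    const double L = 0.01, rad = 0.0011;
    const double vcell = 1000.0 * 3.14 * rad * rad * L;
    const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    const double Acap = 2.0 * Ageo;
    const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
    const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

    const double v = y[0];
    const double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    const double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];

    const double vfrt = v * F / (R * T);

    /* CaMK */
    const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
    const double CaMKo = 0.05, KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - y[38]) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + y[38];
    ydot[38] = aCaMK * CaMKb * (CaMKb + y[38]) - bCaMK * y[38];

    /* reversal potentials */
    double ENa = (R * T / F) * log(nao / nai);
    double EK  = (R * T / F) * log(ko / ki);
    const double PKNa = 0.01833;
    double EKs = (R * T / F) * log((ko + PKNa * nao) / (ki + PKNa * nai));

    /* INa (fast) */
    double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                       8.552 * exp(-(v + 77.42) / 5.955));
    ydot[9] = (mss - y[9]) / tm;
    double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                        6.149 * exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                        0.3343 * exp((v + 5.730) / 56.66));
    ydot[10] = (hss - y[10]) / thf;
    ydot[11] = (hss - y[11]) / ths;
    const double Ahf = 0.99, Ahs = 0.01;
    double h = Ahf * y[10] + Ahs * y[11];
    double jss = hss;
    double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                               0.3052 * exp((v + 0.9941) / 38.45));
    ydot[12] = (jss - y[12]) / tj;
    double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
    ydot[13] = (hssp - y[13]) / (3.0 * ths);
    double hp = Ahf * y[10] + Ahs * y[13];
    ydot[14] = (jss - y[14]) / (1.46 * tj);
    const double GNa = 75.0;
    double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
    double INa = GNa * (v - ENa) * pow(y[9], 3.0) *
                 ((1.0 - fINap) * h * y[12] + fINap * hp * y[14]);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    ydot[15] = (mLss - y[15]) / tm;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    const double thL = 200.0;
    ydot[16] = (hLss - y[16]) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    ydot[17] = (hLssp - y[17]) / (3.0 * thL);
    const double GNaL = 0.0075 * 2.661;   /* endo x optimised rescaling */
    double fINaLp = fINap;
    double INaL = GNaL * (v - ENa) * y[15] *
                  ((1.0 - fINaLp) * y[16] + fINaLp * y[17]);

    /* Ito (endo: delta_epi = 1) */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    ydot[18] = (ass - y[18]) / ta;
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    ydot[19] = (iss - y[19]) / tiF;
    ydot[20] = (iss - y[20]) / tiS;
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    double i_gate = AiF * y[19] + AiS * y[20];
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    ydot[21] = (assp - y[21]) / ta;
    double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                           exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    ydot[22] = (iss - y[22]) / (dti_develop * dti_recover * tiF);
    ydot[23] = (iss - y[23]) / (dti_develop * dti_recover * tiS);
    double ip_gate = AiF * y[22] + AiS * y[23];
    const double Gto = 0.02;
    double fItop = fINap;
    double Ito = Gto * (v - EK) *
                 ((1.0 - fItop) * y[18] * i_gate + fItop * y[21] * ip_gate);

    /* ICaL / ICaNa / ICaK */
    double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    ydot[24] = (dss - y[24]) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                                 0.000035 * exp((v + 5.0) / 6.0));
    ydot[25] = (fss - y[25]) / tff;
    ydot[26] = (fss - y[26]) / tfs;
    const double Aff = 0.6, Afs = 0.4;
    double f = Aff * y[25] + Afs * y[26];
    double fcass = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    ydot[27] = (fcass - y[27]) / tfcaf;
    ydot[28] = (fcass - y[28]) / tfcas;
    double fca = Afcaf * y[27] + Afcas * y[28];
    const double tjca = 75.0;
    ydot[29] = (fcass - y[29]) / tjca;
    ydot[31] = (fss - y[31]) / (2.5 * tff);
    double fp = Aff * y[31] + Afs * y[26];
    ydot[32] = (fcass - y[32]) / (2.5 * tfcaf);
    double fcap = Afcaf * y[32] + Afcas * y[28];
    const double Kmn = 0.002, k2n = 1000.0;
    double km2n = y[29] * 1.0;
    double anca = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cass, 4.0));
    ydot[30] = anca * k2n - y[30] * km2n;
    /* GHK driving-force factors, written via x/(e^x - 1) so v = 0 is finite:
       4 vffrt (..)/(e^{2vfrt}-1) = 2 F f2 (..),  vffrt (..)/(e^{vfrt}-1) = F f1 (..) */
    double f2 = expm1_ratio(2.0 * vfrt);
    double f1 = expm1_ratio(vfrt);
    double PhiCaL  = 2.0 * F * f2 * (cass * exp(2.0 * vfrt) - 0.341 * cao);
    double PhiCaNa = F * f1 * (0.75 * nass * exp(vfrt) - 0.75 * nao);
    double PhiCaK  = F * f1 * (0.75 * kss * exp(vfrt) - 0.75 * ko);
    const double PCa = 0.0001 * 1.007;    /* endo x optimised rescaling */
    const double PCap = 1.1 * PCa;
    const double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    const double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double fICaLp = fINap;
    double nca = y[30], d_gate = y[24], jca = y[29];
    double ICaL = (1.0 - fICaLp) * PCa * PhiCaL * d_gate *
                      (f * (1.0 - nca) + jca * fca * nca) +
                  fICaLp * PCap * PhiCaL * d_gate *
                      (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * d_gate *
                       (f * (1.0 - nca) + jca * fca * nca) +
                   fICaLp * PCaNap * PhiCaNa * d_gate *
                       (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * d_gate *
                      (f * (1.0 - nca) + jca * fca * nca) +
                  fICaLp * PCaKp * PhiCaK * d_gate *
                      (fp * (1.0 - nca) + jca * fcap * nca);

    /* IKr: CiPA dynamic Markov model, 37 C (rates in ms^-1) */
    {
        const double Tq = 37.0;
        const double qp = (Tq - 20.0) / 10.0;
        const double A1 = 0.0264,    B1 = 4.631e-05,  q1 = 4.843;
        const double A2 = 4.986e-06, B2 = -0.004226,  q2 = 4.23;
        const double A3 = 0.001214,  B3 = 0.008516,   q3 = 4.962;
        const double A4 = 1.854e-05, B4 = -0.04641,   q4 = 3.769;
        const double A11 = 0.0007868, B11 = 1.535e-08, q11 = 4.942;
        const double A21 = 5.455e-06, B21 = -0.1688,   q21 = 4.156;
        const double A31 = 0.005509,  B31 = 7.771e-09, q31 = 4.22;
        const double A41 = 0.001416,  B41 = -0.02877,  q41 = 1.459;
        const double A51 = 0.4492,    B51 = 0.008595,  q51 = 5.0;
        const double A52 = 0.3181,    B52 = 3.613e-08, q52 = 4.663;
        const double A53 = 0.149,     B53 = 0.004668,  q53 = 2.412;
        const double A61 = 0.01241,   B61 = 0.1725,    q61 = 5.568;
        const double A62 = 0.3226,    B62 = -0.0006575, q62 = 5.0;
        const double A63 = 0.008978,  B63 = -0.02215,  q63 = 5.682;
        double a11 = A11 * exp(B11 * v) * pow(q11, qp);
        double a21 = A21 * exp(B21 * v) * pow(q21, qp);
        double a3  = A3  * exp(B3  * v) * pow(q3,  qp);
        double a4  = A4  * exp(B4  * v) * pow(q4,  qp);
        double a1  = A1  * exp(B1  * v) * pow(q1,  qp);
        double a2  = A2  * exp(B2  * v) * pow(q2,  qp);
        double a31 = A31 * exp(B31 * v) * pow(q31, qp);
        double a41 = A41 * exp(B41 * v) * pow(q41, qp);
        double a53 = A53 * exp(B53 * v) * pow(q53, qp);
        double a63 = A63 * exp(B63 * v) * pow(q63, qp);
        double a51 = A51 * exp(B51 * v) * pow(q51, qp);
        double a61 = A61 * exp(B61 * v) * pow(q61, qp);
        double a52 = A52 * exp(B52 * v) * pow(q52, qp);
        double a62 = A62 * exp(B62 * v) * pow(q62, qp);
        double IC1 = y[39], IC2 = y[40], C1 = y[41], C2 = y[42];
        double O = y[43], IO = y[44];
        double IObnd = y[45], Obnd = y[46], Cbnd = y[47];
        double Kb = 0.0, Kr = 0.0, Kn = 0.0, Kt = p_Kt;
        if (p_mode > 0.5 && p_D > 0.0) {
            double Dn = pow(p_D, p_n);
            Kb = p_Kmax * p_Ku * Dn / (Dn + p_halfmax);
        }
        Kr = p_Ku * a53 / a63;   /* microscopic reversibility closure */
        Kn = Kt / (1.0 + exp(-(v - p_Vhalf) / 6.789));
        ydot[39] = -(a11 * IC1 - a21 * IC2) + (a51 * C1 - a61 * IC1);
        ydot[40] = (a11 * IC1 - a21 * IC2) - (a3 * IC2 - a4 * IO) +
                   (a52 * C2 - a62 * IC2);
        ydot[41] = -(a1 * C1 - a2 * C2) - (a51 * C1 - a61 * IC1);
        ydot[42] = (a1 * C1 - a2 * C2) - (a31 * C2 - a41 * O) -
                   (a52 * C2 - a62 * IC2);
        ydot[43] = (a31 * C2 - a41 * O) - (a53 * O - a63 * IO) -
                   (Kb * O - p_Ku * Obnd);
        ydot[44] = (a3 * IC2 - a4 * IO) + (a53 * O - a63 * IO) -
                   (Kb * IO - Kr * IObnd);
        ydot[45] = (Kb * IO - Kr * IObnd) + (Kn * Cbnd - Kt * IObnd);
        ydot[46] = (Kb * O - p_Ku * Obnd) + (Kn * Cbnd - Kt * Obnd);
        ydot[47] = (Kt * Obnd - Kn * Cbnd) + (Kt * IObnd - Kn * Cbnd);
    }
    const double GKr = 0.04658545454545456 * 1.013;  /* x optimised rescaling */
    double scale = (p_mode > 0.5) ? 1.0 : p_scale;
    double IKr = scale * GKr * sqrt(ko / 5.4) * y[43] * (v - EK);

    /* IKs */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    ydot[33] = (xs1ss - y[33]) / txs1;
    double xs2ss = xs1ss;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    ydot[34] = (xs2ss - y[34]) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    const double GKs = 0.0034 * 1.87;     /* endo x optimised rescaling */
    double IKs = GKs * KsCa * y[33] * y[34] * (v - EKs);

    /* IK1 */
    double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                    (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) +
                           exp((v + 236.8) / 69.33));
    ydot[35] = (xk1ss - y[35]) / txk1;
    double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
    const double GK1 = 0.1908 * 1.698;    /* endo x optimised rescaling */
    double IK1 = GK1 * sqrt(ko) * rk1 * y[35] * (v - EK);

    /* INaCa (myoplasmic and subspace) */
    const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    const double kcaon = 1.5e6, kcaoff = 5.0e3;
    const double qna = 0.5224, qca = 0.1670;
    double hca = exp(qca * vfrt), hna = exp(qna * vfrt);
    double INaCa_i, INaCa_ss;
    {
        double h1 = 1.0 + nai / kna3 * (1.0 + hna);
        double h2 = (nai * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
        double h5 = nai * nai / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon;
        double k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff, k6 = h6 * cai * kcaon;
        double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        const double KmCaAct = 150.0e-6;
        double allo = 1.0 / (1.0 + pow(KmCaAct / cai, 2.0));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        const double Gncx = 0.0008;
        INaCa_i = 0.8 * Gncx * allo * (1.0 * JncxNa + 2.0 * JncxCa);
        /* subspace copy with cass/nass */
        h1 = 1.0 + nass / kna3 * (1.0 + hna);
        h2 = (nass * hna) / (kna3 * h1);
        h3 = 1.0 / h1;
        h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
        h5 = nass * nass / (h4 * kna1 * kna2);
        h6 = 1.0 / h4;
        k1 = h12 * cao * kcaon;
        k2 = kcaoff;
        k3 = k3p + k3pp;
        k4p = h3 * wca / hca; k4pp = h2 * wnaca; k4 = k4p + k4pp;
        k5 = kcaoff; k6 = h6 * cass * kcaon;
        k7 = h5 * h2 * wna; k8 = h8 * h11 * wna;
        x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        E1 = x1 / (x1 + x2 + x3 + x4); E2 = x2 / (x1 + x2 + x3 + x4);
        E3 = x3 / (x1 + x2 + x3 + x4); E4 = x4 / (x1 + x2 + x3 + x4);
        double allo_ss = 1.0 / (1.0 + pow(KmCaAct / cass, 2.0));
        JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        JncxCa = E2 * k2 - E1 * k1;
        INaCa_ss = 0.2 * Gncx * allo_ss * (1.0 * JncxNa + 2.0 * JncxCa);
    }

    /* INaK */
    double INaK;
    {
        const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
        const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
        const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
        double Knai = Knai0 * exp(delta * vfrt / 3.0);
        double Knao = Knao0 * exp((1.0 - delta) * vfrt / 3.0);
        const double Kki = 0.5, Kko = 0.3582;
        const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
        const double H = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
        const double Knap = 224.0, Kxkur = 292.0;
        double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
        double a1 = (k1p * pow(nai / Knai, 3.0)) /
                    (pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double b1 = k1m * MgADP;
        double a2 = k2p;
        double b2 = (k2m * pow(nao / Knao, 3.0)) /
                    (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double a3 = (k3p * pow(ko / Kko, 2.0)) /
                    (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double b3 = (k3m * P * H) / (1.0 + MgATP / Kmgatp);
        double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
        double b4 = (k4m * pow(ki / Kki, 2.0)) /
                    (pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
        double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
        double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
        double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
        double JnakK = 2.0 * (E4 * b1 - E3 * a1);
        const double Pnak = 30.0;
        INaK = Pnak * (1.0 * JnakNa + 1.0 * JnakK);
    }

    /* background and pump currents */
    double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
    const double GKb = 0.003;
    double IKb = GKb * xkb * (v - EK);
    const double PNab = 3.75e-10;
    double INab = PNab * F * expm1_ratio(vfrt) * (nai * exp(vfrt) - nao);
    const double PCab = 2.5e-8;
    double ICab = PCab * 2.0 * F * expm1_ratio(2.0 * vfrt) *
                  (cai * exp(2.0 * vfrt) - 0.341 * cao);
    const double GpCa = 0.0005;
    double IpCa = GpCa * cai / (0.0005 + cai);

    /* stimulus */
    double Istim = (*t < p_stimdur) ? p_stimamp : 0.0;

    /* diffusion fluxes */
    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    /* SR release */
    const double bt = 4.75;
    const double a_rel = 0.5 * bt;
    double Jrel_inf = a_rel * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    ydot[36] = (Jrel_inf - y[36]) / tau_rel;
    const double btp = 1.25 * bt;
    const double a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    ydot[37] = (Jrel_infp - y[37]) / tau_relp;
    double fJrelp = fINap;
    double Jrel = (1.0 - fJrelp) * y[36] + fJrelp * y[37];

    /* SR uptake */
    double Jupnp = 0.004375 * cai / (cai + 0.00092);
    double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double fJupp = fINap;
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 100.0;

    /* concentration updates (buffered where appropriate; endo buffers) */
    const double cmdnmax = 0.05, kmcmdn = 0.00238;
    const double trpnmax = 0.07, kmtrpn = 0.0005;
    const double BSRmax = 0.047, KmBSR = 0.00087;
    const double BSLmax = 1.124, KmBSL = 0.0087;
    const double csqnmax = 10.0, kmcsqn = 0.8;

    ydot[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
              (F * vmyo) + JdiffNa * vss / vmyo;
    ydot[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (F * vss) - JdiffNa;
    ydot[3] = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK) * Acap /
              (F * vmyo) + JdiffK * vss / vmyo;
    ydot[4] = -ICaK * Acap / (F * vss) - JdiffK;
    {
        double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0) +
                             trpnmax * kmtrpn / pow(kmtrpn + cai, 2.0));
        ydot[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                          (2.0 * F * vmyo) - Jup * vnsr / vmyo +
                          Jdiff * vss / vmyo);
        double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / pow(KmBSR + cass, 2.0) +
                              BSLmax * KmBSL / pow(KmBSL + cass, 2.0));
        ydot[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * F * vss) +
                           Jrel * vjsr / vss - Jdiff);
        ydot[7] = Jup - Jtr * vjsr / vnsr;
        double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / pow(kmcsqn + cajsr, 2.0));
        ydot[8] = Bcajsr * (Jtr - Jrel);
    }

    /* membrane potential */
    ydot[0] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim);

    if (ip[0] >= 8) {
        yout[0] = IKr;
        yout[1] = INaL;
        yout[2] = ICaL;
        yout[3] = IKs;
        yout[4] = IK1;
        yout[5] = Ito;
        yout[6] = INa;
        yout[7] = Istim;
    }
}
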