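// Compiled right-hand side of the coupled tank + biofilm system.
// Mirrors the reference R implementation (.biofilm_rhs in R/solver.R);
// the two are pinned against each other in the test suite. The stiff
// integrator estimates its Jacobian by finite differences, so the RHS
// is evaluated O(N) times per Jacobian and speed matters.

#include <Rcpp.h>
using namespace Rcpp;

// parameter packing order (see .pack_params in R/solver.R)
enum {
  P_NZ, P_MU_MAX, P_K_M, P_Q, P_V, P_A, P_K_DIS, P_Y_GL, P_S_IN_G,
  P_K_B_L, P_K_B_D, P_RHO_L, P_RHO_D, P_D_B_G, P_D_B_H, P_D_AQ_G,
  P_D_AQ_H, P_L_L, P_K_DET, P_LF_FLOOR
};

// [[Rcpp::export]]
NumericVector biofilm_rhs_core(double t, NumericVector y,
                               NumericVector par, double S_in_H) {
  const int Nz = (int) par[P_NZ];
  const double mu_max = par[P_MU_MAX], K_M = par[P_K_M], Q = par[P_Q],
    V = par[P_V], A = par[P_A], k_dis = par[P_K_DIS], Y_GL = par[P_Y_GL],
    S_in_G = par[P_S_IN_G], k_B_L = par[P_K_B_L], k_B_D = par[P_K_B_D],
    rho_L = par[P_RHO_L], rho_D = par[P_RHO_D], D_b_G = par[P_D_B_G],
    D_b_H = par[P_D_B_H], D_aq_G = par[P_D_AQ_G], D_aq_H = par[P_D_AQ_H],
    L_L = par[P_L_L], K_det = par[P_K_DET], Lf_floor = par[P_LF_FLOOR];

  const int i0 = 4, iLf = 4 + 4 * Nz;
  const double Lf_raw = y[iLf];
  const double Lf = Lf_raw > Lf_floor ? Lf_raw : Lf_floor;
  const double dz = Lf / Nz;

  NumericVector dy(4 * Nz + 5);
  std::vector<double> XL(Nz), XD(Nz), SG(Nz), SH(Nz),
    RXL(Nz), RXD(Nz), RSG(Nz), RSH(Nz), v(Nz + 1);

  // clamped local fields and kinetic rates; growth velocity by the
  // midpoint rule on the volumetric source
  v[0] = 0.0;
  for (int i = 0; i < Nz; i++) {
    XL[i] = std::max(y[i0 + i], 0.0);
    XD[i] = std::max(y[i0 + Nz + i], 0.0);
    SG[i] = std::max(y[i0 + 2 * Nz + i], 0.0);
    SH[i] = std::max(y[i0 + 3 * Nz + i], 0.0);
    const double mu = mu_max * SG[i] / (K_M + SG[i]);
    const double kill = k_dis * SH[i] * XL[i];
    RXL[i] = mu * XL[i] - kill;
    RXD[i] = kill;
    RSG[i] = -mu * XL[i] / Y_GL;
    RSH[i] = -(k_B_L * XL[i] + k_B_D * XD[i]) * SH[i];
    const double Pt = XL[i] / rho_L + XD[i] / rho_D;
    const double src = Pt > 0 ? (RXL[i] / rho_L + RXD[i] / rho_D) / Pt : 0.0;
    v[i + 1] = v[i] + src * dz;
  }

  const double v_det = K_det * Lf * Lf;
  double dLf = v[Nz] - v_det;
  if (Lf_raw <= Lf_floor && dLf < 0) dLf = 0.0;
  const double dil = dLf / Lf;

  // particulate transport: upwind flux at the grid-relative velocity,
  // zero flux at the substratum, outflow only at the surface
  double fLprev = 0.0, fDprev = 0.0;
  for (int i = 0; i < Nz; i++) {
    double fL, fD;
    if (i == Nz - 1) {
      const double w = v[Nz] - dLf;          // = v_det >= 0
      const double wp = std::max(w, 0.0);
      fL = wp * XL[Nz - 1];
      fD = wp * XD[Nz - 1];
    } else {
      const double w = v[i + 1] - ((double)(i + 1) / Nz) * dLf;
      const double wp = std::max(w, 0.0), wm = std::min(w, 0.0);
      fL = wp * XL[i] + wm * XL[i + 1];
      fD = wp * XD[i] + wm * XD[i + 1];
    }
    dy[i0 + i]      = -(fL - fLprev) / dz - XL[i] * dil + RXL[i];
    dy[i0 + Nz + i] = -(fD - fDprev) / dz - XD[i] * dil + RXD[i];
    fLprev = fL;
    fDprev = fD;
  }

  // solute diffusion with the Robin surface closure plus the upwinded
  // grid-motion advection of the moving coordinate
  const double StG = y[2], StH = y[3];
  const double Stc[2] = { StG, StH };
  const double Db[2] = { D_b_G, D_b_H };
  const double Daq[2] = { D_aq_G, D_aq_H };
  const double half = dz / 2.0;
  double Jdif[2];
  for (int k = 0; k < 2; k++) {
    const std::vector<double>& S = (k == 0) ? SG : SH;
    const std::vector<double>& R = (k == 0) ? RSG : RSH;
    const double a = Db[k] / half, b = Daq[k] / L_L;
    const double S_surf = (a * S[Nz - 1] + b * Stc[k]) / (a + b);
    double gprev = 0.0;
    for (int i = 0; i < Nz; i++) {
      const double g = (i == Nz - 1)
        ? a * (S_surf - S[Nz - 1])
        : Db[k] * (S[i + 1] - S[i]) / dz;
      double grad;
      if (dLf > 0)
        grad = (i == 0) ? 0.0 : (S[i] - S[i - 1]) / dz;
      else
        grad = (i == Nz - 1) ? (S_surf - S[Nz - 1]) / half
                             : (S[i + 1] - S[i]) / dz;
      const double zc = (i + 0.5) / Nz;
      dy[i0 + (2 + k) * Nz + i] = (g - gprev) / dz + zc * dLf * grad + R[i];
      gprev = g;
    }
    Jdif[k] = -a * (S_surf - S[Nz - 1]);   // positive out of the film
  }

  // tank balances
  const double QV = Q / V, AV = A / V;
  const double XtL = std::max(y[0], 0.0), XtD = std::max(y[1], 0.0);
  const double StGc = std::max(StG, 0.0), StHc = std::max(StH, 0.0);
  const double mu_t = mu_max * StGc / (K_M + StGc);
  const double kill_t = k_dis * StHc * XtL;
  dy[0] = -QV * y[0] + v_det * XL[Nz - 1] * AV + mu_t * XtL - kill_t;
  dy[1] = -QV * y[1] + v_det * XD[Nz - 1] * AV + kill_t;
  dy[2] = QV * (S_in_G - StG) + Jdif[0] * AV - mu_t * XtL / Y_GL;
  dy[3] = QV * (S_in_H - StH) + Jdif[1] * AV
          - (k_B_L * XtL + k_B_D * XtD) * StHc;
  dy[iLf] = dLf;
  return dy;
}
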