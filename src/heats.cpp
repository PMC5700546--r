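#include <Rcpp.h>
using namespace Rcpp;

// Free-ligand mass balance: solve L + M * n_avg(L) = Ltot for L in [0, Ltot].
// K1, K2 are stepwise macroscopic association constants (1/uM); K2 == 0 is
// the single-site model (closed-form quadratic root). Two-site uses a
// safeguarded Newton iteration on the strictly increasing residual.
static double free_ligand_one(double K1, double K2, double M, double Ltot) {
  if (Ltot <= 0.0) return 0.0;
  if (M <= 0.0) return Ltot;
  if (K2 == 0.0) {
    double b = 1.0 + K1 * (M - Ltot);
    double disc = std::sqrt(b * b + 4.0 * K1 * Ltot);
    double L = (b >= 0.0) ? (2.0 * Ltot / (b + disc)) : ((disc - b) / (2.0 * K1));
    return std::min(L, Ltot);
  }
  double lo = 0.0, hi = Ltot;
  double L = 0.5 * Ltot;
  for (int iter = 0; iter < 200; ++iter) {
    double P = 1.0 + K1 * L + K1 * K2 * L * L;
    double num = K1 * L + 2.0 * K1 * K2 * L * L;
    double g = L + M * num / P - Ltot;
    if (g > 0.0) hi = L; else lo = L;
    double dP = K1 + 2.0 * K1 * K2 * L;
    double dnum = K1 + 4.0 * K1 * K2 * L;
    double gp = 1.0 + M * (dnum * P - num * dP) / (P * P);
    double Lnew = L - g / gp;
    if (!(Lnew > lo && Lnew < hi)) Lnew = 0.5 * (lo + hi);
    if (std::abs(Lnew - L) <= 1e-15 * std::max(Lnew, 1e-300)) { L = Lnew; break; }
    L = Lnew;
  }
  return L;
}

// [[Rcpp::export]]
NumericVector cpp_free_ligand(double K1, double K2,
                              NumericVector M, NumericVector Ltot) {
  R_xlen_t n = M.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = free_ligand_one(K1, K2, M[i], Ltot[i]);
  return out;
}

// Per-shot observable heats (kcal) given pre-evolved total concentrations.
// q_i = Q_i - Q_{i-1} + (dV_i/V0) (Q_i + Q_{i-1})/2
//       + dH_dil * (syringe_conc * 1e-6 * dV_i) + q_int,  Q_0 = 0
// [[Rcpp::export]]
NumericVector cpp_injection_heats(double K1, double K2,
                                  double dH1, double dH2,
                                  double f_comp, double dH_dil, double q_int,
                                  NumericVector M_tot, NumericVector L_tot,
                                  NumericVector dV, double V0,
                                  double syringe_conc) {
  R_xlen_t n = M_tot.size();
  NumericVector q(n);
  double Qprev = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double M = f_comp * M_tot[i];
    double L = free_ligand_one(K1, K2, M, L_tot[i]);
    double P = 1.0 + K1 * L + K1 * K2 * L * L;
    double F1 = K1 * L / P;
    double F2 = K1 * K2 * L * L / P;
    double Q = V0 * (M * 1e-6) * (dH1 * F1 + (dH1 + dH2) * F2);
    q[i] = Q - Qprev + (dV[i] / V0) * 0.5 * (Q + Qprev)
           + dH_dil * (syringe_conc * 1e-6 * dV[i]) + q_int;
    Qprev = Q;
  }
  return q;
}

// Gaussian log-likelihood of one experiment's observed heats under the
// forward model; used by the MCMC hot loop.
// [[Rcpp::export]]
double cpp_loglik_exp(double K1, double K2, double dH1, double dH2,
                      double f_comp, double dH_dil, double q_int,
                      double sigma,
                      NumericVector M_tot, NumericVector L_tot,
                      NumericVector dV, double V0, double syringe_conc,
                      NumericVector obs) {
  R_xlen_t n = M_tot.size();
  double Qprev = 0.0;
  double ll = 0.0;
  const double log2pi = 1.8378770664093454836;
  for (R_xlen_t i = 0; i < n; ++i) {
    double M = f_comp * M_tot[i];
    double L = free_ligand_one(K1, K2, M, L_tot[i]);
    double P = 1.0 + K1 * L + K1 * K2 * L * L;
    double F1 = K1 * L / P;
    double F2 = K1 * K2 * L * L / P;
    double Q = V0 * (M * 1e-6) * (dH1 * F1 + (dH1 + dH2) * F2);
    double q = Q - Qprev + (dV[i] / V0) * 0.5 * (Q + Qprev)
               + dH_dil * (syringe_conc * 1e-6 * dV[i]) + q_int;
    Qprev = Q;
    double r = (obs[i] - q) / sigma;
    ll += -0.5 * r * r - std::log(sigma) - 0.5 * log2pi;
  }
  return ll;
}
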