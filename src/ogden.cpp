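// Ogden hyperelasticity at a material point: energy, principal stresses,
// first Piola stress and its consistent tangent via the spectral form of
// the material elasticity tensor. Repeated principal stretches are handled
// by a tiny symmetric perturbation inside the tangent ratios only.
#include "ogden.h"
using namespace arma;

double ogden_W_iso(const vec& lam, const vec& a, const vec& b) {
  double J = lam(0) * lam(1) * lam(2);
  double Jm13 = std::pow(J, -1.0 / 3.0);
  double W = 0.0;
  for (uword t = 0; t < a.n_elem; ++t) {
    double s = 0.0;
    for (int i = 0; i < 3; ++i) s += std::pow(Jm13 * lam(i), b(t));
    W += (a(t) / b(t)) * (s - 3.0);
  }
  return W;
}

void ogden_tau_iso(const vec& lam, const vec& a, const vec& b,
                   vec& tau, mat& dtau, bool want_dtau) {
  double J = lam(0) * lam(1) * lam(2);
  double Jm13 = std::pow(J, -1.0 / 3.0);
  tau.zeros(3);
  if (want_dtau) dtau.zeros(3, 3);
  for (uword t = 0; t < a.n_elem; ++t) {
    vec g(3);
    for (int i = 0; i < 3; ++i) g(i) = std::pow(Jm13 * lam(i), b(t));
    double gm = (g(0) + g(1) + g(2)) / 3.0;
    for (int i = 0; i < 3; ++i) tau(i) += a(t) * (g(i) - gm);
    if (want_dtau) {
      // d g_i / d lam_j = b * g_i * (delta_ij - 1/3) / lam_j
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double dgi = b(t) * g(i) * ((i == j ? 1.0 : 0.0) - 1.0 / 3.0) / lam(j);
          double dgm = 0.0;
          for (int k = 0; k < 3; ++k)
            dgm += b(t) * g(k) * ((k == j ? 1.0 : 0.0) - 1.0 / 3.0) / lam(j);
          dgm /= 3.0;
          dtau(i, j) += a(t) * (dgi - dgm);
        }
    }
  }
}

bool vol_PA(const mat& F, double kappa, mat& P, mat& A, bool want_A) {
  double J = det(F);
  if (J <= 0.0) return false;
  mat FinvT = inv(F).t();
  double Up = kappa * std::log(J) / J;          // U'(J)
  double Upp = kappa * (1.0 - std::log(J)) / (J * J);
  P = Up * J * FinvT;
  if (want_A) {
    A.set_size(9, 9);
    for (int i = 0; i < 3; ++i)
      for (int Jj = 0; Jj < 3; ++Jj)
        for (int k = 0; k < 3; ++k)
          for (int L = 0; L < 3; ++L) {
            double v = (Upp * J + Up) * J * FinvT(k, L) * FinvT(i, Jj)
                     - Up * J * FinvT(i, L) * FinvT(k, Jj);
            A(i + 3 * Jj, k + 3 * L) = v;
          }
  }
  return true;
}

// Spectral material elasticity (Holzapfel-style) from principal second
// Piola stresses S_i(lam) and their derivatives, pushed to A = dP/dF.
bool ogden_PA(const mat& F, const vec& a, const vec& b, double kappa,
              bool with_vol, mat& P, mat& A, bool want_A, double* W_iso_out) {
  double J = det(F);
  if (J <= 0.0) return false;
  mat C = F.t() * F;
  vec lam2;
  mat M;
  if (!eig_sym(lam2, M, C)) return false;
  lam2 = clamp(lam2, 1e-14, datum::inf);
  vec lam = sqrt(lam2);
  if (W_iso_out) *W_iso_out = ogden_W_iso(lam, a, b);

  vec tau;
  mat dtau;
  ogden_tau_iso(lam, a, b, tau, dtau, want_A);
  // S_i = tau_i / lam_i^2
  vec S3(3);
  for (int i = 0; i < 3; ++i) S3(i) = tau(i) / lam2(i);

  mat S = zeros<mat>(3, 3);
  for (int i = 0; i < 3; ++i) S += S3(i) * (M.col(i) * M.col(i).t());
  P = F * S;

  if (want_A) {
    // perturbed stretches for the tangent only, so coalescent-eigenvalue
    // ratios become stable finite differences of the true limits
    vec lp = lam;
    const double del = 1e-5;
    double lref = (lam(0) + lam(1) + lam(2)) / 3.0;
    if (std::abs(lp(1) - lp(0)) < 1e-4 * lref) lp(1) *= (1.0 + del);
    if (std::abs(lp(2) - lp(0)) < 1e-4 * lref ||
        std::abs(lp(2) - lp(1)) < 1e-4 * lref) lp(2) *= (1.0 - del);
    vec taup;
    mat dtaup;
    ogden_tau_iso(lp, a, b, taup, dtaup, true);
    vec Sp(3);
    mat dS(3, 3);
    for (int i = 0; i < 3; ++i) {
      Sp(i) = taup(i) / (lp(i) * lp(i));
      for (int j = 0; j < 3; ++j)
        dS(i, j) = dtaup(i, j) / (lp(i) * lp(i))
                 - (i == j ? 2.0 * taup(i) / std::pow(lp(i), 3) : 0.0);
    }
    // material elasticity CC_IJKL (iso part)
    double CC[3][3][3][3] = {{{{0}}}};
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) {
        double c1 = dS(p, q) / lp(q);
        for (int I = 0; I < 3; ++I)
          for (int Jj = 0; Jj < 3; ++Jj)
            for (int K = 0; K < 3; ++K)
              for (int L = 0; L < 3; ++L)
                CC[I][Jj][K][L] += c1 * M(I, p) * M(Jj, p) * M(K, q) * M(L, q);
      }
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) {
        if (p == q) continue;
        double c2 = (Sp(q) - Sp(p)) / (lp(q) * lp(q) - lp(p) * lp(p));
        for (int I = 0; I < 3; ++I)
          for (int Jj = 0; Jj < 3; ++Jj)
            for (int K = 0; K < 3; ++K)
              for (int L = 0; L < 3; ++L)
                CC[I][Jj][K][L] += c2 * (M(I, p) * M(Jj, q) * M(K, p) * M(L, q)
                                       + M(I, p) * M(Jj, q) * M(K, q) * M(L, p));
      }
    A.zeros(9, 9);
    for (int i = 0; i < 3; ++i)
      for (int Jj = 0; Jj < 3; ++Jj)
        for (int k = 0; k < 3; ++k)
          for (int L = 0; L < 3; ++L) {
            double v = (i == k ? S(L, Jj) : 0.0);
            for (int I = 0; I < 3; ++I)
              for (int K = 0; K < 3; ++K)
                v += F(i, I) * CC[I][Jj][K][L] * F(k, K);
            A(i + 3 * Jj, k + 3 * L) = v;
          }
  }

  if (with_vol && kappa > 0.0) {
    mat Pv, Av;
    if (!vol_PA(F, kappa, Pv, Av, want_A)) return false;
    P += Pv;
    if (want_A) A += Av;
  }
  return true;
}

// ---- R-facing point-wise wrappers -------------------------------------

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".ogden_energy_cpp")]]
double ogden_energy_cpp(arma::vec lam, arma::vec a, arma::vec b, double kappa) {
  double J = lam(0) * lam(1) * lam(2);
  return ogden_W_iso(lam, a, b) + 0.5 * kappa * std::pow(std::log(J), 2);
}

// [[Rcpp::export(name = ".ogden_stress_cpp")]]
Rcpp::List ogden_stress_cpp(arma::mat F, arma::vec a, arma::vec b,
                            double kappa, bool want_A) {
  arma::mat P, A;
  bool ok = ogden_PA(F, a, b, kappa, true, P, A, want_A);
  if (!ok) Rcpp::stop("deformation gradient has non-positive determinant");
  double J = det(F);
  arma::mat sigma = (P * F.t()) / J;
  sigma = 0.5 * (sigma + sigma.t());
  if (want_A)
    return Rcpp::List::create(Rcpp::Named("sigma") = sigma,
                              Rcpp::Named("P") = P, Rcpp::Named("A") = A);
  return Rcpp::List::create(Rcpp::Named("sigma") = sigma,
                            Rcpp::Named("P") = P);
}
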