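#pragma once
#include <RcppArmadillo.h>

// Isochoric Ogden evaluated on unit-volume-scaled stretches, plus a
// quadratic-log volumetric penalty U(J) = 0.5*kappa*(ln J)^2.

double ogden_W_iso(const arma::vec& lam, const arma::vec& a, const arma::vec& b);

// principal isochoric Kirchhoff stresses tau_i and d tau_i / d lambda_j
void ogden_tau_iso(const arma::vec& lam, const arma::vec& a, const arma::vec& b,
                   arma::vec& tau, arma::mat& dtau, bool want_dtau);

// First Piola stress P(F) and (optionally) the 9x9 tangent A = dP/dF for the
// isochoric part; with_vol adds the volumetric penalty at the same point.
// Column-major vec(F) index convention: iJ -> i + 3*J.
// Returns false on det(F) <= 0.
bool ogden_PA(const arma::mat& F, const arma::vec& a, const arma::vec& b,
              double kappa, bool with_vol, arma::mat& P, arma::mat& A,
              bool want_A, double* W_iso_out = nullptr);

// Volumetric-only P and A at F (used by selective reduced integration).
bool vol_PA(const arma::mat& F, double kappa, arma::mat& P, arma::mat& A,
            bool want_A);
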