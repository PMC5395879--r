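// Total-Lagrangian assembly over 8-node hexahedra, optionally enhanced with
// statically condensed incompatible bending modes. The isochoric term uses
// full 2x2x2 Gauss quadrature; the volumetric penalty acts on the
// volume-averaged Jacobian (mean dilatation) so near-incompressibility does
// not lock. Residual and tangent are exact derivatives of the discrete
// energy.
#include "ogden.h"
using namespace arma;

static const double GP = 0.5773502691896258;

static void hex_dNdxi(double xi, double eta, double zeta, mat& dN, vec& N) {
  static const double sgn[8][3] = {
    {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
    {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};
  dN.set_size(8, 3);
  N.set_size(8);
  for (int a = 0; a < 8; ++a) {
    double sx = sgn[a][0], sy = sgn[a][1], sz = sgn[a][2];
    N(a) = 0.125 * (1 + sx * xi) * (1 + sy * eta) * (1 + sz * zeta);
    dN(a, 0) = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta);
    dN(a, 1) = 0.125 * (1 + sx * xi) * sy * (1 + sz * zeta);
    dN(a, 2) = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz;
  }
}

// dNdX and reference Jacobian determinant at a natural point
static double grad_map(const mat& Xe, double xi, double eta, double zeta,
                       mat& dNdX) {
  mat dN;
  vec N;
  hex_dNdxi(xi, eta, zeta, dN, N);
  mat Jm = dN.t() * Xe;          // Jm(i,j) = dX_j / dxi_i
  double dJ = det(Jm);
  dNdX = dN * inv(Jm).t();       // dN_a/dX_j
  return dJ;
}

static void def_grad(const mat& Ue, const mat& dNdX, mat& F) {
  F = eye<mat>(3, 3) + Ue.t() * dNdX;   // F(i,j) = d u_i/d X_j + delta
}

struct Triplets {
  std::vector<uword> ii, jj;
  std::vector<double> xx;
  void reserve(size_t n) { ii.reserve(n); jj.reserve(n); xx.reserve(n); }
  void add_block(const uvec& dofs, const mat& Ke) {
    for (uword p = 0; p < dofs.n_elem; ++p)
      for (uword q = 0; q < dofs.n_elem; ++q) {
        double v = Ke(p, q);
        if (v != 0.0) { ii.push_back(dofs(p)); jj.push_back(dofs(q)); xx.push_back(v); }
      }
  }
  sp_mat to_sp(uword n) const {
    umat loc(2, ii.size());
    vec val(xx.size());
    for (size_t k = 0; k < ii.size(); ++k) {
      loc(0, k) = ii[k];
      loc(1, k) = jj[k];
      val(k) = xx[k];
    }
    return sp_mat(true, loc, val, n, n, true, false);
  }
};

// [[Rcpp::depends(RcppArmadillo)]]

// Follower pressure on oriented quad facets; the quad normal x_,xi cross
// x_,eta points into the cavity, so positive pressure drives collapse.
// [[Rcpp::export(name = ".asm_pressure_cpp")]]
Rcpp::List asm_pressure_cpp(const arma::mat& X, const arma::umat& facets,
                            const arma::vec& u, double p, bool follower,
                            bool want_K) {
  uword nn = X.n_rows, nf = facets.n_rows, ndof = 3 * nn;
  vec f(ndof, fill::zeros);
  vec ftot(3, fill::zeros);
  Triplets tr;
  if (want_K) tr.reserve(nf * 144);
  static const double sq[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};

  for (uword e = 0; e < nf; ++e) {
    mat xe(4, 3);
    uvec dofs(12);
    for (int a = 0; a < 4; ++a) {
      uword n = facets(e, a);
      for (int i = 0; i < 3; ++i) {
        xe(a, i) = X(n, i) + (follower ? u(3 * n + i) : 0.0);
        dofs(3 * a + i) = 3 * n + i;
      }
    }
    vec fe(12, fill::zeros);
    mat Ke(12, 12, fill::zeros);
    for (int g = 0; g < 4; ++g) {
      double xi = sq[g][0] * GP, eta = sq[g][1] * GP;
      vec N(4), dNx(4), dNe(4);
      for (int a = 0; a < 4; ++a) {
        N(a) = 0.25 * (1 + sq[a][0] * xi) * (1 + sq[a][1] * eta);
        dNx(a) = 0.25 * sq[a][0] * (1 + sq[a][1] * eta);
        dNe(a) = 0.25 * (1 + sq[a][0] * xi) * sq[a][1];
      }
      vec xxi = xe.t() * dNx, xeta = xe.t() * dNe;
      vec nrm = cross(xxi, xeta);   // area-weighted normal (into cavity)
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) fe(3 * a + i) += p * N(a) * nrm(i);
      ftot += p * nrm;
      if (want_K && follower) {
        mat skx = {{0, -xxi(2), xxi(1)}, {xxi(2), 0, -xxi(0)}, {-xxi(1), xxi(0), 0}};
        mat ske = {{0, -xeta(2), xeta(1)}, {xeta(2), 0, -xeta(0)}, {-xeta(1), xeta(0), 0}};
        for (int a = 0; a < 4; ++a)
          for (int bq = 0; bq < 4; ++bq) {
            mat blk = p * N(a) * (dNx(bq) * (-ske) + dNe(bq) * skx);
            for (int i = 0; i < 3; ++i)
              for (int k = 0; k < 3; ++k) Ke(3 * a + i, 3 * bq + k) += blk(i, k);
          }
      }
    }
    for (int q = 0; q < 12; ++q) f(dofs(q)) += fe(q);
    if (want_K && follower) tr.add_block(dofs, Ke);
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("f") = f,
                                      Rcpp::Named("ftot") = ftot);
  if (want_K) out["K"] = tr.to_sp(ndof);
  return out;
}

// Frictionless node-to-facet penalty self-contact among the luminal facets.
// Facet normals point into the cavity; a slave node from the opposing wall
// penetrates when its signed distance along the facet normal turns negative.
// [[Rcpp::export(name = ".asm_contact_cpp")]]
Rcpp::List asm_contact_cpp(const arma::mat& X, const arma::umat& facets,
                           const arma::vec& u, double penalty, double cap,
                           bool want_K) {
  uword nn = X.n_rows, nf = facets.n_rows, ndof = 3 * nn;
  vec f(ndof, fill::zeros);
  Triplets tr;

  mat x = X;
  for (uword n = 0; n < nn; ++n)
    for (int i = 0; i < 3; ++i) x(n, i) += u(3 * n + i);

  // facet normals/centroids/areas, node normals and tributary areas
  mat fn(nf, 3), fc(nf, 3);
  vec fr(nf), fa(nf);
  mat nodal_n(nn, 3, fill::zeros);
  vec nodal_a(nn, fill::zeros);
  std::vector<char> is_lum(nn, 0);
  for (uword e = 0; e < nf; ++e) {
    rowvec x0 = x.row(facets(e, 0)), x1 = x.row(facets(e, 1)),
           x2 = x.row(facets(e, 2)), x3 = x.row(facets(e, 3));
    rowvec d1 = x2 - x0, d2 = x3 - x1;
    rowvec nr(3);
    nr(0) = d1(1) * d2(2) - d1(2) * d2(1);
    nr(1) = d1(2) * d2(0) - d1(0) * d2(2);
    nr(2) = d1(0) * d2(1) - d1(1) * d2(0);
    double a2 = norm(nr);
    fa(e) = 0.5 * a2;
    fn.row(e) = nr / std::max(a2, 1e-300);
    fc.row(e) = 0.25 * (x0 + x1 + x2 + x3);
    double r = 0.0;
    for (int a = 0; a < 4; ++a)
      r = std::max(r, norm(x.row(facets(e, a)) - fc.row(e)));
    fr(e) = r;
    for (int a = 0; a < 4; ++a) {
      uword n = facets(e, a);
      is_lum[n] = 1;
      nodal_n.row(n) += fn.row(e);
      nodal_a(n) += 0.25 * fa(e);
    }
  }
  for (uword n = 0; n < nn; ++n)
    if (is_lum[n]) {
      double l = norm(nodal_n.row(n));
      if (l > 0) nodal_n.row(n) /= l;
    }

  double max_pen = 0.0;
  int n_active = 0;
  static const int tri[2][3] = {{0, 1, 2}, {0, 2, 3}};

  for (uword s = 0; s < nn; ++s) {
    if (!is_lum[s]) continue;
    rowvec xs = x.row(s);
    for (uword e = 0; e < nf; ++e) {
      bool own = false;
      for (int a = 0; a < 4; ++a) own = own || (facets(e, a) == s);
      if (own) continue;
      if (dot(nodal_n.row(s), fn.row(e)) > -0.2) continue;  // not opposing
      if (norm(xs - fc.row(e)) > fr(e) + cap) continue;
      for (int t = 0; t < 2; ++t) {
        uword i0 = facets(e, tri[t][0]), i1 = facets(e, tri[t][1]),
              i2 = facets(e, tri[t][2]);
        rowvec p0 = x.row(i0), p1 = x.row(i1), p2 = x.row(i2);
        rowvec e1 = p1 - p0, e2 = p2 - p0;
        rowvec nr(3);
        nr(0) = e1(1) * e2(2) - e1(2) * e2(1);
        nr(1) = e1(2) * e2(0) - e1(0) * e2(2);
        nr(2) = e1(0) * e2(1) - e1(1) * e2(0);
        double nl = norm(nr);
        if (nl < 1e-14) continue;
        nr /= nl;
        double g = dot(xs - p0, nr);
        if (g >= 0.0 || g <= -cap) continue;
        // barycentric coordinates of the in-plane projection
        rowvec q = xs - g * nr - p0;
        double d11 = dot(e1, e1), d12 = dot(e1, e2), d22 = dot(e2, e2);
        double dq1 = dot(q, e1), dq2 = dot(q, e2);
        double den = d11 * d22 - d12 * d12;
        if (std::abs(den) < 1e-20) continue;
        double b1 = (d22 * dq1 - d12 * dq2) / den;
        double b2 = (d11 * dq2 - d12 * dq1) / den;
        double b0 = 1.0 - b1 - b2;
        const double tol = -0.02;
        if (b0 < tol || b1 < tol || b2 < tol) continue;
        double As = nodal_a(s);
        double k = penalty * As;
        vec nrv = nr.t();
        // force on slave along +n (g < 0), reactions on triangle nodes
        uword ids[4] = {s, i0, i1, i2};
        double w[4] = {1.0, -b0, -b1, -b2};
        for (int pj = 0; pj < 4; ++pj)
          for (int i = 0; i < 3; ++i)
            f(3 * ids[pj] + i) += -k * g * w[pj] * nrv(i);
        if (want_K) {
          mat nn3 = k * (nrv * nrv.t());
          for (int pj = 0; pj < 4; ++pj)
            for (int qj = 0; qj < 4; ++qj) {
              uvec dd(6);
              mat blk = w[pj] * w[qj] * nn3;
              for (int i = 0; i < 3; ++i)
                for (int kk = 0; kk < 3; ++kk)
                  if (blk(i, kk) != 0.0) {
                    tr.ii.push_back(3 * ids[pj] + i);
                    tr.jj.push_back(3 * ids[qj] + kk);
                    tr.xx.push_back(blk(i, kk));
                  }
            }
        }
        ++n_active;
        max_pen = std::max(max_pen, -g);
        break;  // one triangle per facet
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("f") = f, Rcpp::Named("max_penetration") = max_pen,
      Rcpp::Named("n_active") = n_active);
  if (want_K) out["K"] = tr.to_sp(ndof);
  return out;
}

// ---- cached-sparsity fast path ------------------------------------------
// The stiffness sparsity of the internal + follower-pressure terms is fixed
// by the mesh (every pressure facet lies on the surface of one element), so
// the CSC pattern is computed once and per-iteration assembly only fills the
// value array. Contact contributions have a changing pattern and stay on the
// triplet path.

// [[Rcpp::export(name = ".asm_pattern_cpp")]]
Rcpp::List asm_pattern_cpp(const arma::umat& elems, const arma::umat& facets,
                           int nn) {
  uword ndof = 3 * (uword)nn;
  uword ne = elems.n_rows, nf = facets.n_rows;
  // collect unique (row, col) pairs as col * ndof + row
  std::vector<long long> keys;
  keys.reserve(ne * 576 + nf * 144);
  auto add_pairs = [&](const std::vector<uword>& dofs) {
    for (size_t p = 0; p < dofs.size(); ++p)
      for (size_t q = 0; q < dofs.size(); ++q)
        keys.push_back((long long)dofs[q] * ndof + dofs[p]);
  };
  for (uword e = 0; e < ne; ++e) {
    std::vector<uword> dofs(24);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) dofs[3 * a + i] = 3 * elems(e, a) + i;
    add_pairs(dofs);
  }
  for (uword f = 0; f < nf; ++f) {
    std::vector<uword> dofs(12);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) dofs[3 * a + i] = 3 * facets(f, a) + i;
    add_pairs(dofs);
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  size_t nnz = keys.size();
  Rcpp::IntegerVector P(ndof + 1), I(nnz);
  for (size_t k = 0; k < nnz; ++k) {
    I[k] = (int)(keys[k] % ndof);
    ++P[(int)(keys[k] / ndof) + 1];
  }
  for (uword c = 0; c < ndof; ++c) P[c + 1] += P[c];
  // position lookup: binary search within a column
  auto pos_of = [&](uword row, uword col) -> int {
    long long key = (long long)col * ndof + row;
    auto it = std::lower_bound(keys.begin(), keys.end(), key);
    return (int)(it - keys.begin());
  };
  Rcpp::IntegerVector map_e(ne * 576), map_f(nf * 144);
  for (uword e = 0; e < ne; ++e) {
    uword dofs[24];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) dofs[3 * a + i] = 3 * elems(e, a) + i;
    for (int p = 0; p < 24; ++p)
      for (int q = 0; q < 24; ++q)
        map_e[e * 576 + q * 24 + p] = pos_of(dofs[p], dofs[q]);
  }
  for (uword f = 0; f < nf; ++f) {
    uword dofs[12];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) dofs[3 * a + i] = 3 * facets(f, a) + i;
    for (int p = 0; p < 12; ++p)
      for (int q = 0; q < 12; ++q)
        map_f[f * 144 + q * 12 + p] = pos_of(dofs[p], dofs[q]);
  }
  return Rcpp::List::create(Rcpp::Named("p") = P, Rcpp::Named("i") = I,
                            Rcpp::Named("nnz") = (double)nnz,
                            Rcpp::Named("map_e") = map_e,
                            Rcpp::Named("map_f") = map_f);
}

// Per-element workspace for the (optionally enhanced) hexahedron.
// Enhanced mode: three incompatible displacement modes (1 - xi_i^2) with
// gradients evaluated through the centroid Jacobian and volume-mean
// corrected (so the patch test holds and homogeneous states are untouched),
// statically condensed by minimizing the element energy over the internal
// dofs. The condensed energy is still an exact function of the nodal dofs,
// so residual/tangent FD consistency is preserved.
struct HexScratch {
  mat dNdX[8], dNdXc;     // cartesian shape gradients per gp and centroid
  double dJ[8], Vref;
  vec Gm[8][3], Gmc[3];   // enhanced-mode gradients per gp / centroid
};

static bool hex_precompute(const mat& Xe, bool enhanced, HexScratch& S) {
  S.Vref = 0.0;
  mat dN;
  vec N;
  double xg[8][3];
  for (int g = 0; g < 8; ++g) {
    xg[g][0] = (g & 1) ? GP : -GP;
    xg[g][1] = (g & 2) ? GP : -GP;
    xg[g][2] = (g & 4) ? GP : -GP;
    S.dJ[g] = grad_map(Xe, xg[g][0], xg[g][1], xg[g][2], S.dNdX[g]);
    if (S.dJ[g] <= 0.0) return false;
    S.Vref += S.dJ[g];
  }
  grad_map(Xe, 0, 0, 0, S.dNdXc);
  if (enhanced) {
    hex_dNdxi(0, 0, 0, dN, N);
    mat Jc = dN.t() * Xe;            // dX_j/dxi_i at the centroid
    mat dxi_dX = inv(Jc.t());        // (i,j) = dxi_i/dX_j
    vec gi[3];
    for (int i = 0; i < 3; ++i) gi[i] = dxi_dX.row(i).t();
    vec mean[3];
    for (int i = 0; i < 3; ++i) mean[i] = zeros<vec>(3);
    for (int g = 0; g < 8; ++g)
      for (int i = 0; i < 3; ++i) {
        S.Gm[g][i] = -2.0 * xg[g][i] * gi[i];
        mean[i] += (S.dJ[g] / S.Vref) * S.Gm[g][i];
      }
    for (int g = 0; g < 8; ++g)
      for (int i = 0; i < 3; ++i) S.Gm[g][i] -= mean[i];
    for (int i = 0; i < 3; ++i) S.Gmc[i] = -mean[i];  // xi = 0
  }
  return true;
}

// deformation gradient at gp (or centroid with g = -1) including modes
static void hex_defgrad(const HexScratch& S, const mat& Ue, const vec& alpha,
                        bool enhanced, int g, mat& F) {
  const mat& dN = (g < 0) ? S.dNdXc : S.dNdX[g];
  F = eye<mat>(3, 3) + Ue.t() * dN;
  if (enhanced)
    for (int i = 0; i < 3; ++i) {
      const vec& Gv = (g < 0) ? S.Gmc[i] : S.Gm[g][i];
      for (int k = 0; k < 3; ++k)
        for (int n = 0; n < 3; ++n) F(k, n) += alpha(3 * i + k) * Gv(n);
    }
}

// extended B-matrix (vec F vs [u; alpha]) at gp / centroid
static void hex_Gmat(const HexScratch& S, bool enhanced, int g, mat& G) {
  int nc = enhanced ? 33 : 24;
  G.zeros(9, nc);
  const mat& dN = (g < 0) ? S.dNdXc : S.dNdX[g];
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i)
      for (int J = 0; J < 3; ++J)
        G(i + 3 * J, 3 * a + i) = dN(a, J);
  if (enhanced)
    for (int i = 0; i < 3; ++i) {
      const vec& Gv = (g < 0) ? S.Gmc[i] : S.Gm[g][i];
      for (int k = 0; k < 3; ++k)
        for (int n = 0; n < 3; ++n) G(k + 3 * n, 24 + 3 * i + k) = Gv(n);
    }
}

// element energy at (u, alpha); +inf on inversion. The volumetric penalty
// acts on the volume-averaged Jacobian (mean dilatation), which keeps the
// penalty locking-free and leaves homogeneous states untouched by the
// incompatible modes (patch test).
static double hex_energy(const HexScratch& S, const mat& Ue, const vec& alpha,
                         bool enhanced, const vec& a_, const vec& b_,
                         double kap) {
  double E = 0.0, Jbar = 0.0;
  mat F;
  for (int g = 0; g < 8; ++g) {
    hex_defgrad(S, Ue, alpha, enhanced, g, F);
    if (!F.is_finite()) return datum::inf;
    double Jg = det(F);
    if (Jg <= 0.0) return datum::inf;
    Jbar += S.dJ[g] * Jg / S.Vref;
    mat C = F.t() * F;
    vec l2 = clamp(eig_sym(C), 1e-14, datum::inf);
    E += S.dJ[g] * ogden_W_iso(sqrt(l2), a_, b_);
  }
  if (Jbar <= 0.0) return datum::inf;
  E += S.Vref * 0.5 * kap * std::pow(std::log(Jbar), 2);
  return E;
}

// gradient/hessian of the element energy w.r.t. [u; alpha]
static bool hex_grad_hess(const HexScratch& S, const mat& Ue, const vec& alpha,
                          bool enhanced, const vec& a_, const vec& b_,
                          double kap, vec& fe, mat& Ke, bool want_K,
                          double& energy, double& min_detF) {
  int nc = enhanced ? 33 : 24;
  fe.zeros(nc);
  if (want_K) Ke.zeros(nc, nc);
  mat F, P, A, G;
  double Jbar = 0.0;
  vec bvec(nc, fill::zeros);       // d Jbar / d q
  mat Hj;                          // U'-weighted second derivative of Jbar
  if (want_K) Hj.zeros(nc, nc);
  for (int g = 0; g < 8; ++g) {
    hex_defgrad(S, Ue, alpha, enhanced, g, F);
    if (!F.is_finite()) return false;
    double jF = det(F);
    if (jF < min_detF) min_detF = jF;
    if (jF <= 0.0) return false;
    double Wg = 0.0;
    if (!ogden_PA(F, a_, b_, 0.0, false, P, A, want_K, &Wg)) return false;
    hex_Gmat(S, enhanced, g, G);
    fe += S.dJ[g] * (G.t() * vectorise(P));
    if (want_K) Ke += S.dJ[g] * (G.t() * A * G);
    energy += S.dJ[g] * Wg;
    // mean-dilatation bookkeeping via the closed-form contraction of
    // d cof(F)/dF with the B-matrix: with c_{kappa,k} = sum_J v_kappa(J)
    // FinvT(k,J) (v = shape/mode gradient rows), the contributions are
    // b[(kappa,i)] = J c_{kappa,i} and
    // (G' D G)[(kappa,i),(mu,k)] = J (c_{kappa,i} c_{mu,k} - c_{kappa,k} c_{mu,i})
    mat FinvT = inv(F).t();
    int nent = enhanced ? 11 : 8;
    mat Cm(nent, 3);
    Cm.rows(0, 7) = S.dNdX[g] * FinvT.t();
    if (enhanced)
      for (int m2 = 0; m2 < 3; ++m2)
        for (int k = 0; k < 3; ++k)
          Cm(8 + m2, k) = dot(S.Gm[g][m2], FinvT.row(k).t());
    Jbar += S.dJ[g] * jF / S.Vref;
    double wj = S.dJ[g] * jF;
    for (int kp = 0; kp < nent; ++kp)
      for (int i = 0; i < 3; ++i)
        bvec(3 * kp + i) += (wj / S.Vref) * Cm(kp, i);
    if (want_K) {
      for (int kp = 0; kp < nent; ++kp)
        for (int i = 0; i < 3; ++i) {
          int p = 3 * kp + i;
          for (int mu = 0; mu < nent; ++mu)
            for (int k = 0; k < 3; ++k)
              Hj(p, 3 * mu + k) +=
                wj * (Cm(kp, i) * Cm(mu, k) - Cm(kp, k) * Cm(mu, i));
        }
    }
  }
  if (Jbar <= 0.0) return false;
  double Up = kap * std::log(Jbar) / Jbar;
  double Upp = kap * (1.0 - std::log(Jbar)) / (Jbar * Jbar);
  fe += S.Vref * Up * bvec;
  energy += S.Vref * 0.5 * kap * std::pow(std::log(Jbar), 2);
  if (want_K) Ke += S.Vref * (Upp * (bvec * bvec.t())) + Up * Hj;
  return true;
}

// gradient/hessian of the element energy w.r.t. the modes only, plus the
// nodal force scale (cheap inner kernel for the static condensation loop)
static bool hex_mode_grad(const HexScratch& S, const mat& Ue, const vec& alpha,
                          const vec& a_, const vec& b_, double kap,
                          vec& ga, mat& Ha, double& fscale) {
  ga.zeros(9);
  Ha.zeros(9, 9);
  double fsq = 0.0, Jbar = 0.0;
  vec ba(9, fill::zeros);
  mat Hj(9, 9, fill::zeros);
  mat F, P, A, Ga(9, 9);
  for (int gp = 0; gp < 8; ++gp) {
    double wgt = S.dJ[gp];
    hex_defgrad(S, Ue, alpha, true, gp, F);
    if (!F.is_finite()) return false;
    double jF = det(F);
    if (jF <= 0.0) return false;
    if (!ogden_PA(F, a_, b_, 0.0, false, P, A, true)) return false;
    Ga.zeros();
    for (int i = 0; i < 3; ++i) {
      const vec& Gv = S.Gm[gp][i];
      for (int k = 0; k < 3; ++k)
        for (int n = 0; n < 3; ++n) Ga(k + 3 * n, 3 * i + k) = Gv(n);
    }
    ga += wgt * (Ga.t() * vectorise(P));
    Ha += wgt * (Ga.t() * A * Ga);
    mat FinvT = inv(F).t();
    mat Cm(3, 3);   // modes only
    for (int m2 = 0; m2 < 3; ++m2)
      for (int k = 0; k < 3; ++k)
        Cm(m2, k) = dot(S.Gm[gp][m2], FinvT.row(k).t());
    Jbar += wgt * jF / S.Vref;
    double wj = wgt * jF;
    for (int m2 = 0; m2 < 3; ++m2)
      for (int i = 0; i < 3; ++i)
        ba(3 * m2 + i) += (wj / S.Vref) * Cm(m2, i);
    for (int m2 = 0; m2 < 3; ++m2)
      for (int i = 0; i < 3; ++i)
        for (int mu = 0; mu < 3; ++mu)
          for (int k = 0; k < 3; ++k)
            Hj(3 * m2 + i, 3 * mu + k) +=
              wj * (Cm(m2, i) * Cm(mu, k) - Cm(m2, k) * Cm(mu, i));
    const mat& dN = S.dNdX[gp];
    // nodal force contribution norm (for the relative tolerance)
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double v = 0.0;
        for (int J = 0; J < 3; ++J) v += P(i, J) * dN(a, J);
        fsq += (wgt * v) * (wgt * v);
      }
  }
  if (Jbar <= 0.0) return false;
  double Up = kap * std::log(Jbar) / Jbar;
  double Upp = kap * (1.0 - std::log(Jbar)) / (Jbar * Jbar);
  ga += S.Vref * Up * ba;
  Ha += S.Vref * (Upp * (ba * ba.t())) + Up * Hj;
  fscale = std::sqrt(fsq);
  return true;
}


// static condensation: minimize the element energy over the incompatible
// modes at fixed nodal displacements; returns false when the local Newton
// cannot reduce the mode gradient sufficiently
static bool hex_solve_modes(const HexScratch& S, const mat& Ue,
                            const vec& a_, const vec& b_, double kap,
                            vec& alpha) {
  bool lok = false;
  double ga_norm = datum::inf, fscale = 1e-8;
  vec ga;
  mat Ha;
  for (int it = 0; it < 40; ++it) {
    if (!hex_mode_grad(S, Ue, alpha, a_, b_, kap, ga, Ha, fscale)) {
      if (it == 0 && norm(alpha) > 0) { alpha.zeros(); continue; }
      ga_norm = datum::inf;
      break;
    }
    ga_norm = norm(ga);
    fscale = std::max(fscale, 1e-8);
    if (ga_norm <= 1e-9 * fscale) { lok = true; break; }
    // the mode energy can lose convexity at large compressive states:
    // if the plain Newton direction is not a descent direction, fall back
    // to an eigenvalue-shifted (modified Newton) solve. Ha is symmetrized;
    // the coalescent-stretch perturbation leaves ~1e-5 asymmetry.
    mat Has = 0.5 * (Ha + Ha.t());
    vec da;
    double shift = 0.0;
    bool solved = solve(da, Has, -ga);
    if (!solved || dot(da, ga) >= 0) {
      vec eh;
      if (!eig_sym(eh, Has)) break;
      shift = (eh(0) <= 0.0) ? (-eh(0) + 1e-3 * std::abs(eh(8)) + 1e-12)
                             : 1e-8 * std::abs(eh(8));
      if (!solve(da, Has + shift * eye<mat>(9, 9), -ga)) break;
    }
    double step = 1.0;
    if (shift > 0.0 || ga_norm > 1e-3 * fscale) {
      double E0 = hex_energy(S, Ue, alpha, true, a_, b_, kap);
      int bt = 0;
      while (bt < 25) {
        double E1 = hex_energy(S, Ue, alpha + step * da, true, a_, b_, kap);
        if (std::isfinite(E1) && E1 <= E0 + 1e-10 * std::abs(E0) + 1e-300)
          break;
        step *= 0.5;
        ++bt;
      }
      if (bt >= 25) break;
    }
    alpha += step * da;
    if (step * norm(da) <= 1e-13 * (1.0 + norm(alpha))) {
      if (hex_mode_grad(S, Ue, alpha, a_, b_, kap, ga, Ha, fscale))
        ga_norm = norm(ga);
      break;
    }
  }
  return lok || ga_norm <= 1e-6 * std::max(fscale, 1e-8);
}

// internal forces; tangent values accumulated into xval via map_e
// [[Rcpp::export(name = ".asm_internal_fill_cpp")]]
Rcpp::List asm_internal_fill_cpp(const arma::mat& X, const arma::umat& elems,
                                 const arma::vec& u, const Rcpp::List& mat_a,
                                 const Rcpp::List& mat_b,
                                 const arma::vec& mat_kappa,
                                 const arma::uvec& elem_mat,
                                 const Rcpp::IntegerVector& map_e,
                                 Rcpp::NumericVector xval, bool want_K,
                                 bool enhanced, Rcpp::NumericMatrix alpha_io) {
  uword nn = X.n_rows, ne = elems.n_rows, ndof = 3 * nn;
  vec f(ndof, fill::zeros);
  double energy = 0.0, min_detF = datum::inf;
  bool ok = true;
  int bad_elem = -1, bad_code = 0;
  uword nmat = mat_kappa.n_elem;
  std::vector<vec> av(nmat), bv(nmat);
  for (uword m = 0; m < nmat; ++m) {
    av[m] = Rcpp::as<vec>(mat_a[m]);
    bv[m] = Rcpp::as<vec>(mat_b[m]);
  }
  double* xv = xval.begin();
  const int* me = map_e.begin();
  // no-copy view onto the persistent warm-start storage (9 x ne)
  mat alpha_m(alpha_io.begin(), 9, enhanced ? ne : 0, false, true);
  HexScratch S;
  vec fe;
  mat Ke;

  for (uword e = 0; e < ne && ok; ++e) {
    mat Xe(8, 3), Ue(8, 3);
    uvec dofs(24);
    for (int a = 0; a < 8; ++a) {
      uword n = elems(e, a);
      Xe.row(a) = X.row(n);
      for (int i = 0; i < 3; ++i) {
        Ue(a, i) = u(3 * n + i);
        dofs(3 * a + i) = 3 * n + i;
      }
    }
    uword m = elem_mat(e);
    const vec& a_ = av[m];
    const vec& b_ = bv[m];
    double kap = mat_kappa(m);
    if (!hex_precompute(Xe, enhanced, S)) { ok = false; bad_elem = e; bad_code = 1; break; }

    vec alpha(9, fill::zeros);
    if (enhanced) {
      alpha = alpha_m.col(e);   // warm start from the previous assembly
      bool okm = hex_solve_modes(S, Ue, a_, b_, kap, alpha);
      if (!okm && norm(alpha_m.col(e)) > 0) {
        // a contaminated warm start can sit in a spurious basin: cold restart
        alpha.zeros();
        okm = hex_solve_modes(S, Ue, a_, b_, kap, alpha);
      }
      if (!okm) { ok = false; bad_elem = e; bad_code = 2; break; }
      alpha_m.col(e) = alpha;
    }

    double en = 0.0;
    if (!hex_grad_hess(S, Ue, alpha, enhanced, a_, b_, kap, fe, Ke, want_K,
                       en, min_detF)) { ok = false; bad_elem = e; bad_code = 3; break; }
    energy += en;

    vec fu = fe.head(24);
    mat Ku;
    if (want_K) {
      if (enhanced) {
        mat Kuu = Ke.submat(0, 0, 23, 23);
        mat Kua = Ke.submat(0, 24, 23, 32);
        mat Kaa = Ke.submat(24, 24, 32, 32);
        mat sol;
        if (!solve(sol, Kaa, Kua.t())) { ok = false; bad_elem = e; bad_code = 4; break; }
        Ku = Kuu - Kua * sol;
      } else {
        Ku = Ke;
      }
    }
    for (int p = 0; p < 24; ++p) f(dofs(p)) += fu(p);
    if (want_K) {
      const int* m0 = me + e * 576;
      for (int q = 0; q < 24; ++q)
        for (int p = 0; p < 24; ++p)
          xv[m0[q * 24 + p]] += Ku(p, q);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("f") = f, Rcpp::Named("energy") = energy,
      Rcpp::Named("ok") = ok, Rcpp::Named("min_detF") = min_detF,
      Rcpp::Named("bad_elem") = bad_elem, Rcpp::Named("bad_code") = bad_code);
}

// follower pressure; scaled tangent values accumulated into xval via map_f
// [[Rcpp::export(name = ".asm_pressure_fill_cpp")]]
Rcpp::List asm_pressure_fill_cpp(const arma::mat& X, const arma::umat& facets,
                                 const arma::vec& u, double p, bool follower,
                                 const Rcpp::IntegerVector& map_f,
                                 Rcpp::NumericVector xval, double kscale,
                                 bool want_K) {
  uword nn = X.n_rows, nf = facets.n_rows, ndof = 3 * nn;
  vec f(ndof, fill::zeros);
  vec ftot(3, fill::zeros);
  static const double sq[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};
  double* xv = xval.begin();
  const int* mf = map_f.begin();

  for (uword e = 0; e < nf; ++e) {
    mat xe(4, 3);
    uvec dofs(12);
    for (int a = 0; a < 4; ++a) {
      uword n = facets(e, a);
      for (int i = 0; i < 3; ++i) {
        xe(a, i) = X(n, i) + (follower ? u(3 * n + i) : 0.0);
        dofs(3 * a + i) = 3 * n + i;
      }
    }
    vec fe(12, fill::zeros);
    mat Ke(12, 12, fill::zeros);
    for (int g = 0; g < 4; ++g) {
      double xi = sq[g][0] * GP, eta = sq[g][1] * GP;
      vec N(4), dNx(4), dNe(4);
      for (int a = 0; a < 4; ++a) {
        N(a) = 0.25 * (1 + sq[a][0] * xi) * (1 + sq[a][1] * eta);
        dNx(a) = 0.25 * sq[a][0] * (1 + sq[a][1] * eta);
        dNe(a) = 0.25 * (1 + sq[a][0] * xi) * sq[a][1];
      }
      vec xxi = xe.t() * dNx, xeta = xe.t() * dNe;
      vec nrm = cross(xxi, xeta);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) fe(3 * a + i) += p * N(a) * nrm(i);
      ftot += p * nrm;
      if (want_K && follower) {
        mat skx = {{0, -xxi(2), xxi(1)}, {xxi(2), 0, -xxi(0)}, {-xxi(1), xxi(0), 0}};
        mat ske = {{0, -xeta(2), xeta(1)}, {xeta(2), 0, -xeta(0)}, {-xeta(1), xeta(0), 0}};
        for (int a = 0; a < 4; ++a)
          for (int bq = 0; bq < 4; ++bq) {
            mat blk = p * N(a) * (dNx(bq) * (-ske) + dNe(bq) * skx);
            for (int i = 0; i < 3; ++i)
              for (int k = 0; k < 3; ++k) Ke(3 * a + i, 3 * bq + k) += blk(i, k);
          }
      }
    }
    for (int q = 0; q < 12; ++q) f(dofs(q)) += fe(q);
    if (want_K && follower) {
      const int* m0 = mf + e * 144;
      for (int q = 0; q < 12; ++q)
        for (int p2 = 0; p2 < 12; ++p2)
          xv[m0[q * 12 + p2]] += kscale * Ke(p2, q);
    }
  }
  return Rcpp::List::create(Rcpp::Named("f") = f, Rcpp::Named("ftot") = ftot);
}

// single-element energy/gradient/hessian probe (internal, for verification)
// [[Rcpp::export(name = ".hex_probe_cpp")]]
Rcpp::List hex_probe_cpp(const arma::mat& Xe, const arma::mat& Ue,
                         const arma::vec& alpha, const arma::vec& a_,
                         const arma::vec& b_, double kap, bool enhanced) {
  HexScratch S;
  if (!hex_precompute(Xe, enhanced, S))
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  double E = hex_energy(S, Ue, alpha, enhanced, a_, b_, kap);
  vec fe;
  mat Ke;
  double en = 0.0, dmin = datum::inf;
  bool ok = hex_grad_hess(S, Ue, alpha, enhanced, a_, b_, kap, fe, Ke, true,
                          en, dmin);
  return Rcpp::List::create(Rcpp::Named("ok") = ok, Rcpp::Named("E") = E,
                            Rcpp::Named("f") = fe, Rcpp::Named("K") = Ke);
}

// Principal Green-Lagrange strains per element (descending): evaluated at
// the element centroid (mode = 0) or as the extreme values over the eight
// corner nodes (mode = 1; captures the bending fiber strain a centroid
// evaluation misses in one-element-thick walls). With enhanced != 0, the
// deformation gradient includes the statically condensed incompatible
// modes, re-solved from the displacement field (deterministic).
// [[Rcpp::export(name = ".elem_strains_cpp")]]
arma::mat elem_strains_cpp(const arma::mat& X, const arma::umat& elems,
                           const arma::vec& u, int at_corners, int enhanced,
                           const Rcpp::List& mat_a, const Rcpp::List& mat_b,
                           const arma::vec& mat_kappa,
                           const arma::uvec& elem_mat) {
  uword ne = elems.n_rows;
  mat out(ne, 3);
  mat dNdX, F;
  uword nmat = mat_kappa.n_elem;
  std::vector<vec> av(nmat), bv(nmat);
  for (uword m = 0; m < nmat; ++m) {
    av[m] = Rcpp::as<vec>(mat_a[m]);
    bv[m] = Rcpp::as<vec>(mat_b[m]);
  }
  static const double crn[8][3] = {
    {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
    {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};
  HexScratch S;
  for (uword e = 0; e < ne; ++e) {
    mat Xe(8, 3), Ue(8, 3);
    for (int a = 0; a < 8; ++a) {
      uword n = elems(e, a);
      Xe.row(a) = X.row(n);
      for (int i = 0; i < 3; ++i) Ue(a, i) = u(3 * n + i);
    }
    vec alpha(9, fill::zeros);
    bool enh = enhanced != 0;
    if (enh || at_corners) hex_precompute(Xe, enh, S);
    if (enh) {
      uword m = elem_mat(e);
      if (!hex_solve_modes(S, Ue, av[m], bv[m], mat_kappa(m), alpha))
        alpha.zeros();
    }
    vec best(3);
    if (!at_corners) {
      grad_map(Xe, 0, 0, 0, dNdX);
      F = eye<mat>(3, 3) + Ue.t() * dNdX;
      if (enh)
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k)
            for (int n2 = 0; n2 < 3; ++n2)
              F(k, n2) += alpha(3 * i + k) * S.Gmc[i](n2);
      mat E = 0.5 * (F.t() * F - eye<mat>(3, 3));
      best = sort(eig_sym(E), "descend");
    } else {
      best(0) = -datum::inf; best(1) = 0; best(2) = datum::inf;
      mat dN;
      vec N;
      for (int c = 0; c < 8; ++c) {
        double dJ = grad_map(Xe, crn[c][0], crn[c][1], crn[c][2], dNdX);
        if (dJ <= 0.0) continue;
        F = eye<mat>(3, 3) + Ue.t() * dNdX;
        if (enh) {
          // mode gradients at the corner via the centroid Jacobian
          hex_dNdxi(0, 0, 0, dN, N);
          mat Jc = dN.t() * Xe;
          mat dxi_dX = inv(Jc.t());
          for (int i = 0; i < 3; ++i) {
            vec gi = -2.0 * crn[c][i] * dxi_dX.row(i).t() + S.Gmc[i];
            for (int k = 0; k < 3; ++k)
              for (int n2 = 0; n2 < 3; ++n2)
                F(k, n2) += alpha(3 * i + k) * gi(n2);
          }
        }
        mat E = 0.5 * (F.t() * F - eye<mat>(3, 3));
        vec ev = sort(eig_sym(E), "descend");
        if (ev(0) > best(0)) best(0) = ev(0);
        if (ev(2) < best(2)) best(2) = ev(2);
        best(1) = ev(1);
      }
      if (!std::isfinite(best(0))) best.zeros();
    }
    out.row(e) = best.t();
  }
  return out;
}

// Reference volume per element (for audits).
// [[Rcpp::export(name = ".elem_volumes_cpp")]]
arma::vec elem_volumes_cpp(const arma::mat& X, const arma::umat& elems) {
  uword ne = elems.n_rows;
  vec out(ne, fill::zeros);
  mat dNdX;
  for (uword e = 0; e < ne; ++e) {
    mat Xe(8, 3);
    for (int a = 0; a < 8; ++a) Xe.row(a) = X.row(elems(e, a));
    for (int g = 0; g < 8; ++g) {
      double xi = (g & 1) ? GP : -GP;
      double eta = (g & 2) ? GP : -GP;
      double zeta = (g & 4) ? GP : -GP;
      out(e) += grad_map(Xe, xi, eta, zeta, dNdX);
    }
  }
  return out;
}
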