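// Low-level finite-element kernels for the left-ventricle model:
//  - trilinear hexahedra, total-Lagrangian formulation
//  - selective reduced integration: isochoric + active stress at the 2x2x2
//    Gauss points, volumetric penalty at the element centre (locking control)
//  - follower (deformation-dependent) pressure load on bilinear quad faces
//  - cavity-volume functional V = (1/3) oint x . n dA with exact gradient
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

const double GPT = 0.5773502691896257; // 1/sqrt(3)

const double XI[8]   = {-1,  1,  1, -1, -1,  1,  1, -1};
const double ETA[8]  = {-1, -1,  1,  1, -1, -1,  1,  1};
const double ZETA[8] = {-1, -1, -1, -1,  1,  1,  1,  1};

// integration points 0..7: full 2x2x2 (w = 1); point 8: centre (w = 8)
inline void hex_gp(int gp, double &xi, double &eta, double &zeta, double &w) {
  if (gp == 8) { xi = 0.0; eta = 0.0; zeta = 0.0; w = 8.0; }
  else { xi = GPT * XI[gp]; eta = GPT * ETA[gp]; zeta = GPT * ZETA[gp]; w = 1.0; }
}

arma::mat hex_dNdxi(double xi, double eta, double zeta) {
  arma::mat d(8, 3);
  for (int a = 0; a < 8; ++a) {
    d(a, 0) = 0.125 * XI[a]   * (1.0 + ETA[a] * eta) * (1.0 + ZETA[a] * zeta);
    d(a, 1) = 0.125 * ETA[a]  * (1.0 + XI[a] * xi)   * (1.0 + ZETA[a] * zeta);
    d(a, 2) = 0.125 * ZETA[a] * (1.0 + XI[a] * xi)   * (1.0 + ETA[a] * eta);
  }
  return d;
}

struct FEModel {
  arma::mat nodes;              // N x 3 reference coordinates (mm)
  arma::umat elems;             // nE x 8, 0-based connectivity
  std::vector<arma::mat> dNdX;  // nE*9 entries, each 8 x 3
  std::vector<double> wdet;     // nE*9, gauss weight * detJ (reference)
};

inline double det3(const double F[9]) {
  return F[0] * (F[4] * F[8] - F[5] * F[7])
       - F[1] * (F[3] * F[8] - F[5] * F[6])
       + F[2] * (F[3] * F[7] - F[4] * F[6]);
}

inline void inv3(const double A[9], double Ai[9], double det) {
  const double id = 1.0 / det;
  Ai[0] = (A[4] * A[8] - A[5] * A[7]) * id;
  Ai[1] = (A[2] * A[7] - A[1] * A[8]) * id;
  Ai[2] = (A[1] * A[5] - A[2] * A[4]) * id;
  Ai[3] = (A[5] * A[6] - A[3] * A[8]) * id;
  Ai[4] = (A[0] * A[8] - A[2] * A[6]) * id;
  Ai[5] = (A[2] * A[3] - A[0] * A[5]) * id;
  Ai[6] = (A[3] * A[7] - A[4] * A[6]) * id;
  Ai[7] = (A[1] * A[6] - A[0] * A[7]) * id;
  Ai[8] = (A[0] * A[4] - A[1] * A[3]) * id;
}

// Internal-force contribution of one element; R (8x3, column-major as
// R[a + 8*i]) is accumulated. ue is 8x3 column-major (ue[a + 8*i]).
// mat = {a1,a2,a3,b1,b2,kappa}; s_a >= 0 is the prescribed fibre shortening.
inline void elem_residual(const FEModel &M, int e, const double *ue,
                          const double *mat, const double *f0,
                          bool act, double phi, double E0, double s_a,
                          const double *lam_ref,
                          double *R,
                          double *lam_out, double *sig_out, double *J_out) {
  const double a1 = mat[0], a2 = mat[1], a3 = mat[2],
               b1 = mat[3], b2 = mat[4], kap = mat[5];
  double sig_tot = 0.0, sig_act = 0.0, Jbar = 1.0;
  for (int gp = 0; gp < 9; ++gp) {
    const double *B = M.dNdX[(size_t)e * 9 + gp].memptr(); // 8x3 col-major
    const double w = M.wdet[(size_t)e * 9 + gp];
    double F[9]; // row-major F[3*i+j] = dx_i/dX_j
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = (i == j) ? 1.0 : 0.0;
        const double *Bj = B + 8 * j, *ui = ue + 8 * i;
        for (int a = 0; a < 8; ++a) s += ui[a] * Bj[a];
        F[3 * i + j] = s;
      }
    const double J = det3(F);
    if (!(J > 0.0))
      stop("non-positive deformation Jacobian (J = %g) in element %d", J, e + 1);
    double C[9]; // C = F^T F (symmetric, row-major)
    for (int i = 0; i < 3; ++i)
      for (int j = i; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += F[3 * k + i] * F[3 * k + j];
        C[3 * i + j] = C[3 * j + i] = s;
      }
    double Ci[9];
    inv3(C, Ci, J * J);
    double S[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    if (gp == 8) {
      const double c = kap * (J - 1.0) * J;
      for (int k = 0; k < 9; ++k) S[k] = c * Ci[k];
      Jbar = J;
    } else {
      const double I1 = C[0] + C[4] + C[8];
      double Cf[3];
      for (int i = 0; i < 3; ++i)
        Cf[i] = C[3 * i] * f0[0] + C[3 * i + 1] * f0[1] + C[3 * i + 2] * f0[2];
      const double I4 = f0[0] * Cf[0] + f0[1] * Cf[1] + f0[2] * Cf[2];
      const double Jm23 = std::pow(J, -2.0 / 3.0);
      const double x1 = Jm23 * I1 - 3.0, x4 = Jm23 * I4 - 1.0;
      const double W1 = a1 + 2.0 * a2 * x1 + 3.0 * a3 * x1 * x1;
      const double W4 = 2.0 * b1 * x4 + 4.0 * b2 * x4 * x4 * x4;
      const double lamf = std::sqrt(I4);
      double c_ff = 2.0 * W4 * Jm23;           // coefficient of f0 (x) f0
      const double c_I = 2.0 * W1 * Jm23;      // coefficient of identity
      double c_Ci = -(2.0 * W1 * Jm23 * I1 + 2.0 * W4 * Jm23 * I4) / 3.0;
      if (lam_out) lam_out[gp] = lamf;
      if (act) {
        const double eps_e = std::log(lamf / lam_ref[gp]) + s_a;
        if (eps_e > 0.0) {
          const double ee = std::exp(eps_e);
          const double sa = E0 * ee * (ee - 1.0);
          // fibre pseudo-potential form (J ~ 1 by the volumetric penalty):
          // S_a = phi sa / I4 f0 (x) f0 keeps the tangent symmetric
          c_ff += phi * sa / I4;
          sig_act += phi * sa / 8.0;
        }
      }
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          S[3 * i + j] = c_ff * f0[i] * f0[j] + c_Ci * Ci[3 * i + j]
                       + ((i == j) ? c_I : 0.0);
      if (sig_out) {
        // total Cauchy (iso + active at this gp) along the deformed fibre:
        // fd ~ F f0, sigma_ff = fd . (F S F^T) fd / (J |fd|^2)
        double fd[3];
        for (int i = 0; i < 3; ++i)
          fd[i] = F[3 * i] * f0[0] + F[3 * i + 1] * f0[1] + F[3 * i + 2] * f0[2];
        const double fd2 = fd[0] * fd[0] + fd[1] * fd[1] + fd[2] * fd[2];
        // v = S F^T fd ; sigma_ff = (F^T fd) . S (F^T fd) / (J fd2)
        double Ftfd[3];
        for (int j = 0; j < 3; ++j)
          Ftfd[j] = F[j] * fd[0] + F[3 + j] * fd[1] + F[6 + j] * fd[2];
        double num = 0;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            num += Ftfd[i] * S[3 * i + j] * Ftfd[j];
        sig_tot += num / (J * fd2) / 8.0;
      }
    }
    // P = F S ; R[a,i] += w * B[a,K] * P[i,K]
    double P[9];
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) {
        double s = 0;
        for (int m = 0; m < 3; ++m) s += F[3 * i + m] * S[3 * m + k];
        P[3 * i + k] = s;
      }
    for (int i = 0; i < 3; ++i) {
      double *Ri = R + 8 * i;
      const double p0 = w * P[3 * i], p1 = w * P[3 * i + 1],
                   p2 = w * P[3 * i + 2];
      const double *B0 = B, *B1 = B + 8, *B2 = B + 16;
      for (int a = 0; a < 8; ++a) Ri[a] += p0 * B0[a] + p1 * B1[a] + p2 * B2[a];
    }
  }
  if (sig_out) {
    sig_out[0] = sig_tot + kap * (Jbar - 1.0); // add hydrostatic part
    sig_out[1] = sig_act;
  }
  if (J_out) *J_out = Jbar;
}

} // namespace

// [[Rcpp::export]]
SEXP fe_precompute(const arma::mat &nodes, const arma::imat &elems1) {
  const int nE = elems1.n_rows;
  XPtr<FEModel> ptr(new FEModel(), true);
  ptr->nodes = nodes;
  ptr->elems.set_size(nE, 8);
  for (int e = 0; e < nE; ++e)
    for (int a = 0; a < 8; ++a)
      ptr->elems(e, a) = (arma::uword)(elems1(e, a) - 1);
  ptr->dNdX.resize((size_t)nE * 9);
  ptr->wdet.resize((size_t)nE * 9);
  for (int e = 0; e < nE; ++e) {
    arma::mat Xe(8, 3);
    for (int a = 0; a < 8; ++a) Xe.row(a) = nodes.row(ptr->elems(e, a));
    for (int gp = 0; gp < 9; ++gp) {
      double xi, eta, zeta, w;
      hex_gp(gp, xi, eta, zeta, w);
      arma::mat dNdxi = hex_dNdxi(xi, eta, zeta);
      arma::mat33 Jm = Xe.t() * dNdxi;
      const double dJ = arma::det(Jm);
      if (!(dJ > 0.0))
        stop("degenerate element %d: non-positive reference Jacobian %g", e + 1, dJ);
      ptr->dNdX[(size_t)e * 9 + gp] = dNdxi * arma::inv(Jm);
      ptr->wdet[(size_t)e * 9 + gp] = w * dJ;
    }
  }
  return ptr;
}

// [[Rcpp::export]]
arma::vec fe_elem_volumes(SEXP model) {
  XPtr<FEModel> M(model);
  const int nE = M->elems.n_rows;
  arma::vec v(nE, arma::fill::zeros);
  for (int e = 0; e < nE; ++e)
    for (int gp = 0; gp < 8; ++gp) v(e) += M->wdet[(size_t)e * 9 + gp];
  return v;
}

// Assemble internal force (and optionally forward-difference tangent triplets).
// U: N x 3 nodal displacements. Global dof = 3*(node-1) + comp.
// [[Rcpp::export]]
List fe_assemble(SEXP model, const arma::mat &U, const arma::vec &matpars,
                 const arma::mat &fibres, double phi, double E0,
                 const arma::vec &s_a, const arma::ivec &active,
                 const arma::mat &lam_ref, bool tangent, double fd_step = 1e-6) {
  XPtr<FEModel> M(model);
  const int nE = M->elems.n_rows, N = M->nodes.n_rows;
  arma::vec fint(3 * N, arma::fill::zeros);
  arma::mat lam(nE, 8), sig(nE, 2);
  arma::vec Jbar(nE);
  IntegerVector Ki, Kj;
  NumericVector Kx;
  if (tangent) {
    Ki = IntegerVector((size_t)nE * 576);
    Kj = IntegerVector((size_t)nE * 576);
    Kx = NumericVector((size_t)nE * 576);
  }
  const double *mp = matpars.memptr();
  size_t tt = 0;
  for (int e = 0; e < nE; ++e) {
    double ue[24], f0[3], R0[24], Rp[24], Ke[576];
    for (int a = 0; a < 8; ++a) {
      const arma::uword n = M->elems(e, a);
      for (int i = 0; i < 3; ++i) ue[a + 8 * i] = U(n, i);
    }
    for (int i = 0; i < 3; ++i) f0[i] = fibres(e, i);
    const bool act = active(e) != 0;
    arma::rowvec lamref_e = lam_ref.row(e);
    double lrow[8], srow[2], jb;
    std::fill(R0, R0 + 24, 0.0);
    elem_residual(*M, e, ue, mp, f0, act, phi, E0, s_a(e),
                  lamref_e.memptr(), R0, lrow, srow, &jb);
    for (int gp = 0; gp < 8; ++gp) lam(e, gp) = lrow[gp];
    sig(e, 0) = srow[0]; sig(e, 1) = srow[1]; Jbar(e) = jb;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        fint(3 * M->elems(e, a) + i) += R0[a + 8 * i];
    if (tangent) {
      const double h = fd_step;
      for (int d = 0; d < 24; ++d) {
        ue[d] += h;
        std::fill(Rp, Rp + 24, 0.0);
        elem_residual(*M, e, ue, mp, f0, act, phi, E0, s_a(e),
                      lamref_e.memptr(), Rp, nullptr, nullptr, nullptr);
        ue[d] -= h;
        for (int r = 0; r < 24; ++r) Ke[r + 24 * d] = (Rp[r] - R0[r]) / h;
      }
      for (int b = 0; b < 8; ++b)
        for (int j = 0; j < 3; ++j) {
          const int col = 3 * M->elems(e, b) + j + 1;
          const double *Kcol = Ke + 24 * (b + 8 * j);
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i) {
              Ki[tt] = 3 * M->elems(e, a) + i + 1;
              Kj[tt] = col;
              Kx[tt] = Kcol[a + 8 * i];
              ++tt;
            }
        }
    }
  }
  List out = List::create(_["f"] = fint, _["lam"] = lam, _["sig_ff"] = sig.col(0),
                          _["sig_act"] = sig.col(1), _["Jbar"] = Jbar);
  if (tangent) { out["Ki"] = Ki; out["Kj"] = Kj; out["Kx"] = Kx; }
  return out;
}

// Follower pressure on bilinear quad faces (node ordering gives the normal
// x_xi x x_eta pointing OUT of the fluid, i.e. into the wall). Returns the
// nodal force per unit pressure times p, plus optional load-stiffness triplets
// (d f / d x); the mechanics residual uses f_int - f and K_int - K.
// [[Rcpp::export]]
List face_pressure(const arma::mat &x, const arma::imat &faces1, double p,
                   bool tangent) {
  const int nF = faces1.n_rows, N = x.n_rows;
  const double g = GPT;
  const double QXI[4] = {-1, 1, 1, -1}, QETA[4] = {-1, -1, 1, 1};
  arma::vec f(3 * N, arma::fill::zeros);
  IntegerVector Ki, Kj;
  NumericVector Kx;
  if (tangent) {
    Ki = IntegerVector((size_t)nF * 576 / 4); // 12x12 blocks, 4 gps
    Kj = IntegerVector((size_t)nF * 576 / 4);
    Kx = NumericVector((size_t)nF * 576 / 4);
  }
  size_t tt = 0;
  for (int fc = 0; fc < nF; ++fc) {
    arma::uvec nd(4);
    for (int a = 0; a < 4; ++a) nd(a) = (arma::uword)(faces1(fc, a) - 1);
    arma::mat xe(4, 3);
    for (int a = 0; a < 4; ++a) xe.row(a) = x.row(nd(a));
    arma::mat Kf(12, 12, arma::fill::zeros);
    for (int q = 0; q < 4; ++q) {
      const double xi = g * QXI[q], eta = g * QETA[q];
      double Nq[4], Nxi[4], Neta[4];
      for (int a = 0; a < 4; ++a) {
        Nq[a]  = 0.25 * (1 + QXI[a] * xi) * (1 + QETA[a] * eta);
        Nxi[a] = 0.25 * QXI[a] * (1 + QETA[a] * eta);
        Neta[a]= 0.25 * QETA[a] * (1 + QXI[a] * xi);
      }
      arma::vec3 xxi(arma::fill::zeros), xeta(arma::fill::zeros);
      for (int a = 0; a < 4; ++a) {
        xxi  += Nxi[a]  * xe.row(a).t();
        xeta += Neta[a] * xe.row(a).t();
      }
      arma::vec3 cr = arma::cross(xxi, xeta);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) f(3 * nd(a) + i) += p * Nq[a] * cr(i);
      if (tangent) {
        arma::mat33 skxi = {{0, -xxi(2), xxi(1)}, {xxi(2), 0, -xxi(0)},
                            {-xxi(1), xxi(0), 0}};
        arma::mat33 sketa = {{0, -xeta(2), xeta(1)}, {xeta(2), 0, -xeta(0)},
                             {-xeta(1), xeta(0), 0}};
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            arma::mat33 blk = p * Nq[a] * (-Nxi[b] * sketa + Neta[b] * skxi);
            Kf.submat(3 * a, 3 * b, 3 * a + 2, 3 * b + 2) += blk;
          }
      }
    }
    if (tangent) {
      for (int b = 0; b < 4; ++b)
        for (int j = 0; j < 3; ++j)
          for (int a = 0; a < 4; ++a)
            for (int i = 0; i < 3; ++i) {
              Ki[tt] = 3 * (int)nd(a) + i + 1;
              Kj[tt] = 3 * (int)nd(b) + j + 1;
              Kx[tt] = Kf(3 * a + i, 3 * b + j);
              ++tt;
            }
    }
  }
  List out = List::create(_["f"] = f);
  if (tangent) { out["Ki"] = Ki; out["Kj"] = Kj; out["Kx"] = Kx; }
  return out;
}

// Accumulate triplet values into a fixed sparsity pattern: slot[k] is the
// 1-based nonzero index for triplet k (0 = dropped, e.g. constrained dof).
// [[Rcpp::export]]
NumericVector accum_pattern(const IntegerVector &slot,
                            const NumericVector &vals, int nnz) {
  NumericVector x(nnz);
  const int n = slot.size();
  for (int k = 0; k < n; ++k)
    if (slot[k] > 0) x[slot[k] - 1] += vals[k];
  return x;
}

// Volume enclosed by a closed faceted surface (divergence theorem) with its
// exact gradient with respect to nodal positions.
// [[Rcpp::export]]
List cavity_volume_cpp(const arma::mat &x, const arma::imat &faces1, bool grad) {
  const int nF = faces1.n_rows, N = x.n_rows;
  const double g = GPT;
  const double QXI[4] = {-1, 1, 1, -1}, QETA[4] = {-1, -1, 1, 1};
  double V = 0.0;
  arma::vec gv;
  if (grad) gv.zeros(3 * N);
  for (int fc = 0; fc < nF; ++fc) {
    arma::uvec nd(4);
    for (int a = 0; a < 4; ++a) nd(a) = (arma::uword)(faces1(fc, a) - 1);
    arma::mat xe(4, 3);
    for (int a = 0; a < 4; ++a) xe.row(a) = x.row(nd(a));
    for (int q = 0; q < 4; ++q) {
      const double xi = g * QXI[q], eta = g * QETA[q];
      double Nq[4], Nxi[4], Neta[4];
      for (int a = 0; a < 4; ++a) {
        Nq[a]  = 0.25 * (1 + QXI[a] * xi) * (1 + QETA[a] * eta);
        Nxi[a] = 0.25 * QXI[a] * (1 + QETA[a] * eta);
        Neta[a]= 0.25 * QETA[a] * (1 + QXI[a] * xi);
      }
      arma::vec3 xp(arma::fill::zeros), xxi(arma::fill::zeros),
                 xeta(arma::fill::zeros);
      for (int a = 0; a < 4; ++a) {
        xp   += Nq[a]   * xe.row(a).t();
        xxi  += Nxi[a]  * xe.row(a).t();
        xeta += Neta[a] * xe.row(a).t();
      }
      arma::vec3 cr = arma::cross(xxi, xeta);
      V += arma::dot(xp, cr) / 3.0;
      if (grad) {
        arma::vec3 c1 = arma::cross(xeta, xp), c2 = arma::cross(xp, xxi);
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i)
            gv(3 * nd(a) + i) +=
              (Nq[a] * cr(i) + Nxi[a] * c1(i) + Neta[a] * c2(i)) / 3.0;
      }
    }
  }
  List out = List::create(_["V"] = V);
  if (grad) out["g"] = gv;
  return out;
}
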