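// Element kernels for displacement-driven incompressible Yeoh hyperelasticity.
//
// Total-Lagrangian formulation with the energy (per element e)
//   Pi_e = int_e Psi(I1(F)) dV0 + V_e [ p_e (Jbar_e - 1) - p_e^2 / (2 kappa) ]
// where Jbar_e is the element-mean volume ratio and p_e a per-element pressure
// unknown (Q1/P0 mixed, perturbed Lagrangian).  Penalty mode eliminates p_e as
// p_e = kappa (Jbar_e - 1), adding the rank-one kappa term to the tangent.
//
// First Piola stress: P = 2 Psi'(I1) F + p_eff J F^{-T}.
// Units: mm, kPa (forces mN).  The 2*pi factor of axisymmetric volumes is
// dropped consistently from every term.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double GP = 0.5773502691896257645091488; // 1/sqrt(3)

// --- shape functions -------------------------------------------------------

// quad4 on [-1,1]^2, nodes (-,-),(+,-),(+,+),(-,+)
static void shape_quad4(double xi, double eta, vec &N, mat &dN) {
  const double sx[4] = {-1, 1, 1, -1}, sy[4] = {-1, -1, 1, 1};
  N.set_size(4); dN.set_size(4, 2);
  for (int a = 0; a < 4; ++a) {
    N(a) = 0.25 * (1 + sx[a] * xi) * (1 + sy[a] * eta);
    dN(a, 0) = 0.25 * sx[a] * (1 + sy[a] * eta);
    dN(a, 1) = 0.25 * sy[a] * (1 + sx[a] * xi);
  }
}

// hex8 on [-1,1]^3, bottom face CCW then top face
static void shape_hex8(double xi, double eta, double ze, vec &N, mat &dN) {
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  N.set_size(8); dN.set_size(8, 3);
  for (int a = 0; a < 8; ++a) {
    N(a) = 0.125 * (1 + sx[a] * xi) * (1 + sy[a] * eta) * (1 + sz[a] * ze);
    dN(a, 0) = 0.125 * sx[a] * (1 + sy[a] * eta) * (1 + sz[a] * ze);
    dN(a, 1) = 0.125 * sy[a] * (1 + sx[a] * xi) * (1 + sz[a] * ze);
    dN(a, 2) = 0.125 * sz[a] * (1 + sx[a] * xi) * (1 + sy[a] * eta);
  }
}

struct QPData {
  mat gradN;   // nen x dim, derivatives wrt reference coords
  vec N;       // nen
  double w;    // quadrature weight x detJ0 (x R for axisymmetric)
  double R;    // reference radius (axisymmetric only)
  mat F;       // 3 x 3 deformation gradient
  double J, I1;
};

// Evaluate kinematics at all quadrature points of one element.
// kind: 0 = axisymmetric quad4 (coords R,Z), 1 = hex8 (x,y,z).
static bool element_qp(int kind, const mat &X, const mat &ue,
                       std::vector<QPData> &qps) {
  int nqp = (kind == 0) ? 4 : 8;
  qps.resize(nqp);
  vec N; mat dN;
  for (int q = 0; q < nqp; ++q) {
    double xi = (q % 2 == 0) ? -GP : GP;
    double eta = ((q / 2) % 2 == 0) ? -GP : GP;
    if (kind == 0) shape_quad4(xi, eta, N, dN);
    else {
      double ze = (q / 4 == 0) ? -GP : GP;
      shape_hex8(xi, eta, ze, N, dN);
    }
    mat J0 = X.t() * dN;           // dim x dim
    double detJ0 = arma::det(J0);
    if (detJ0 <= 0) return false;
    QPData &qp = qps[q];
    qp.N = N;
    qp.gradN = dN * arma::inv(J0);
    qp.w = detJ0;                  // unit Gauss weights for 2-point rule
    mat F(3, 3, arma::fill::eye);
    mat H = ue.t() * qp.gradN;     // dim x dim displacement gradient
    if (kind == 0) {
      double R = arma::dot(N, X.col(0));
      qp.R = R;
      qp.w *= R;
      F(0, 0) += H(0, 0); F(0, 1) = H(0, 1);
      F(1, 0) = H(1, 0);  F(1, 1) += H(1, 1);
      F(2, 2) = 1.0 + arma::dot(N, ue.col(0)) / R;
    } else {
      qp.R = 0;
      F.submat(0, 0, 2, 2) += H;
    }
    qp.F = F;
    qp.J = arma::det(F);
    if (qp.J <= 0) return false;
    qp.I1 = arma::accu(F % F);
    qps[q] = qp;
  }
  return true;
}

// dPsi/dI1 and d2Psi/dI1^2 for Psi = c1 x + c2 x^2 + c3 x^3, x = I1 - 3
static inline void yeoh_dpsi(double I1, double c1, double c2, double c3,
                             double &p1, double &p2) {
  double x = I1 - 3.0;
  p1 = c1 + 2.0 * c2 * x + 3.0 * c3 * x * x;
  p2 = 2.0 * c2 + 6.0 * c3 * x;
}

// Assemble global residual, stiffness triplets, constraint gradient and
// element volume data for the current state (u, pbar).
// mode: 0 = mixed (p_eff = pbar, G returned for the saddle system),
//       1 = penalty/augmented (p_eff = pbar + kappa (Jbar-1), rank-one added).
// stab: dimensionless pointwise volumetric stabilization.  Adds the stress
//       stab * 2 Psi'(I1) * (J-1) J F^{-T}, proportional to the local tangent
//       shear stiffness; identically zero wherever J = 1 pointwise
//       (homogeneous states, the mid-length sampling region), it prevents
//       within-element volume collapse at clamp corners at extreme stretch
//       without introducing a foreign stress scale.
// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(const arma::mat &nodes, const arma::imat &elems,
                  const arma::mat &u, const arma::vec &pbar,
                  double kappa, double c1, double c2, double c3,
                  int kind, int mode, double stab) {
  const int dim = (kind == 0) ? 2 : 3;
  const int nen = (kind == 0) ? 4 : 8;
  const int ndl = nen * dim;
  const int nel = elems.n_rows;
  const int ndof = nodes.n_rows * dim;

  vec fglob(ndof, arma::fill::zeros);
  vec Jbar(nel), Ve(nel);
  double maxJdev = 0.0;

  arma::uvec Ki(static_cast<size_t>(nel) * ndl * ndl);
  arma::uvec Kj(Ki.n_elem);
  vec Kv(Ki.n_elem);
  arma::uvec Gi(static_cast<size_t>(nel) * ndl);
  arma::uvec Gj(Gi.n_elem);
  vec Gv(Gi.n_elem);
  size_t kt = 0, gt = 0;

  std::vector<QPData> qps;
  mat X(nen, dim), ue(nen, dim);
  arma::uvec gdof(ndl);
  mat Kloc(ndl, ndl);
  vec floc(ndl), gloc(ndl);
  std::vector<mat> G(ndl), A(ndl);

  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < nen; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < dim; ++i) {
        X(a, i) = nodes(n, i);
        ue(a, i) = u(n, i);
        gdof(a * dim + i) = static_cast<arma::uword>(n) * dim + i;
      }
    }
    if (!element_qp(kind, X, ue, qps))
      stop("element %d inverted (non-positive Jacobian)", e + 1);

    double vol0 = 0, vol = 0;
    for (auto &qp : qps) { vol0 += qp.w; vol += qp.J * qp.w; }
    Ve(e) = vol0;
    Jbar(e) = vol / vol0;
    double peff = pbar(e) + (mode == 1 ? kappa * (Jbar(e) - 1.0) : 0.0);

    Kloc.zeros(); floc.zeros(); gloc.zeros();
    for (auto &qp : qps) {
      maxJdev = std::max(maxJdev, std::fabs(qp.J - 1.0));
      double p1, p2;
      yeoh_dpsi(qp.I1, c1, c2, c3, p1, p2);
      mat Fi = arma::inv(qp.F);
      double ks = stab * 2.0 * p1;                 // local stabilization modulus
      double peffq = peff + ks * (qp.J - 1.0);     // + pointwise stabilization
      double kvol = ks * qp.J * qp.J;              // symmetric tangent extra
      double cx = stab * 4.0 * p2 * (qp.J - 1.0) * qp.J;  // dks/dF coupling
      mat P = 2.0 * p1 * qp.F + peffq * qp.J * Fi.t();

      if (kind == 1) {
        // structured fast path: dof m = (a,i) has dF = e_i (x) gradN_a
        mat Hm = qp.gradN * Fi;        // (a,i) -> F^{-T}:G_m
        mat Cm = qp.gradN * qp.F.t();  // (a,i) -> F:G_m
        mat Fm = qp.gradN * P.t();     // (a,i) -> P:G_m
        mat D = qp.gradN * qp.gradN.t();
        for (int a = 0; a < nen; ++a)
          for (int i = 0; i < dim; ++i) {
            int m = a * dim + i;
            floc(m) += qp.w * Fm(a, i);
            gloc(m) += qp.w * qp.J * Hm(a, i);
            for (int b = 0; b < nen; ++b)
              for (int j = 0; j < dim; ++j) {
                double k = 4.0 * p2 * Cm(a, i) * Cm(b, j)
                  + peffq * qp.J * (Hm(a, i) * Hm(b, j) - Hm(a, j) * Hm(b, i))
                  + kvol * Hm(a, i) * Hm(b, j)
                  + cx * Hm(a, i) * Cm(b, j);
                if (i == j) k += 2.0 * p1 * D(a, b);
                Kloc(m, b * dim + j) += qp.w * k;
              }
          }
      } else {
        // axisymmetric: explicit 3x3 dF matrices (hoop term couples u_r)
        for (int a = 0; a < nen; ++a) {
          mat Gr(3, 3, arma::fill::zeros), Gz(3, 3, arma::fill::zeros);
          Gr(0, 0) = qp.gradN(a, 0); Gr(0, 1) = qp.gradN(a, 1);
          Gr(2, 2) = qp.N(a) / qp.R;
          Gz(1, 0) = qp.gradN(a, 0); Gz(1, 1) = qp.gradN(a, 1);
          G[a * 2] = Gr; G[a * 2 + 1] = Gz;
        }
        for (int m = 0; m < ndl; ++m) A[m] = Fi * G[m];
        for (int m = 0; m < ndl; ++m) {
          double trAm = arma::trace(A[m]);
          floc(m) += qp.w * arma::accu(P % G[m]);
          gloc(m) += qp.w * qp.J * trAm;
          for (int n = 0; n < ndl; ++n) {
            double k = 2.0 * p1 * arma::accu(G[m] % G[n])
              + 4.0 * p2 * arma::accu(qp.F % G[m]) * arma::accu(qp.F % G[n])
              + peffq * qp.J * (trAm * arma::trace(A[n])
                                - arma::trace(A[m] * A[n]))
              + kvol * trAm * arma::trace(A[n])
              + cx * trAm * arma::accu(qp.F % G[n]);
            Kloc(m, n) += qp.w * k;
          }
        }
      }
    }
    if (mode == 1 && kappa > 0)
      Kloc += (kappa / Ve(e)) * (gloc * gloc.t());

    for (int m = 0; m < ndl; ++m) {
      fglob(gdof(m)) += floc(m);
      Gi(gt) = gdof(m) + 1; Gj(gt) = e + 1; Gv(gt) = gloc(m); ++gt;
      for (int n = 0; n < ndl; ++n) {
        Ki(kt) = gdof(m) + 1; Kj(kt) = gdof(n) + 1; Kv(kt) = Kloc(m, n); ++kt;
      }
    }
  }

  return List::create(_["f"] = fglob,
                      _["Ki"] = IntegerVector(Ki.begin(), Ki.end()),
                      _["Kj"] = IntegerVector(Kj.begin(), Kj.end()),
                      _["Kv"] = NumericVector(Kv.begin(), Kv.end()),
                      _["Gi"] = IntegerVector(Gi.begin(), Gi.end()),
                      _["Gj"] = IntegerVector(Gj.begin(), Gj.end()),
                      _["Gv"] = NumericVector(Gv.begin(), Gv.end()),
                      _["Jbar"] = Jbar, _["Ve"] = Ve,
                      _["maxJdev"] = maxJdev);
}

// Per-quadrature-point fields for post-processing: reference coordinates,
// volume weight, J, I1, Cauchy stress components and the axial stretch
// (deformation-gradient axial diagonal entry) of the current state.
// Columns: elem, x1, x2, x3, w, J, I1, s11, s22, s33, s12, s13, s23, Fzz
// (axisymmetric: x1 = R, x2 = Z, s11 = s_rr, s22 = s_zz, s33 = s_tt,
//  s12 = s_rz; hex: axes x,y,z with z axial).
// [[Rcpp::export(name = ".fem_fields")]]
arma::mat fem_fields(const arma::mat &nodes, const arma::imat &elems,
                     const arma::mat &u, const arma::vec &pbar,
                     double kappa, double c1, double c2, double c3,
                     int kind, int mode, double stab) {
  const int dim = (kind == 0) ? 2 : 3;
  const int nen = (kind == 0) ? 4 : 8;
  const int nqp = (kind == 0) ? 4 : 8;
  const int nel = elems.n_rows;

  arma::mat out(static_cast<size_t>(nel) * nqp, 14);
  std::vector<QPData> qps;
  mat X(nen, dim), ue(nen, dim);
  size_t row = 0;

  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < nen; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < dim; ++i) { X(a, i) = nodes(n, i); ue(a, i) = u(n, i); }
    }
    if (!element_qp(kind, X, ue, qps))
      stop("element %d inverted (non-positive Jacobian)", e + 1);
    double vol0 = 0, vol = 0;
    for (auto &qp : qps) { vol0 += qp.w; vol += qp.J * qp.w; }
    double Jb = vol / vol0;
    double peff = pbar(e) + (mode == 1 ? kappa * (Jb - 1.0) : 0.0);
    for (auto &qp : qps) {
      double p1, p2;
      yeoh_dpsi(qp.I1, c1, c2, c3, p1, p2);
      mat B = qp.F * qp.F.t();
      mat sig = (2.0 * p1 / qp.J) * B;
      sig.diag() += peff + stab * 2.0 * p1 * (qp.J - 1.0);
      out(row, 0) = e + 1;
      for (int i = 0; i < 3; ++i)
        out(row, 1 + i) = (i < dim) ? arma::dot(qp.N, X.col(i)) : 0.0;
      out(row, 4) = qp.w;
      out(row, 5) = qp.J;
      out(row, 6) = qp.I1;
      out(row, 7) = sig(0, 0); out(row, 8) = sig(1, 1); out(row, 9) = sig(2, 2);
      out(row, 10) = sig(0, 1); out(row, 11) = sig(0, 2); out(row, 12) = sig(1, 2);
      out(row, 13) = (kind == 0) ? qp.F(1, 1) : qp.F(2, 2);
      ++row;
    }
  }
  return out;
}

// Minimum reference-configuration Jacobian determinant over all quadrature
// points (mesh quality / orientation check).
// [[Rcpp::export(name = ".fem_min_detj")]]
double fem_min_detj(const arma::mat &nodes, const arma::imat &elems, int kind) {
  const int dim = (kind == 0) ? 2 : 3;
  const int nen = (kind == 0) ? 4 : 8;
  const int nqp = (kind == 0) ? 4 : 8;
  vec N; mat dN;
  double mind = arma::datum::inf;
  mat X(nen, dim);
  for (arma::uword e = 0; e < elems.n_rows; ++e) {
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) X(a, i) = nodes(elems(e, a) - 1, i);
    for (int q = 0; q < nqp; ++q) {
      double xi = (q % 2 == 0) ? -GP : GP;
      double eta = ((q / 2) % 2 == 0) ? -GP : GP;
      if (kind == 0) shape_quad4(xi, eta, N, dN);
      else shape_hex8(xi, eta, (q / 4 == 0) ? -GP : GP, N, dN);
      mind = std::min(mind, arma::det(mat(X.t() * dN)));
    }
  }
  return mind;
}
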