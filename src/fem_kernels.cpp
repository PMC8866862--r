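// Low-level TET10 element kernels: stiffness integration, global triplet
// assembly and integration-point strain/stress recovery. Straight-edged
// quadratic tetrahedra only (constant Jacobian), 4-point Gauss rule.
// Voigt order throughout: 11, 22, 33, 12, 13, 23 with engineering shear.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// 4-point rule, exact to polynomial degree 2 (the B'CB integrand of a
// straight TET10 is degree 2). Barycentric coordinates.
const double GA = 0.5854101966249685;
const double GB = 0.1381966011250105;
const double gauss4[4][4] = {
  {GA, GB, GB, GB}, {GB, GA, GB, GB}, {GB, GB, GA, GB}, {GB, GB, GB, GA}};

// dN/dlambda for the 10 shape functions at barycentric lam[4].
// Vertices: N_i = lam_i(2 lam_i - 1). Edges (1,2),(2,3),(3,1),(1,4),(2,4),(3,4).
void shape_grad_lambda(const double lam[4], double dNdL[10][4]) {
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 4; ++j) dNdL[i][j] = 0.0;
  for (int i = 0; i < 4; ++i) dNdL[i][i] = 4.0 * lam[i] - 1.0;
  const int ed[6][2] = {{0,1},{1,2},{2,0},{0,3},{1,3},{2,3}};
  for (int e = 0; e < 6; ++e) {
    int a = ed[e][0], b = ed[e][1];
    dNdL[4 + e][a] = 4.0 * lam[b];
    dNdL[4 + e][b] = 4.0 * lam[a];
  }
}

// Cartesian shape gradients at one Gauss point given grad(lambda) (4x3).
void shape_grad_xyz(const double lam[4], const arma::mat& gradL,
                    arma::mat& dN) {
  double dNdL[10][4];
  shape_grad_lambda(lam, dNdL);
  for (int i = 0; i < 10; ++i)
    for (int d = 0; d < 3; ++d) {
      double s = 0.0;
      for (int j = 0; j < 4; ++j) s += dNdL[i][j] * gradL(j, d);
      dN(i, d) = s;
    }
}

// grad(lambda) (4x3) and detJ from the 4 vertex coordinates (rows of X).
double lambda_gradients(const arma::mat& X, arma::mat& gradL) {
  arma::mat J(3, 3);
  for (int c = 0; c < 3; ++c) {
    J(0, c) = X(0, c) - X(3, c);
    J(1, c) = X(1, c) - X(3, c);
    J(2, c) = X(2, c) - X(3, c);
  }
  // J rows are d x / d lambda_k (k = 1..3, offsets from vertex 4); the map
  // (lambda_1..3) -> x reverses orientation for a positively oriented tet,
  // so 6V = -det(J).
  double detJ = -arma::det(J);
  arma::mat Jinv = arma::inv(J);
  // lambda_k (k=1..3) gradients are rows of Jinv^T; lambda_4 = 1 - sum.
  for (int k = 0; k < 3; ++k)
    for (int d = 0; d < 3; ++d) gradL(k, d) = Jinv(d, k);
  for (int d = 0; d < 3; ++d)
    gradL(3, d) = -(gradL(0, d) + gradL(1, d) + gradL(2, d));
  return detJ;
}

void fill_B(const arma::mat& dN, arma::mat& B) {
  B.zeros();
  for (int i = 0; i < 10; ++i) {
    double dx = dN(i, 0), dy = dN(i, 1), dz = dN(i, 2);
    int c = 3 * i;
    B(0, c) = dx;
    B(1, c + 1) = dy;
    B(2, c + 2) = dz;
    B(3, c) = dy; B(3, c + 1) = dx;       // gamma_12
    B(4, c) = dz; B(4, c + 2) = dx;       // gamma_13
    B(5, c + 1) = dz; B(5, c + 2) = dy;   // gamma_23
  }
}

// Voigt index pairs for the tensor<->Voigt map (0-based).
const int VI[6] = {0, 1, 2, 0, 0, 1};
const int VJ[6] = {0, 1, 2, 1, 2, 2};

} // namespace

// Element stiffness (30x30) of one straight TET10, 4-point Gauss.
// coords: 10x3 node coordinates, C: 6x6 stiffness in Voigt order.
// [[Rcpp::export]]
arma::mat fk_elem_stiffness(const arma::mat& coords, const arma::mat& C) {
  arma::mat X = coords.rows(0, 3);
  arma::mat gradL(4, 3);
  double detJ = lambda_gradients(X, gradL);
  if (detJ <= 0) stop("non-positive Jacobian in element");
  arma::mat K(30, 30, arma::fill::zeros);
  arma::mat dN(10, 3), B(6, 30);
  for (int g = 0; g < 4; ++g) {
    shape_grad_xyz(gauss4[g], gradL, dN);
    fill_B(dN, B);
    K += (detJ / 24.0) * (B.t() * C * B);
  }
  return K;
}

// Global assembly: lower-triangle COO triplets of the symmetric stiffness.
// conn is 1-based (ne x 10); Cm holds per-element 6x6 stiffness rows
// (ne x 36, row-major by Voigt row). Returns i, j (1-based DOF), x,
// element volumes and min detJ.
// [[Rcpp::export]]
List fk_assemble_triplets(const arma::mat& coords, const IntegerMatrix& conn,
                          const arma::mat& Cm) {
  const int ne = conn.nrow();
  const R_xlen_t per = 465; // 30*31/2
  IntegerVector iv(per * (R_xlen_t)ne), jv(per * (R_xlen_t)ne);
  NumericVector xv(per * (R_xlen_t)ne);
  NumericVector vol(ne);
  double mindet = R_PosInf;
  arma::mat X(4, 3), gradL(4, 3), dN(10, 3), B(6, 30), C(6, 6), K(30, 30);
  std::vector<int> gdof(30);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) X(a, d) = coords(conn(e, a) - 1, d);
    double detJ = lambda_gradients(X, gradL);
    if (detJ <= 0) stop("non-positive Jacobian in element %d", e + 1);
    if (detJ < mindet) mindet = detJ;
    vol[e] = detJ / 6.0;
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 6; ++c) C(r, c) = Cm(e, 6 * r + c);
    K.zeros();
    for (int g = 0; g < 4; ++g) {
      shape_grad_xyz(gauss4[g], gradL, dN);
      fill_B(dN, B);
      K += (detJ / 24.0) * (B.t() * C * B);
    }
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      gdof[3 * a] = 3 * n + 1; gdof[3 * a + 1] = 3 * n + 2; gdof[3 * a + 2] = 3 * n + 3;
    }
    R_xlen_t base = per * (R_xlen_t)e;
    R_xlen_t k = 0;
    for (int a = 0; a < 30; ++a)
      for (int b = 0; b <= a; ++b) {
        int gi = gdof[a], gj = gdof[b];
        double val = K(a, b);
        if (gi >= gj) { iv[base + k] = gi; jv[base + k] = gj; }
        else          { iv[base + k] = gj; jv[base + k] = gi; }
        xv[base + k] = val;
        ++k;
      }
  }
  return List::create(_["i"] = iv, _["j"] = jv, _["x"] = xv,
                      _["volume"] = vol, _["min_detJ"] = mindet);
}

// Strain/stress recovery at the 4 Gauss points of every element.
// u: full nodal displacement vector (3*nnodes). Returns per-point
// strain (6), stress (6), integration weight (volume share), element id,
// and Gauss-point coordinates.
// [[Rcpp::export]]
List fk_recover(const arma::mat& coords, const IntegerMatrix& conn,
                const arma::mat& Cm, const arma::vec& u) {
  const int ne = conn.nrow();
  arma::mat strain(4 * (size_t)ne, 6), stress(4 * (size_t)ne, 6);
  arma::vec wt(4 * (size_t)ne);
  IntegerVector eid(4 * (R_xlen_t)ne);
  arma::mat pts(4 * (size_t)ne, 3);
  arma::mat X(4, 3), gradL(4, 3), dN(10, 3), B(6, 30), C(6, 6);
  arma::vec ue(30), eps(6), sig(6);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) X(a, d) = coords(conn(e, a) - 1, d);
    double detJ = lambda_gradients(X, gradL);
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 6; ++c) C(r, c) = Cm(e, 6 * r + c);
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      ue[3 * a] = u[3 * n]; ue[3 * a + 1] = u[3 * n + 1]; ue[3 * a + 2] = u[3 * n + 2];
    }
    for (int g = 0; g < 4; ++g) {
      shape_grad_xyz(gauss4[g], gradL, dN);
      fill_B(dN, B);
      eps = B * ue;
      sig = C * eps;
      size_t row = 4 * (size_t)e + g;
      for (int k = 0; k < 6; ++k) { strain(row, k) = eps[k]; stress(row, k) = sig[k]; }
      wt[row] = detJ / 24.0;
      eid[row] = e + 1;
      for (int d = 0; d < 3; ++d) {
        double p = 0.0;
        for (int a = 0; a < 4; ++a) p += gauss4[g][a] * X(a, d);
        pts(row, d) = p;
      }
    }
  }
  return List::create(_["strain"] = strain, _["stress"] = stress,
                      _["weight"] = wt, _["element"] = eid, _["point"] = pts);
}

// Rotate a Voigt stiffness from a local frame to global axes by full
// fourth-order tensor rotation. frame rows are the local basis vectors
// e1,e2,e3 expressed in global coordinates, so v_local = Q v_global and
// C_glob[pqrs] = Q[ip] Q[jq] Q[kr] Q[ls] C_loc[ijkl].
// [[Rcpp::export]]
arma::mat fk_rotate_stiffness(const arma::mat& C, const arma::mat& Q) {
  double Ct[3][3][3][3];
  for (int I = 0; I < 6; ++I)
    for (int J = 0; J < 6; ++J) {
      int i = VI[I], j = VJ[I], k = VI[J], l = VJ[J];
      double v = C(I, J);
      Ct[i][j][k][l] = v; Ct[j][i][k][l] = v;
      Ct[i][j][l][k] = v; Ct[j][i][l][k] = v;
    }
  double Cg[3][3][3][3];
  for (int p = 0; p < 3; ++p)
    for (int q = 0; q < 3; ++q)
      for (int r = 0; r < 3; ++r)
        for (int s = 0; s < 3; ++s) {
          double acc = 0.0;
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              for (int k = 0; k < 3; ++k)
                for (int l = 0; l < 3; ++l)
                  acc += Q(i, p) * Q(j, q) * Q(k, r) * Q(l, s) * Ct[i][j][k][l];
          Cg[p][q][r][s] = acc;
        }
  arma::mat out(6, 6);
  for (int I = 0; I < 6; ++I)
    for (int J = 0; J < 6; ++J) out(I, J) = Cg[VI[I]][VJ[I]][VI[J]][VJ[J]];
  return out;
}

// Batch rotation: one base stiffness, per-element frames (ne x 9, rows of
// Q stored e1x,e1y,e1z,e2x,...). Returns ne x 36 row-major stiffness rows.
// [[Rcpp::export]]
arma::mat fk_rotate_batch(const arma::mat& C, const arma::mat& frames) {
  const int ne = frames.n_rows;
  arma::mat out(ne, 36);
  arma::mat Q(3, 3);
  for (int e = 0; e < ne; ++e) {
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) Q(r, c) = frames(e, 3 * r + c);
    arma::mat Cg = fk_rotate_stiffness(C, Q);
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 6; ++c) out(e, 6 * r + c) = Cg(r, c);
  }
  return out;
}

// TET10 shape functions at barycentric coordinates lam (length 4).
// [[Rcpp::export]]
arma::vec fk_shape_functions(const arma::vec& lam) {
  arma::vec N(10);
  for (int i = 0; i < 4; ++i) N[i] = lam[i] * (2.0 * lam[i] - 1.0);
  const int ed[6][2] = {{0,1},{1,2},{2,0},{0,3},{1,3},{2,3}};
  for (int e = 0; e < 6; ++e) N[4 + e] = 4.0 * lam[ed[e][0]] * lam[ed[e][1]];
  return N;
}
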