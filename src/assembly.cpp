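// Finite-element kernels: small-strain and finite-strain (Yeoh) assembly on
// quadratic simplices (6-node triangles, plane strain; 10-node tetrahedra),
// consistent luminal pressure loads, element measures, and a kd-tree nearest
// neighbour used by the interface-matching objective.
//
// Conventions: node coordinates are an n x d matrix (d = 2 or 3, mm),
// connectivity is 1-based, element mid-side ordering follows VTK
// (quadratic triangle edges 1-2, 2-3, 3-1; quadratic tet edges 1-2, 2-3,
// 1-3, 1-4, 2-4, 3-4). Moduli in kPa, pressures in kPa.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int MAXNEN = 10;

// ---------------------------------------------------------------- shapes ----

// 6-node triangle, area coordinates L1 = 1-xi-eta, L2 = xi, L3 = eta
static void shp_tri6(double xi, double eta, double *N, double dN[][3]) {
  double L1 = 1.0 - xi - eta, L2 = xi, L3 = eta;
  double d1[2] = {-1.0, -1.0}, d2[2] = {1.0, 0.0}, d3[2] = {0.0, 1.0};
  N[0] = L1 * (2.0 * L1 - 1.0);
  N[1] = L2 * (2.0 * L2 - 1.0);
  N[2] = L3 * (2.0 * L3 - 1.0);
  N[3] = 4.0 * L1 * L2;
  N[4] = 4.0 * L2 * L3;
  N[5] = 4.0 * L3 * L1;
  for (int k = 0; k < 2; ++k) {
    dN[0][k] = (4.0 * L1 - 1.0) * d1[k];
    dN[1][k] = (4.0 * L2 - 1.0) * d2[k];
    dN[2][k] = (4.0 * L3 - 1.0) * d3[k];
    dN[3][k] = 4.0 * (L1 * d2[k] + L2 * d1[k]);
    dN[4][k] = 4.0 * (L2 * d3[k] + L3 * d2[k]);
    dN[5][k] = 4.0 * (L3 * d1[k] + L1 * d3[k]);
  }
}

// 10-node tetrahedron, L1 = 1-xi-eta-zeta, L2 = xi, L3 = eta, L4 = zeta
static void shp_tet10(double xi, double eta, double zeta, double *N,
                      double dN[][3]) {
  double L1 = 1.0 - xi - eta - zeta, L2 = xi, L3 = eta, L4 = zeta;
  double d1[3] = {-1.0, -1.0, -1.0}, d2[3] = {1.0, 0.0, 0.0},
         d3[3] = {0.0, 1.0, 0.0}, d4[3] = {0.0, 0.0, 1.0};
  N[0] = L1 * (2.0 * L1 - 1.0);
  N[1] = L2 * (2.0 * L2 - 1.0);
  N[2] = L3 * (2.0 * L3 - 1.0);
  N[3] = L4 * (2.0 * L4 - 1.0);
  N[4] = 4.0 * L1 * L2;
  N[5] = 4.0 * L2 * L3;
  N[6] = 4.0 * L1 * L3;
  N[7] = 4.0 * L1 * L4;
  N[8] = 4.0 * L2 * L4;
  N[9] = 4.0 * L3 * L4;
  for (int k = 0; k < 3; ++k) {
    dN[0][k] = (4.0 * L1 - 1.0) * d1[k];
    dN[1][k] = (4.0 * L2 - 1.0) * d2[k];
    dN[2][k] = (4.0 * L3 - 1.0) * d3[k];
    dN[3][k] = (4.0 * L4 - 1.0) * d4[k];
    dN[4][k] = 4.0 * (L1 * d2[k] + L2 * d1[k]);
    dN[5][k] = 4.0 * (L2 * d3[k] + L3 * d2[k]);
    dN[6][k] = 4.0 * (L1 * d3[k] + L3 * d1[k]);
    dN[7][k] = 4.0 * (L1 * d4[k] + L4 * d1[k]);
    dN[8][k] = 4.0 * (L2 * d4[k] + L4 * d2[k]);
    dN[9][k] = 4.0 * (L3 * d4[k] + L4 * d3[k]);
  }
}

// quadrature: degree-2 rules (3-point triangle, 4-point tetrahedron)
static int quad_rule(int dim, double pts[][3], double *w) {
  if (dim == 2) {
    double a = 1.0 / 6.0, b = 2.0 / 3.0;
    double p[3][2] = {{a, a}, {b, a}, {a, b}};
    for (int q = 0; q < 3; ++q) {
      pts[q][0] = p[q][0];
      pts[q][1] = p[q][1];
      pts[q][2] = 0.0;
      w[q] = 1.0 / 6.0;
    }
    return 3;
  }
  double a = 0.5854101966249685, b = 0.1381966011250105;
  double p[4][3] = {{b, b, b}, {a, b, b}, {b, a, b}, {b, b, a}};
  for (int q = 0; q < 4; ++q) {
    for (int k = 0; k < 3; ++k) pts[q][k] = p[q][k];
    w[q] = 1.0 / 24.0;
  }
  return 4;
}

static void shape_at(int dim, int nen, const double *pt, double *N,
                     double dN[][3]) {
  if (dim == 2)
    shp_tri6(pt[0], pt[1], N, dN);
  else
    shp_tet10(pt[0], pt[1], pt[2], N, dN);
  if (nen != (dim == 2 ? 6 : 10))
    stop("only 6-node triangles / 10-node tetrahedra are supported");
}

// ------------------------------------------------------------ small 3x3 ----

static inline double det2(const double J[2][2]) {
  return J[0][0] * J[1][1] - J[0][1] * J[1][0];
}

static inline double det3m(const double *F) {
  return F[0] * (F[4] * F[8] - F[5] * F[7]) -
         F[1] * (F[3] * F[8] - F[5] * F[6]) +
         F[2] * (F[3] * F[7] - F[4] * F[6]);
}

static inline void inv3m(const double *F, double J, double *Fi) {
  double iJ = 1.0 / J;
  Fi[0] = (F[4] * F[8] - F[5] * F[7]) * iJ;
  Fi[1] = (F[2] * F[7] - F[1] * F[8]) * iJ;
  Fi[2] = (F[1] * F[5] - F[2] * F[4]) * iJ;
  Fi[3] = (F[5] * F[6] - F[3] * F[8]) * iJ;
  Fi[4] = (F[0] * F[8] - F[2] * F[6]) * iJ;
  Fi[5] = (F[2] * F[3] - F[0] * F[5]) * iJ;
  Fi[6] = (F[3] * F[7] - F[4] * F[6]) * iJ;
  Fi[7] = (F[1] * F[6] - F[0] * F[7]) * iJ;
  Fi[8] = (F[0] * F[4] - F[1] * F[3]) * iJ;
}

// Jacobian of the isoparametric map and reference-gradient of shapes.
// Returns detJ; fills dNdX (nen x dim).
static double map_gradients(int dim, int nen, const double *xe,
                            double dN[][3], double dNdX[][3]) {
  if (dim == 2) {
    double J[2][2] = {{0, 0}, {0, 0}};
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j) J[i][j] += xe[a * 2 + i] * dN[a][j];
    double d = det2(J);
    if (d <= 0.0) return d;
    double Ji[2][2] = {{J[1][1] / d, -J[0][1] / d}, {-J[1][0] / d, J[0][0] / d}};
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < 2; ++i)
        dNdX[a][i] = dN[a][0] * Ji[0][i] + dN[a][1] * Ji[1][i];
    return d;
  }
  double J[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  for (int a = 0; a < nen; ++a)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) J[i * 3 + j] += xe[a * 3 + i] * dN[a][j];
  double d = det3m(J);
  if (d <= 0.0) return d;
  double Ji[9];
  inv3m(J, d, Ji);
  for (int a = 0; a < nen; ++a)
    for (int i = 0; i < 3; ++i)
      dNdX[a][i] =
          dN[a][0] * Ji[0 * 3 + i] + dN[a][1] * Ji[1 * 3 + i] + dN[a][2] * Ji[2 * 3 + i];
  return d;
}

// ------------------------------------------------- linear elastic solid ----

// Unit-modulus stiffness triplets. Per-element contributions are returned with
// the owning element index so that the caller can scale each triplet by the
// Young's modulus of the element's tissue class: K(E) = sum_t E_t K_t.
// [[Rcpp::export]]
List cpp_stiffness_unit(NumericMatrix coords, IntegerMatrix elems, double nu) {
  int dim = coords.ncol(), nen = elems.ncol(), nel = elems.nrow();
  int nd = nen * dim;
  int nst = (dim == 2) ? 3 : 6;
  // D matrix for E = 1
  double D[6][6] = {{0}};
  double c = 1.0 / ((1.0 + nu) * (1.0 - 2.0 * nu));
  if (dim == 2) {
    D[0][0] = D[1][1] = c * (1.0 - nu);
    D[0][1] = D[1][0] = c * nu;
    D[2][2] = c * (1.0 - 2.0 * nu) / 2.0;
  } else {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) D[i][j] = (i == j) ? c * (1.0 - nu) : c * nu;
    for (int i = 3; i < 6; ++i) D[i][i] = c * (1.0 - 2.0 * nu) / 2.0;
  }
  double pts[8][3], w[8];
  int nqp = quad_rule(dim, pts, w);
  double N[MAXNEN], dN[MAXNEN][3], dNdX[MAXNEN][3];

  R_xlen_t ntrip = (R_xlen_t)nel * nd * nd;
  IntegerVector I(ntrip), Jv(ntrip), elem_of(ntrip);
  NumericVector V(ntrip);
  std::vector<double> Ke(nd * nd), B(nst * nd);

  R_xlen_t t = 0;
  for (int e = 0; e < nel; ++e) {
    double xe[MAXNEN * 3];
    int conn[MAXNEN];
    for (int a = 0; a < nen; ++a) {
      conn[a] = elems(e, a) - 1;
      for (int i = 0; i < dim; ++i) xe[a * dim + i] = coords(conn[a], i);
    }
    std::fill(Ke.begin(), Ke.end(), 0.0);
    for (int q = 0; q < nqp; ++q) {
      shape_at(dim, nen, pts[q], N, dN);
      double detJ = map_gradients(dim, nen, xe, dN, dNdX);
      if (detJ <= 0.0) stop("non-positive Jacobian in element %d", e + 1);
      std::fill(B.begin(), B.end(), 0.0);
      for (int a = 0; a < nen; ++a) {
        if (dim == 2) {
          B[0 * nd + a * 2 + 0] = dNdX[a][0];
          B[1 * nd + a * 2 + 1] = dNdX[a][1];
          B[2 * nd + a * 2 + 0] = dNdX[a][1];
          B[2 * nd + a * 2 + 1] = dNdX[a][0];
        } else {
          B[0 * nd + a * 3 + 0] = dNdX[a][0];
          B[1 * nd + a * 3 + 1] = dNdX[a][1];
          B[2 * nd + a * 3 + 2] = dNdX[a][2];
          B[3 * nd + a * 3 + 0] = dNdX[a][1];  // gamma_xy
          B[3 * nd + a * 3 + 1] = dNdX[a][0];
          B[4 * nd + a * 3 + 1] = dNdX[a][2];  // gamma_yz
          B[4 * nd + a * 3 + 2] = dNdX[a][1];
          B[5 * nd + a * 3 + 0] = dNdX[a][2];  // gamma_zx
          B[5 * nd + a * 3 + 2] = dNdX[a][0];
        }
      }
      double wdet = w[q] * detJ;
      // Ke += B' D B * wdet
      for (int r = 0; r < nd; ++r) {
        double DBr[6];
        for (int s = 0; s < nst; ++s) {
          DBr[s] = 0.0;
          for (int u = 0; u < nst; ++u) DBr[s] += D[s][u] * B[u * nd + r];
        }
        for (int ccol = 0; ccol < nd; ++ccol) {
          double v = 0.0;
          for (int s = 0; s < nst; ++s) v += B[s * nd + ccol] * DBr[s];
          Ke[r * nd + ccol] += v * wdet;
        }
      }
    }
    for (int r = 0; r < nd; ++r) {
      int gi = conn[r / dim] * dim + (r % dim) + 1;
      for (int cc = 0; cc < nd; ++cc) {
        I[t] = gi;
        Jv[t] = conn[cc / dim] * dim + (cc % dim) + 1;
        V[t] = Ke[r * nd + cc];
        elem_of[t] = e + 1;
        ++t;
      }
    }
  }
  return List::create(_["i"] = I, _["j"] = Jv, _["x"] = V,
                      _["elem"] = elem_of);
}

// ----------------------------------------------------------- Yeoh solid ----

// First Piola-Kirchhoff stress P and material tangent A = dP/dF for
// W = sum_k Ck0 (I1bar - 3)^k + kappa/2 (J - 1)^2, I1bar = J^{-2/3} tr(F'F).
// F, P row-major 3x3; A row-major 3x3x3x3. Returns false when J <= 0.
static bool yeoh_PA(const double *F, double C10, double C20, double C30,
                    double kap, double *P, double *A) {
  double J = det3m(F);
  if (J <= 0.0) return false;
  double Fi[9];
  inv3m(F, J, Fi);
  double FiT[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) FiT[i * 3 + j] = Fi[j * 3 + i];
  double I1 = 0.0;
  for (int i = 0; i < 9; ++i) I1 += F[i] * F[i];
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double I1b = Jm23 * I1;
  double x = I1b - 3.0;
  double w1 = C10 + 2.0 * C20 * x + 3.0 * C30 * x * x;
  double w2 = 2.0 * C20 + 6.0 * C30 * x;
  double G[9];
  for (int i = 0; i < 9; ++i) G[i] = 2.0 * Jm23 * F[i] - (2.0 / 3.0) * I1b * FiT[i];
  double volc = kap * (J * J - J);  // kappa (J-1) J
  for (int i = 0; i < 9; ++i) P[i] = w1 * G[i] + volc * FiT[i];
  double kvol1 = kap * (2.0 * J - 1.0) * J;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l) {
          double dG = -(4.0 / 3.0) * Jm23 * F[i * 3 + j] * FiT[k * 3 + l] -
                      (2.0 / 3.0) * G[k * 3 + l] * FiT[i * 3 + j] +
                      (2.0 / 3.0) * I1b * Fi[j * 3 + k] * Fi[l * 3 + i];
          if (i == k && j == l) dG += 2.0 * Jm23;
          double a = w2 * G[i * 3 + j] * G[k * 3 + l] + w1 * dG +
                     kvol1 * FiT[k * 3 + l] * FiT[i * 3 + j] -
                     volc * Fi[j * 3 + k] * Fi[l * 3 + i];
          A[((i * 3 + j) * 3 + k) * 3 + l] = a;
        }
  return true;
}

// Internal force and tangent stiffness for the Yeoh solid, total-Lagrangian.
// u is the current displacement (n x dim); matpar is nel x 4 (C10 C20 C30
// kappa, per element). Plane strain in 2D (F33 = 1). Also reports min J and
// the maximum deviatoric invariant excess max(I1bar - 3) for strain checks.
// [[Rcpp::export]]
List cpp_assemble_yeoh(NumericMatrix coords, IntegerMatrix elems,
                       NumericMatrix u, NumericMatrix matpar, bool want_K) {
  int dim = coords.ncol(), nen = elems.ncol(), nel = elems.nrow();
  int nd = nen * dim;
  double pts[8][3], w[8];
  int nqp = quad_rule(dim, pts, w);
  double N[MAXNEN], dN[MAXNEN][3], dNdX[MAXNEN][3];
  double P[9], A[81];

  R_xlen_t ntrip = want_K ? (R_xlen_t)nel * nd * nd : 0;
  IntegerVector I(ntrip), Jv(ntrip);
  NumericVector V(ntrip);
  NumericVector fint((R_xlen_t)coords.nrow() * dim);
  std::vector<double> Ke(nd * nd);
  double minJ = R_PosInf, maxI1x = 0.0;
  bool ok = true;

  R_xlen_t t = 0;
  for (int e = 0; e < nel && ok; ++e) {
    double xe[MAXNEN * 3], ue[MAXNEN * 3];
    int conn[MAXNEN];
    for (int a = 0; a < nen; ++a) {
      conn[a] = elems(e, a) - 1;
      for (int i = 0; i < dim; ++i) {
        xe[a * dim + i] = coords(conn[a], i);
        ue[a * dim + i] = u(conn[a], i);
      }
    }
    if (want_K) std::fill(Ke.begin(), Ke.end(), 0.0);
    double fe[MAXNEN * 3] = {0.0};
    for (int q = 0; q < nqp; ++q) {
      shape_at(dim, nen, pts[q], N, dN);
      double detJ = map_gradients(dim, nen, xe, dN, dNdX);
      if (detJ <= 0.0) stop("non-positive reference Jacobian in element %d", e + 1);
      // deformation gradient, embedded in 3x3
      double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      for (int a = 0; a < nen; ++a)
        for (int i = 0; i < dim; ++i)
          for (int j = 0; j < dim; ++j)
            F[i * 3 + j] += ue[a * dim + i] * dNdX[a][j];
      if (!yeoh_PA(F, matpar(e, 0), matpar(e, 1), matpar(e, 2), matpar(e, 3),
                   P, A)) {
        ok = false;
        break;
      }
      double Jdef = det3m(F);
      if (Jdef < minJ) minJ = Jdef;
      double I1 = 0.0;
      for (int i = 0; i < 9; ++i) I1 += F[i] * F[i];
      double x = std::pow(Jdef, -2.0 / 3.0) * I1 - 3.0;
      if (x > maxI1x) maxI1x = x;
      double wdet = w[q] * detJ;
      for (int a = 0; a < nen; ++a)
        for (int i = 0; i < dim; ++i) {
          double v = 0.0;
          for (int j = 0; j < dim; ++j) v += P[i * 3 + j] * dNdX[a][j];
          fe[a * dim + i] += v * wdet;
        }
      if (want_K) {
        for (int a = 0; a < nen; ++a)
          for (int i = 0; i < dim; ++i)
            for (int b = 0; b < nen; ++b)
              for (int k = 0; k < dim; ++k) {
                double v = 0.0;
                for (int j = 0; j < dim; ++j)
                  for (int l = 0; l < dim; ++l)
                    v += A[((i * 3 + j) * 3 + k) * 3 + l] * dNdX[a][j] *
                         dNdX[b][l];
                Ke[(a * dim + i) * nd + (b * dim + k)] += v * wdet;
              }
      }
    }
    if (!ok) break;
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) fint[conn[a] * dim + i] += fe[a * dim + i];
    if (want_K) {
      for (int r = 0; r < nd; ++r) {
        int gi = conn[r / dim] * dim + (r % dim) + 1;
        for (int cc = 0; cc < nd; ++cc) {
          I[t] = gi;
          Jv[t] = conn[cc / dim] * dim + (cc % dim) + 1;
          V[t] = Ke[r * nd + cc];
          ++t;
        }
      }
    }
  }
  return List::create(_["ok"] = ok, _["i"] = I, _["j"] = Jv, _["x"] = V,
                      _["fint"] = fint, _["minJ"] = minJ,
                      _["maxI1dev"] = maxI1x);
}

// ------------------------------------------------------- pressure loads ----

// Consistent nodal forces for a uniform pressure on quadratic boundary
// facets, evaluated on the supplied (possibly deformed) coordinates. In 2D a
// facet is a 3-node edge (end, end, mid); the force direction is the
// left-hand perpendicular of the running tangent, so facet orientation
// encodes the push direction. In 3D a facet is a 6-node triangle and the
// direction follows the right-hand normal of its corner ordering.
// [[Rcpp::export]]
NumericVector cpp_pressure_force(NumericMatrix coords, IntegerMatrix facets,
                                 double P) {
  int dim = coords.ncol();
  NumericVector f((R_xlen_t)coords.nrow() * dim);
  if (dim == 2) {
    // 3-point Gauss on t in [0,1]
    double tq[3] = {0.1127016653792583, 0.5, 0.8872983346207417};
    double wq[3] = {5.0 / 18.0, 8.0 / 18.0, 5.0 / 18.0};
    for (int e = 0; e < facets.nrow(); ++e) {
      int nidx[3] = {facets(e, 0) - 1, facets(e, 1) - 1, facets(e, 2) - 1};
      for (int q = 0; q < 3; ++q) {
        double t = tq[q];
        double N[3] = {(1 - t) * (1 - 2 * t), t * (2 * t - 1), 4 * t * (1 - t)};
        double dN[3] = {4 * t - 3, 4 * t - 1, 4 - 8 * t};
        double tx = 0, ty = 0;
        for (int a = 0; a < 3; ++a) {
          tx += dN[a] * coords(nidx[a], 0);
          ty += dN[a] * coords(nidx[a], 1);
        }
        double nx = ty, ny = -tx;  // perpendicular of the running tangent
        for (int a = 0; a < 3; ++a) {
          f[nidx[a] * 2 + 0] += P * wq[q] * N[a] * nx;
          f[nidx[a] * 2 + 1] += P * wq[q] * N[a] * ny;
        }
      }
    }
  } else {
    double pts[8][3], w[8];
    int nqp = quad_rule(2, pts, w);
    double N[6], dN[6][3];
    for (int e = 0; e < facets.nrow(); ++e) {
      int nidx[6];
      for (int a = 0; a < 6; ++a) nidx[a] = facets(e, a) - 1;
      for (int q = 0; q < nqp; ++q) {
        shp_tri6(pts[q][0], pts[q][1], N, dN);
        double g1[3] = {0, 0, 0}, g2[3] = {0, 0, 0};
        for (int a = 0; a < 6; ++a)
          for (int i = 0; i < 3; ++i) {
            g1[i] += dN[a][0] * coords(nidx[a], i);
            g2[i] += dN[a][1] * coords(nidx[a], i);
          }
        double n[3] = {g1[1] * g2[2] - g1[2] * g2[1],
                       g1[2] * g2[0] - g1[0] * g2[2],
                       g1[0] * g2[1] - g1[1] * g2[0]};
        for (int a = 0; a < 6; ++a)
          for (int i = 0; i < 3; ++i)
            f[nidx[a] * 3 + i] += P * w[q] * N[a] * n[i];
      }
    }
  }
  return f;
}

// -------------------------------------------------------------- measures ----

// Element areas/volumes by quadrature, with the minimum isoparametric
// Jacobian per element (<= 0 flags an inverted or degenerate element).
// [[Rcpp::export]]
List cpp_measures(NumericMatrix coords, IntegerMatrix elems) {
  int dim = coords.ncol(), nen = elems.ncol(), nel = elems.nrow();
  double pts[8][3], w[8];
  int nqp = quad_rule(dim, pts, w);
  double N[MAXNEN], dN[MAXNEN][3], dNdX[MAXNEN][3];
  NumericVector meas(nel), minj(nel);
  for (int e = 0; e < nel; ++e) {
    double xe[MAXNEN * 3];
    for (int a = 0; a < nen; ++a) {
      int na = elems(e, a) - 1;
      for (int i = 0; i < dim; ++i) xe[a * dim + i] = coords(na, i);
    }
    double m = 0.0, mj = R_PosInf;
    for (int q = 0; q < nqp; ++q) {
      shape_at(dim, nen, pts[q], N, dN);
      double detJ = map_gradients(dim, nen, xe, dN, dNdX);
      if (detJ < mj) mj = detJ;
      m += w[q] * detJ;
    }
    meas[e] = m;
    minj[e] = mj;
  }
  return List::create(_["measure"] = meas, _["min_jacobian"] = minj);
}

// --------------------------------------------------------------- kd-tree ----

struct KDTree {
  const double *pts;  // column-major n x d
  int n, d;
  std::vector<int> idx;     // permutation of point indices
  std::vector<int> lo, hi;  // node ranges into idx (leaf when small)
  // recursion realized directly on idx ranges; nodes alternate axes by depth

  KDTree(const double *p, int n_, int d_) : pts(p), n(n_), d(d_), idx(n_) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }
  double coord(int i, int ax) const { return pts[(R_xlen_t)ax * n + i]; }
  void build(int l, int r, int depth) {
    if (r - l <= 8) return;
    int ax = depth % d, m = (l + r) / 2;
    const double *P = pts;
    int N = n;
    std::nth_element(idx.begin() + l, idx.begin() + m, idx.begin() + r,
                     [P, N, ax](int a, int b) {
                       double ca = P[(R_xlen_t)ax * N + a],
                              cb = P[(R_xlen_t)ax * N + b];
                       return ca < cb || (ca == cb && a < b);
                     });
    build(l, m, depth + 1);
    build(m + 1, r, depth + 1);
  }
  void query(const double *q, int l, int r, int depth, double &bd2,
             int &bi) const {
    if (r - l <= 8) {
      for (int i = l; i < r; ++i) scan(q, idx[i], bd2, bi);
      return;
    }
    int ax = depth % d, m = (l + r) / 2;
    int pm = idx[m];
    scan(q, pm, bd2, bi);
    double diff = q[ax] - coord(pm, ax);
    if (diff < 0) {
      query(q, l, m, depth + 1, bd2, bi);
      if (diff * diff <= bd2) query(q, m + 1, r, depth + 1, bd2, bi);
    } else {
      query(q, m + 1, r, depth + 1, bd2, bi);
      if (diff * diff <= bd2) query(q, l, m, depth + 1, bd2, bi);
    }
  }
  void scan(const double *q, int i, double &bd2, int &bi) const {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double dd = q[k] - coord(i, k);
      s += dd * dd;
    }
    if (s < bd2 || (s == bd2 && i < bi)) {
      bd2 = s;
      bi = i;
    }
  }
};

// Nearest reference point for every query point (Euclidean); ties on exact
// distance resolve to the lowest reference row index.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix ref, NumericMatrix query) {
  int n = ref.nrow(), d = ref.ncol(), m = query.nrow();
  if (n < 1) stop("empty reference point set");
  if (query.ncol() != d) stop("dimension mismatch in nearest-neighbour query");
  KDTree tree(ref.begin(), n, d);
  IntegerVector out(m);
  NumericVector dist(m);
  std::vector<double> q(d);
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < d; ++k) q[k] = query(i, k);
    double bd2 = R_PosInf;
    int bi = n;
    tree.query(q.data(), 0, n, 0, bd2, bi);
    out[i] = bi + 1;
    dist[i] = std::sqrt(bd2);
  }
  return List::create(_["index"] = out, _["dist"] = dist);
}

// ------------------------------------------------------- scatter add ----

// Accumulate triplet values into an n-vector by precomputed 1-based
// positions (the CSC slot layout of the reduced stiffness matrix).
// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector values, IntegerVector pos,
                              int n) {
  NumericVector out(n);
  R_xlen_t m = values.size();
  if (pos.size() != m) stop("values/pos length mismatch");
  for (R_xlen_t k = 0; k < m; ++k) out[pos[k] - 1] += values[k];
  return out;
}
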