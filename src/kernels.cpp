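// Computational kernels for the charge-based BEM:
//  - closed-form E-field of a uniformly charged flat triangle (solid angle
//    + edge-potential terms), principal value on the triangle plane
//  - exact pairwise Coulomb sums (point charges / current elements)
//  - grid-based near-pair search and near-field corrections
//  - Barnes-Hut treecode (Cartesian moments up to octupole order)
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

static const double INV4PI = 1.0 / (4.0 * M_PI);

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// E-field at p of a unit (scaled) charge density on triangle (v1,v2,v3),
// including the 1/(4*pi) factor.  On the triangle's own plane the normal
// component is the principal value (zero); in-plane components are kept.
static void triField(const double* v1, const double* v2, const double* v3,
                     const double* p, double* E) {
  double e1[3], e2[3], nrm[3];
  for (int k = 0; k < 3; ++k) { e1[k] = v2[k] - v1[k]; e2[k] = v3[k] - v1[k]; }
  cross3(e1, e2, nrm);
  double twoA = norm3(nrm);
  if (twoA <= 0.0) { E[0] = E[1] = E[2] = 0.0; return; }
  for (int k = 0; k < 3; ++k) nrm[k] /= twoA;
  double d1[3];
  for (int k = 0; k < 3; ++k) d1[k] = p[k] - v1[k];
  double w = dot3(d1, nrm);
  double diam = std::sqrt(std::max(dot3(e1, e1), dot3(e2, e2)));

  // signed solid angle (van Oosterom & Strackee); negated so that the
  // normal term is +2*pi*n on the side the normal points to
  double r1[3], r2[3], r3[3];
  for (int k = 0; k < 3; ++k) {
    r1[k] = v1[k] - p[k]; r2[k] = v2[k] - p[k]; r3[k] = v3[k] - p[k];
  }
  double l1 = norm3(r1), l2 = norm3(r2), l3 = norm3(r3);
  double c12[3];
  cross3(r1, r2, c12);
  double num = dot3(c12, r3);
  double den = l1 * l2 * l3 + dot3(r1, r2) * l3 + dot3(r1, r3) * l2 +
               dot3(r2, r3) * l1;
  double omega = (std::fabs(w) < 1e-12 * diam) ? 0.0 : -2.0 * std::atan2(num, den);

  double Ex = omega * nrm[0], Ey = omega * nrm[1], Ez = omega * nrm[2];

  const double* vs[4] = {v1, v2, v3, v1};
  for (int i = 0; i < 3; ++i) {
    const double* a = vs[i];
    const double* b = vs[i + 1];
    double u[3];
    for (int k = 0; k < 3; ++k) u[k] = b[k] - a[k];
    double L = norm3(u);
    if (L <= 0.0) continue;
    for (int k = 0; k < 3; ++k) u[k] /= L;
    double am[3], bm[3];
    for (int k = 0; k < 3; ++k) { am[k] = a[k] - p[k]; bm[k] = b[k] - p[k]; }
    double sm = dot3(am, u), sp = dot3(bm, u);
    double Rm = norm3(am), Rp = norm3(bm);
    // two algebraically equal forms of the edge potential integral;
    // pick the numerically stable one (larger denominator)
    double I;
    double den1 = Rm + sm, den2 = Rp - sp;
    if (den1 >= den2) {
      I = (den1 > 0.0) ? std::log((Rp + sp) / den1) : 0.0;
    } else {
      I = (den2 > 0.0) ? std::log((Rm - sm) / den2) : 0.0;
    }
    double m[3];
    cross3(u, nrm, m);
    Ex += m[0] * I; Ey += m[1] * I; Ez += m[2] * I;
  }
  E[0] = INV4PI * Ex; E[1] = INV4PI * Ey; E[2] = INV4PI * Ez;
}

// Field of one or more uniformly charged triangles at arbitrary points.
// tri9: nt x 9 matrix (v1x v1y v1z v2x ... v3z); x: charge density per
// triangle (scaled, V/m); returns np x 3 summed field.
// [[Rcpp::export]]
NumericMatrix cpp_tri_field_points(NumericMatrix tri9, NumericVector x,
                                   NumericMatrix pts) {
  int nt = tri9.nrow(), np = pts.nrow();
  if (x.size() != nt) stop("length(x) must equal nrow(tri9)");
  NumericMatrix out(np, 3);
  std::vector<double> T(tri9.begin(), tri9.end());
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double acc[3] = {0, 0, 0}, E[3];
    for (int n = 0; n < nt; ++n) {
      double v1[3], v2[3], v3[3];
      for (int k = 0; k < 3; ++k) {
        v1[k] = T[n + (size_t)nt * k];
        v2[k] = T[n + (size_t)nt * (3 + k)];
        v3[k] = T[n + (size_t)nt * (6 + k)];
      }
      triField(v1, v2, v3, p, E);
      acc[0] += x[n] * E[0]; acc[1] += x[n] * E[1]; acc[2] += x[n] * E[2];
    }
    out(i, 0) = acc[0]; out(i, 1) = acc[1]; out(i, 2) = acc[2];
  }
  return out;
}

// Dense system matrix A_mn = 0.5 delta_mn - K_m n_m . <E_n>_{t_m}, where
// <.>_{t_m} is a quadrature average over facet m (barycentric rule qbary/qw)
// and E_n the analytic field of a unit charge density on facet n.
// [[Rcpp::export]]
NumericMatrix cpp_assemble_dense(NumericMatrix tri9, NumericMatrix normals,
                                 NumericVector K, NumericMatrix qbary,
                                 NumericVector qw) {
  int N = tri9.nrow(), nq = qbary.nrow();
  NumericMatrix A(N, N);
  std::vector<double> T(tri9.begin(), tri9.end());
  // quadrature points per observation facet, precomputed
  std::vector<double> QP((size_t)N * nq * 3);
  for (int m = 0; m < N; ++m) {
    for (int q = 0; q < nq; ++q) {
      for (int k = 0; k < 3; ++k) {
        double v1 = T[m + (size_t)N * k];
        double v2 = T[m + (size_t)N * (3 + k)];
        double v3 = T[m + (size_t)N * (6 + k)];
        QP[((size_t)m * nq + q) * 3 + k] =
          qbary(q, 0) * v1 + qbary(q, 1) * v2 + qbary(q, 2) * v3;
      }
    }
  }
  for (int n = 0; n < N; ++n) {
    double v1[3], v2[3], v3[3];
    for (int k = 0; k < 3; ++k) {
      v1[k] = T[n + (size_t)N * k];
      v2[k] = T[n + (size_t)N * (3 + k)];
      v3[k] = T[n + (size_t)N * (6 + k)];
    }
    for (int m = 0; m < N; ++m) {
      if (m == n) continue;  // flat-facet self-term: exactly 0.5 on diagonal
      double s = 0.0, E[3];
      for (int q = 0; q < nq; ++q) {
        const double* p = &QP[((size_t)m * nq + q) * 3];
        triField(v1, v2, v3, p, E);
        s += qw[q] * (normals(m, 0) * E[0] + normals(m, 1) * E[1] +
                      normals(m, 2) * E[2]);
      }
      A(m, n) = -K[m] * s;
    }
  }
  for (int m = 0; m < N; ++m) A(m, m) = 0.5;
  return A;
}

// Exact pairwise Coulomb field (1/4pi) sum_j q_j (p - s_j)/|p - s_j|^3.
// exclude_self skips source-target pairs closer than 1e-14 (used when the
// sources and targets are the same centroids).
// [[Rcpp::export]]
NumericMatrix cpp_point_charge_field(NumericMatrix src, NumericVector q,
                                     NumericMatrix pts, bool exclude_self) {
  int ns = src.nrow(), np = pts.nrow();
  NumericMatrix out(np, 3);
  std::vector<double> sx(ns), sy(ns), sz(ns), qq(ns);
  for (int j = 0; j < ns; ++j) {
    sx[j] = src(j, 0); sy[j] = src(j, 1); sz[j] = src(j, 2); qq[j] = q[j];
  }
  for (int i = 0; i < np; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double ax = 0, ay = 0, az = 0;
    for (int j = 0; j < ns; ++j) {
      double dx = px - sx[j], dy = py - sy[j], dz = pz - sz[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (exclude_self && r2 < 1e-28) continue;
      double inv = 1.0 / std::sqrt(r2);
      double f = qq[j] * inv * inv * inv;
      ax += f * dx; ay += f * dy; az += f * dz;
    }
    out(i, 0) = INV4PI * ax; out(i, 1) = INV4PI * ay; out(i, 2) = INV4PI * az;
  }
  return out;
}

// Exact pairwise sum of oriented current elements: sum_j m_j / |p - s_j|
// (the 1/R kernel of the magnetic vector potential); distances are floored
// at eps to regularize points next to an element.
// [[Rcpp::export]]
NumericMatrix cpp_vecpot_sum(NumericMatrix src, NumericMatrix mom,
                             NumericMatrix pts, double eps) {
  int ns = src.nrow(), np = pts.nrow();
  NumericMatrix out(np, 3);
  for (int i = 0; i < np; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double ax = 0, ay = 0, az = 0;
    for (int j = 0; j < ns; ++j) {
      double dx = px - src(j, 0), dy = py - src(j, 1), dz = pz - src(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < eps) r = eps;
      if (r == 0.0) stop("observation point coincides with a coil element");
      double inv = 1.0 / r;
      ax += mom(j, 0) * inv; ay += mom(j, 1) * inv; az += mom(j, 2) * inv;
    }
    out(i, 0) = ax; out(i, 1) = ay; out(i, 2) = az;
  }
  return out;
}

// Near-pair search on a uniform grid: ordered pairs (m, n), m != n, with
// |c_m - c_n| < eta * (rho_m + rho_n).  Returns 1-based index vectors.
// [[Rcpp::export]]
List cpp_near_pairs(NumericMatrix centroids, NumericVector rho, double eta) {
  int N = centroids.nrow();
  double rmax = 0.0;
  for (int i = 0; i < N; ++i) rmax = std::max(rmax, (double)rho[i]);
  double h = std::max(eta * 2.0 * rmax, 1e-300);
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) mn[k] = std::min(mn[k], centroids(i, k));
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(N * 2);
  std::vector<int> cx(N), cy(N), cz(N);
  for (int i = 0; i < N; ++i) {
    cx[i] = (int)std::floor((centroids(i, 0) - mn[0]) / h);
    cy[i] = (int)std::floor((centroids(i, 1) - mn[1]) / h);
    cz[i] = (int)std::floor((centroids(i, 2) - mn[2]) / h);
    long long key = (long long)cx[i] + 2097152LL * ((long long)cy[i] +
                    2097152LL * (long long)cz[i]);
    grid[key].push_back(i);
  }
  std::vector<int> pi, pj;
  pi.reserve((size_t)N * 32);
  pj.reserve((size_t)N * 32);
  for (int i = 0; i < N; ++i) {
    double xi = centroids(i, 0), yi = centroids(i, 1), zi = centroids(i, 2);
    for (int ax = cx[i] - 1; ax <= cx[i] + 1; ++ax)
      for (int ay = cy[i] - 1; ay <= cy[i] + 1; ++ay)
        for (int az = cz[i] - 1; az <= cz[i] + 1; ++az) {
          long long key = (long long)ax + 2097152LL * ((long long)ay +
                          2097152LL * (long long)az);
          std::unordered_map<long long, std::vector<int> >::iterator it =
            grid.find(key);
          if (it == grid.end()) continue;
          const std::vector<int>& cell = it->second;
          for (size_t t = 0; t < cell.size(); ++t) {
            int j = cell[t];
            if (j == i) continue;
            double dx = xi - centroids(j, 0), dy = yi - centroids(j, 1),
                   dz = zi - centroids(j, 2);
            double cut = eta * (rho[i] + rho[j]);
            if (dx * dx + dy * dy + dz * dz < cut * cut) {
              pi.push_back(i + 1);
              pj.push_back(j + 1);
            }
          }
        }
  }
  return List::create(_["i"] = IntegerVector(pi.begin(), pi.end()),
                      _["j"] = IntegerVector(pj.begin(), pj.end()));
}

// Near-field correction values for the matrix-free operator: for each pair
// (m, n) the difference between the analytic panel term and the point-charge
// term, projected on n_m and scaled by -K_m, i.e. the sparse correction
// Delta_mn to add on top of the far point-charge product.
// [[Rcpp::export]]
NumericVector cpp_near_values(NumericMatrix tri9, NumericMatrix centroids,
                              NumericMatrix normals, NumericVector areas,
                              NumericVector K, IntegerVector pi,
                              IntegerVector pj, NumericMatrix qbary,
                              NumericVector qw) {
  int N = tri9.nrow(), nq = qbary.nrow();
  R_xlen_t npair = pi.size();
  NumericVector val(npair);
  std::vector<double> T(tri9.begin(), tri9.end());
  for (R_xlen_t k = 0; k < npair; ++k) {
    int m = pi[k] - 1, n = pj[k] - 1;
    double v1[3], v2[3], v3[3];
    for (int c = 0; c < 3; ++c) {
      v1[c] = T[n + (size_t)N * c];
      v2[c] = T[n + (size_t)N * (3 + c)];
      v3[c] = T[n + (size_t)N * (6 + c)];
    }
    // analytic term averaged over facet m's quadrature points
    double an = 0.0, E[3];
    for (int q = 0; q < nq; ++q) {
      double p[3];
      for (int c = 0; c < 3; ++c) {
        double w1 = T[m + (size_t)N * c], w2 = T[m + (size_t)N * (3 + c)],
               w3 = T[m + (size_t)N * (6 + c)];
        p[c] = qbary(q, 0) * w1 + qbary(q, 1) * w2 + qbary(q, 2) * w3;
      }
      triField(v1, v2, v3, p, E);
      an += qw[q] * (normals(m, 0) * E[0] + normals(m, 1) * E[1] +
                     normals(m, 2) * E[2]);
    }
    // point-charge term at the centroid of m (what the far backend adds)
    double dx = centroids(m, 0) - centroids(n, 0),
           dy = centroids(m, 1) - centroids(n, 1),
           dz = centroids(m, 2) - centroids(n, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double pc = 0.0;
    if (r2 > 0) {
      double inv = 1.0 / std::sqrt(r2);
      double f = INV4PI * areas[n] * inv * inv * inv;
      pc = f * (normals(m, 0) * dx + normals(m, 1) * dy + normals(m, 2) * dz);
    }
    val[k] = -K[m] * (an - pc);
  }
  return val;
}

// Secondary E-field of the facet charges at arbitrary points: analytic
// panel integrals for facets with |p - c_n| < eta*(rho_p + rho_n) (or for
// all facets when exact = true), centroid point charges otherwise.
// rho_pts supplies a per-point radius (facet circumradius when the points
// are facet centroids, 0 for free-space points).  guard > 0 raises an error
// when a point is closer than guard*rho_n to facet n.
// [[Rcpp::export]]
NumericMatrix cpp_secondary_field(NumericMatrix tri9, NumericMatrix centroids,
                                  NumericVector areas, NumericVector rho,
                                  NumericVector x, NumericMatrix pts,
                                  NumericVector rho_pts, double eta,
                                  bool exact, double guard) {
  int N = tri9.nrow(), np = pts.nrow();
  NumericMatrix out(np, 3);
  std::vector<double> T(tri9.begin(), tri9.end());
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double acc[3] = {0, 0, 0}, E[3];
    double rp = rho_pts[i];
    for (int n = 0; n < N; ++n) {
      double dx = p[0] - centroids(n, 0), dy = p[1] - centroids(n, 1),
             dz = p[2] - centroids(n, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (guard > 0.0) {
        double g = guard * rho[n];
        if (r2 < g * g)
          stop("observation point %d violates the distance guard at facet %d",
               i + 1, n + 1);
      }
      double cut = eta * (rp + rho[n]);
      if (exact || r2 < cut * cut) {
        double v1[3], v2[3], v3[3];
        for (int c = 0; c < 3; ++c) {
          v1[c] = T[n + (size_t)N * c];
          v2[c] = T[n + (size_t)N * (3 + c)];
          v3[c] = T[n + (size_t)N * (6 + c)];
        }
        triField(v1, v2, v3, p, E);
        acc[0] += x[n] * E[0]; acc[1] += x[n] * E[1]; acc[2] += x[n] * E[2];
      } else {
        double inv = 1.0 / std::sqrt(r2);
        double f = INV4PI * x[n] * areas[n] * inv * inv * inv;
        acc[0] += f * dx; acc[1] += f * dy; acc[2] += f * dz;
      }
    }
    out(i, 0) = acc[0]; out(i, 1) = acc[1]; out(i, 2) = acc[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Barnes-Hut treecode with Cartesian moments up to order 3 (octupole).
// One tree serves two kernels: the Coulomb field of scalar charges
// (gradient kernel) and the 1/R sum of vector-weighted current elements.
// ---------------------------------------------------------------------------

// moments per weight channel in symmetric-reduced storage:
// M0 scalar; M1[3]; M2 six unique (xx,yy,zz,xy,xz,yz) plus trace;
// M3 ten unique (xxx,yyy,zzz,xxy,xxz,xyy,yyz,xzz,yzz,xyz) plus the
// single-contraction vector w_l = sum_i M3_iil
struct TreeNode {
  double center[3];
  double radius;        // max distance from center to a contained source
  int start, end;       // range in the permutation array
  int child[8];         // -1 when absent
  bool leaf;
  std::vector<double> M0;   // nw
  std::vector<double> M1;   // 3*nw
  std::vector<double> M2;   // 6*nw
  std::vector<double> tr2;  // nw
  std::vector<double> M3;   // 10*nw
  std::vector<double> w3;   // 3*nw
};

struct Tree {
  std::vector<TreeNode> nodes;
  std::vector<int> perm;           // permuted source indices
  const double* S;                 // ns x 3 source coordinates (column-major)
  int ns, nw;
  const double* W;                 // ns x nw weights (column-major)
  int leaf_size;

  double sx(int j) const { return S[j]; }
  double sy(int j) const { return S[j + ns]; }
  double sz(int j) const { return S[j + 2 * ns]; }

  int build(int start, int end, double cx, double cy, double cz, double half) {
    int id = (int)nodes.size();
    nodes.push_back(TreeNode());
    TreeNode& nd = nodes[id];
    nd.center[0] = cx; nd.center[1] = cy; nd.center[2] = cz;
    nd.start = start; nd.end = end;
    for (int k = 0; k < 8; ++k) nd.child[k] = -1;
    nd.leaf = (end - start <= leaf_size);
    double r2max = 0.0;
    for (int t = start; t < end; ++t) {
      int j = perm[t];
      double dx = sx(j) - cx, dy = sy(j) - cy, dz = sz(j) - cz;
      r2max = std::max(r2max, dx * dx + dy * dy + dz * dz);
    }
    nd.radius = std::sqrt(r2max);
    // moments about the node center (symmetric-reduced)
    nd.M0.assign(nw, 0.0);
    nd.M1.assign(3 * nw, 0.0);
    nd.M2.assign(6 * nw, 0.0);
    nd.tr2.assign(nw, 0.0);
    nd.M3.assign(10 * nw, 0.0);
    nd.w3.assign(3 * nw, 0.0);
    for (int t = start; t < end; ++t) {
      int j = perm[t];
      double dx = sx(j) - cx, dy = sy(j) - cy, dz = sz(j) - cz;
      for (int w = 0; w < nw; ++w) {
        double q = W[j + (size_t)ns * w];
        nd.M0[w] += q;
        nd.M1[0 + 3 * w] += q * dx;
        nd.M1[1 + 3 * w] += q * dy;
        nd.M1[2 + 3 * w] += q * dz;
        nd.M2[0 + 6 * w] += q * dx * dx;
        nd.M2[1 + 6 * w] += q * dy * dy;
        nd.M2[2 + 6 * w] += q * dz * dz;
        nd.M2[3 + 6 * w] += q * dx * dy;
        nd.M2[4 + 6 * w] += q * dx * dz;
        nd.M2[5 + 6 * w] += q * dy * dz;
        nd.M3[0 + 10 * w] += q * dx * dx * dx;
        nd.M3[1 + 10 * w] += q * dy * dy * dy;
        nd.M3[2 + 10 * w] += q * dz * dz * dz;
        nd.M3[3 + 10 * w] += q * dx * dx * dy;
        nd.M3[4 + 10 * w] += q * dx * dx * dz;
        nd.M3[5 + 10 * w] += q * dx * dy * dy;
        nd.M3[6 + 10 * w] += q * dy * dy * dz;
        nd.M3[7 + 10 * w] += q * dx * dz * dz;
        nd.M3[8 + 10 * w] += q * dy * dz * dz;
        nd.M3[9 + 10 * w] += q * dx * dy * dz;
      }
    }
    for (int w = 0; w < nw; ++w) {
      nd.tr2[w] = nd.M2[0 + 6 * w] + nd.M2[1 + 6 * w] + nd.M2[2 + 6 * w];
      // w3_l = sum_i M3_iil
      nd.w3[0 + 3 * w] = nd.M3[0 + 10 * w] + nd.M3[5 + 10 * w] +
        nd.M3[7 + 10 * w];
      nd.w3[1 + 3 * w] = nd.M3[3 + 10 * w] + nd.M3[1 + 10 * w] +
        nd.M3[8 + 10 * w];
      nd.w3[2 + 3 * w] = nd.M3[4 + 10 * w] + nd.M3[6 + 10 * w] +
        nd.M3[2 + 10 * w];
    }
    if (!nd.leaf) {
      // partition the range into octants
      int octStart[9];
      std::vector<int> oct(end - start);
      int cnt[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      for (int t = start; t < end; ++t) {
        int j = perm[t];
        int o = (sx(j) > cx ? 1 : 0) | (sy(j) > cy ? 2 : 0) |
                (sz(j) > cz ? 4 : 0);
        oct[t - start] = o;
        cnt[o]++;
      }
      octStart[0] = start;
      for (int o = 1; o <= 8; ++o) octStart[o] = octStart[o - 1] + cnt[o - 1];
      std::vector<int> tmp(perm.begin() + start, perm.begin() + end);
      int fill[8];
      for (int o = 0; o < 8; ++o) fill[o] = octStart[o];
      for (int t = 0; t < end - start; ++t) perm[fill[oct[t]]++] = tmp[t];
      double h2 = half * 0.5;
      for (int o = 0; o < 8; ++o) {
        if (cnt[o] == 0) continue;
        double ncx = cx + ((o & 1) ? h2 : -h2);
        double ncy = cy + ((o & 2) ? h2 : -h2);
        double ncz = cz + ((o & 4) ? h2 : -h2);
        int cid = build(octStart[o], octStart[o + 1], ncx, ncy, ncz, h2);
        nodes[id].child[o] = cid;   // note: nd reference may be stale
      }
    }
    return id;
  }
};

// contract x with the symmetric-reduced M2/M3 moments of one channel:
// t_l = M2_lj x_j, s2 = x M2 x, u_l = M3_ljk x_j x_k, s3 = M3 x x x
static inline void contractMoments(const double* M2, const double* M3,
                                   const double* x, double* t, double* s2,
                                   double* u, double* s3) {
  double xx = x[0] * x[0], yy = x[1] * x[1], zz = x[2] * x[2];
  double xy = x[0] * x[1], xz = x[0] * x[2], yz = x[1] * x[2];
  t[0] = M2[0] * x[0] + M2[3] * x[1] + M2[4] * x[2];
  t[1] = M2[3] * x[0] + M2[1] * x[1] + M2[5] * x[2];
  t[2] = M2[4] * x[0] + M2[5] * x[1] + M2[2] * x[2];
  *s2 = t[0] * x[0] + t[1] * x[1] + t[2] * x[2];
  u[0] = M3[0] * xx + M3[5] * yy + M3[7] * zz +
         2.0 * (M3[3] * xy + M3[4] * xz + M3[9] * yz);
  u[1] = M3[3] * xx + M3[1] * yy + M3[8] * zz +
         2.0 * (M3[5] * xy + M3[9] * xz + M3[6] * yz);
  u[2] = M3[4] * xx + M3[6] * yy + M3[2] * zz +
         2.0 * (M3[9] * xy + M3[7] * xz + M3[8] * yz);
  *s3 = u[0] * x[0] + u[1] * x[1] + u[2] * x[2];
}

// gradient-kernel expansion: E_l = D_l of sum_k moments (x) D^k G
static void momentFieldGrad(const TreeNode& nd, const double* p, double* E) {
  double x[3] = {p[0] - nd.center[0], p[1] - nd.center[1],
                 p[2] - nd.center[2]};
  double r2 = dot3(x, x), R = std::sqrt(r2);
  double iR2 = 1.0 / r2;
  double iR3 = 1.0 / (R * r2), iR5 = iR3 * iR2, iR7 = iR5 * iR2,
         iR9 = iR7 * iR2;
  double t[3], s2, u[3], s3;
  contractMoments(&nd.M2[0], &nd.M3[0], x, t, &s2, u, &s3);
  double s1 = nd.M1[0] * x[0] + nd.M1[1] * x[1] + nd.M1[2] * x[2];
  double wx = nd.w3[0] * x[0] + nd.w3[1] * x[1] + nd.w3[2] * x[2];
  double c_x = nd.M0[0] * iR3 + 3.0 * s1 * iR5 + 7.5 * s2 * iR7 -
               1.5 * nd.tr2[0] * iR5 + 17.5 * s3 * iR9 - 7.5 * wx * iR7;
  for (int l = 0; l < 3; ++l) {
    E[l] = c_x * x[l] - nd.M1[l] * iR3 - 3.0 * t[l] * iR5 -
           7.5 * u[l] * iR7 + 1.5 * nd.w3[l] * iR5;
  }
}

// value of the expansion of sum w/R for each weight channel
static void momentPotential(const TreeNode& nd, const double* p, int nw,
                            double* V) {
  double x[3] = {p[0] - nd.center[0], p[1] - nd.center[1],
                 p[2] - nd.center[2]};
  double r2 = dot3(x, x), R = std::sqrt(r2);
  double iR = 1.0 / R, iR2 = 1.0 / r2;
  double iR3 = iR * iR2, iR5 = iR3 * iR2, iR7 = iR5 * iR2;
  for (int w = 0; w < nw; ++w) {
    double t[3], s2, u[3], s3;
    contractMoments(&nd.M2[6 * w], &nd.M3[10 * w], x, t, &s2, u, &s3);
    double s1 = nd.M1[0 + 3 * w] * x[0] + nd.M1[1 + 3 * w] * x[1] +
                nd.M1[2 + 3 * w] * x[2];
    double wx = nd.w3[0 + 3 * w] * x[0] + nd.w3[1 + 3 * w] * x[1] +
                nd.w3[2 + 3 * w] * x[2];
    V[w] = nd.M0[w] * iR + s1 * iR3 +
           (1.5 * s2 - 0.5 * nd.tr2[w] * r2) * iR5 +
           (2.5 * s3 - 1.5 * r2 * wx) * iR7;
  }
}

static Tree* buildTree(const NumericMatrix& src, const NumericMatrix& wts,
                       int leaf_size) {
  Tree* tr = new Tree();
  tr->S = src.begin();
  tr->ns = src.nrow();
  tr->W = wts.begin();
  tr->nw = wts.ncol();
  tr->leaf_size = leaf_size;
  tr->perm.resize(tr->ns);
  for (int i = 0; i < tr->ns; ++i) tr->perm[i] = i;
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf},
         mx[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < tr->ns; ++i)
    for (int k = 0; k < 3; ++k) {
      mn[k] = std::min(mn[k], src(i, k));
      mx[k] = std::max(mx[k], src(i, k));
    }
  double half = 0.0;
  for (int k = 0; k < 3; ++k) half = std::max(half, (mx[k] - mn[k]) / 2.0);
  half = std::max(half, 1e-300);
  tr->nodes.reserve(tr->ns / leaf_size * 4 + 16);
  tr->build(0, tr->ns, (mn[0] + mx[0]) / 2.0, (mn[1] + mx[1]) / 2.0,
            (mn[2] + mx[2]) / 2.0, half);
  return tr;
}

// Treecode Coulomb field of scalar charges q at sources; exclude_id >= 0
// excludes that source index from the direct interactions (self term).
// [[Rcpp::export]]
NumericMatrix cpp_tree_field(NumericMatrix src, NumericVector q,
                             NumericMatrix pts, double theta,
                             bool exclude_self, int leaf_size = 48) {
  NumericMatrix W(src.nrow(), 1);
  for (int i = 0; i < src.nrow(); ++i) W(i, 0) = q[i];
  Tree* tr = buildTree(src, W, leaf_size);
  int np = pts.nrow();
  NumericMatrix out(np, 3);
  std::vector<int> stack;
  stack.reserve(256);
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double acc[3] = {0, 0, 0};
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      const TreeNode& nd = tr->nodes[id];
      double dx = p[0] - nd.center[0], dy = p[1] - nd.center[1],
             dz = p[2] - nd.center[2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!nd.leaf && nd.radius < theta * d) {
        double E[3];
        momentFieldGrad(nd, p, E);
        acc[0] += E[0]; acc[1] += E[1]; acc[2] += E[2];
      } else if (nd.leaf) {
        for (int t = nd.start; t < nd.end; ++t) {
          int j = tr->perm[t];
          double ex = p[0] - tr->sx(j), ey = p[1] - tr->sy(j),
                 ez = p[2] - tr->sz(j);
          double r2 = ex * ex + ey * ey + ez * ez;
          if (exclude_self && r2 < 1e-28) continue;
          double inv = 1.0 / std::sqrt(r2);
          double f = q[j] * inv * inv * inv;
          acc[0] += f * ex; acc[1] += f * ey; acc[2] += f * ez;
        }
      } else {
        for (int k = 0; k < 8; ++k)
          if (nd.child[k] >= 0) stack.push_back(nd.child[k]);
      }
    }
    out(i, 0) = INV4PI * acc[0];
    out(i, 1) = INV4PI * acc[1];
    out(i, 2) = INV4PI * acc[2];
  }
  delete tr;
  return out;
}

// Treecode 1/R sum with 3 weight channels (current-element moments).
// [[Rcpp::export]]
NumericMatrix cpp_tree_vecpot(NumericMatrix src, NumericMatrix mom,
                              NumericMatrix pts, double theta, double eps,
                              int leaf_size = 48) {
  Tree* tr = buildTree(src, mom, leaf_size);
  int np = pts.nrow();
  NumericMatrix out(np, 3);
  std::vector<int> stack;
  stack.reserve(256);
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double acc[3] = {0, 0, 0};
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      const TreeNode& nd = tr->nodes[id];
      double dx = p[0] - nd.center[0], dy = p[1] - nd.center[1],
             dz = p[2] - nd.center[2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!nd.leaf && nd.radius < theta * d) {
        double V[3];
        momentPotential(nd, p, 3, V);
        acc[0] += V[0]; acc[1] += V[1]; acc[2] += V[2];
      } else if (nd.leaf) {
        for (int t = nd.start; t < nd.end; ++t) {
          int j = tr->perm[t];
          double ex = p[0] - tr->sx(j), ey = p[1] - tr->sy(j),
                 ez = p[2] - tr->sz(j);
          double r = std::sqrt(ex * ex + ey * ey + ez * ez);
          if (r < eps) r = eps;
          double inv = 1.0 / r;
          acc[0] += mom(j, 0) * inv;
          acc[1] += mom(j, 1) * inv;
          acc[2] += mom(j, 2) * inv;
        }
      } else {
        for (int k = 0; k < 8; ++k)
          if (nd.child[k] >= 0) stack.push_back(nd.child[k]);
      }
    }
    out(i, 0) = acc[0]; out(i, 1) = acc[1]; out(i, 2) = acc[2];
  }
  delete tr;
  return out;
}
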