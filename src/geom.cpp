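// Geometric kernels: ray casting against the synthetic scene primitives
// (conical frusta, spheres, ground plane) and brute-force k-nearest-neighbor
// mean distances for the statistical outlier removal filter.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>

using namespace Rcpp;

namespace {

// Ray vs tapered cylinder (conical frustum) without end caps.
// Axis p0 -> p1, radii r0 at p0 and r1 at p1.  Returns smallest t > tmin
// with the hit between the end planes, or Inf.
double ray_frustum(const double* o, const double* v,
                   const double* p0, const double* p1,
                   double r0, double r1, double tmin) {
  double ax = p1[0]-p0[0], ay = p1[1]-p0[1], az = p1[2]-p0[2];
  double h2 = ax*ax + ay*ay + az*az;
  if (h2 <= 0) return R_PosInf;
  double h = std::sqrt(h2);
  ax /= h; ay /= h; az /= h;
  double wx = o[0]-p0[0], wy = o[1]-p0[1], wz = o[2]-p0[2];
  double wa = wx*ax + wy*ay + wz*az;
  double va = v[0]*ax + v[1]*ay + v[2]*az;
  double wpx = wx - wa*ax, wpy = wy - wa*ay, wpz = wz - wa*az;
  double vpx = v[0] - va*ax, vpy = v[1] - va*ay, vpz = v[2] - va*az;
  double s = (r1 - r0) / h;
  double A = vpx*vpx + vpy*vpy + vpz*vpz - s*s*va*va;
  double B = wpx*vpx + wpy*vpy + wpz*vpz - s*va*(r0 + s*wa);
  double C = wpx*wpx + wpy*wpy + wpz*wpz - (r0 + s*wa)*(r0 + s*wa);
  double best = R_PosInf;
  if (std::fabs(A) < 1e-14) {
    if (std::fabs(B) > 1e-14) {
      double t = -C / (2.0*B);
      double u = wa + t*va;
      if (t > tmin && u >= 0 && u <= h) best = t;
    }
    return best;
  }
  double disc = B*B - A*C;
  if (disc < 0) return R_PosInf;
  double sq = std::sqrt(disc);
  for (int k = 0; k < 2; k++) {
    double t = (k == 0) ? (-B - sq)/A : (-B + sq)/A;
    double u = wa + t*va;
    if (t > tmin && u >= 0 && u <= h && t < best) best = t;
  }
  return best;
}

double ray_sphere(const double* o, const double* v,
                  const double* c, double r, double tmin) {
  double wx = o[0]-c[0], wy = o[1]-c[1], wz = o[2]-c[2];
  double B = wx*v[0] + wy*v[1] + wz*v[2];
  double C = wx*wx + wy*wy + wz*wz - r*r;
  double disc = B*B - C;
  if (disc < 0) return R_PosInf;
  double sq = std::sqrt(disc);
  double t = -B - sq;
  if (t > tmin) return t;
  t = -B + sq;
  if (t > tmin) return t;
  return R_PosInf;
}

} // namespace

// origins, dirs: n x 3 (unit directions).  prim_type: 0 frustum, 1 sphere.
// prim_par: m x 8 = p0(xyz), p1(xyz), r0, r1 (spheres: p0 = center, r0 = radius).
// Returns n x 2: column 1 = range (Inf if no hit), column 2 = primitive index
// (1-based; 0 = ground).
// [[Rcpp::export(name = ".cast_rays_cpp")]]
NumericMatrix cast_rays_cpp(NumericMatrix origins, NumericMatrix dirs,
                            IntegerVector prim_type, NumericMatrix prim_par,
                            bool ground, double ground_z, double tmax) {
  const int n = origins.nrow(), m = prim_type.size();
  NumericMatrix res(n, 2);
  const double tmin = 1e-9;
  if (!R_finite(tmax) || tmax <= 0) tmax = R_PosInf;
  // per-primitive x-interval for a cheap reject (scan planes are nearly
  // perpendicular to the row axis, so most primitives are far in x)
  std::vector<double> pxlo(m), pxhi(m);
  for (int j = 0; j < m; j++) {
    double r = std::max(prim_par(j,6), prim_par(j,7));
    pxlo[j] = std::min(prim_par(j,0), prim_par(j,3)) - r;
    pxhi[j] = std::max(prim_par(j,0), prim_par(j,3)) + r;
  }
  for (int i = 0; i < n; i++) {
    double o[3] = { origins(i,0), origins(i,1), origins(i,2) };
    double v[3] = { dirs(i,0), dirs(i,1), dirs(i,2) };
    double best = R_PosInf;
    int hit = -1;
    double reach = (tmax < R_PosInf) ? tmax : 1e9;
    double rxlo = o[0] + std::min(0.0, v[0] * reach);
    double rxhi = o[0] + std::max(0.0, v[0] * reach);
    for (int j = 0; j < m; j++) {
      if (rxhi < pxlo[j] || rxlo > pxhi[j]) continue;
      double p0[3] = { prim_par(j,0), prim_par(j,1), prim_par(j,2) };
      double t;
      if (prim_type[j] == 1) {
        t = ray_sphere(o, v, p0, prim_par(j,6), tmin);
      } else {
        double p1[3] = { prim_par(j,3), prim_par(j,4), prim_par(j,5) };
        t = ray_frustum(o, v, p0, p1, prim_par(j,6), prim_par(j,7), tmin);
      }
      if (t < best) { best = t; hit = j + 1; }
    }
    if (ground && v[2] < -1e-12) {
      double t = (ground_z - o[2]) / v[2];
      if (t > tmin && t < best) { best = t; hit = 0; }
    }
    res(i, 0) = best;
    res(i, 1) = (best < R_PosInf) ? hit : NA_REAL;
    if ((i & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return res;
}

// Mean Euclidean distance from each point to its k nearest neighbors
// (excluding itself).  Brute force; exact.
// [[Rcpp::export(name = ".knn_mean_dist_cpp")]]
NumericVector knn_mean_dist_cpp(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  NumericVector out(n);
  std::vector<double> d2(n);
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; i++) { x[i]=pts(i,0); y[i]=pts(i,1); z[i]=pts(i,2); }
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < n; j++) {
      double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      d2[j] = dx*dx + dy*dy + dz*dz;
    }
    d2[i] = R_PosInf;  // exclude self
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    double far2 = d2[k-1];
    // recompute to sum the k smallest (nth_element reordered d2)
    double acc = 0; int cnt = 0;
    for (int j = 0; j < n && cnt < k; j++) {
      double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      double dd = dx*dx + dy*dy + dz*dz;
      if (j != i && dd <= far2) { acc += std::sqrt(dd); cnt++; }
    }
    out[i] = acc / (double)k;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Gabriel test: for each candidate edge (a,b), TRUE iff the open ball on
// diameter ab contains no other point.  Uniform-grid acceleration.
// [[Rcpp::export(name = ".gabriel_edges_cpp")]]
LogicalVector gabriel_edges_cpp(NumericMatrix pts, IntegerMatrix edges) {
  const int n = pts.nrow(), m = edges.nrow();
  LogicalVector res(m);
  if (n == 0 || m == 0) return res;
  double lo[3], hi[3];
  for (int d = 0; d < 3; d++) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++) {
      double v = pts(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  // cell size ~ average spacing times a few
  double ext = std::max(hi[0]-lo[0], std::max(hi[1]-lo[1], hi[2]-lo[2]));
  if (ext <= 0) ext = 1.0;
  double cell = ext / std::max(4.0, std::cbrt((double)n));
  int nc[3];
  for (int d = 0; d < 3; d++) {
    nc[d] = (int)std::floor((hi[d]-lo[d]) / cell) + 1;
    if (nc[d] < 1) nc[d] = 1;
  }
  auto cidx = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / cell);
    if (c < 0) c = 0;
    if (c >= nc[d]) c = nc[d]-1;
    return c;
  };
  std::vector<std::vector<int>> grid((size_t)nc[0]*nc[1]*nc[2]);
  for (int i = 0; i < n; i++) {
    int cx = cidx(pts(i,0),0), cy = cidx(pts(i,1),1), cz = cidx(pts(i,2),2);
    grid[((size_t)cx*nc[1]+cy)*nc[2]+cz].push_back(i);
  }
  for (int e = 0; e < m; e++) {
    int a = edges(e,0)-1, b = edges(e,1)-1;
    double c0 = 0.5*(pts(a,0)+pts(b,0)), c1 = 0.5*(pts(a,1)+pts(b,1)),
           c2 = 0.5*(pts(a,2)+pts(b,2));
    double dx = pts(a,0)-c0, dy = pts(a,1)-c1, dz = pts(a,2)-c2;
    double r2 = dx*dx+dy*dy+dz*dz;
    double r = std::sqrt(r2);
    int x0 = cidx(c0-r,0), x1 = cidx(c0+r,0);
    int y0 = cidx(c1-r,1), y1 = cidx(c1+r,1);
    int z0 = cidx(c2-r,2), z1 = cidx(c2+r,2);
    bool empty = true;
    for (int cx = x0; cx <= x1 && empty; cx++)
      for (int cy = y0; cy <= y1 && empty; cy++)
        for (int cz = z0; cz <= z1 && empty; cz++) {
          const std::vector<int>& cellv = grid[((size_t)cx*nc[1]+cy)*nc[2]+cz];
          for (int j : cellv) {
            if (j == a || j == b) continue;
            double ux = pts(j,0)-c0, uy = pts(j,1)-c1, uz = pts(j,2)-c2;
            if (ux*ux+uy*uy+uz*uz < r2 * (1.0 - 1e-12)) { empty = false; break; }
          }
        }
    res[e] = empty;
    if ((e & 8191) == 0) Rcpp::checkUserInterrupt();
  }
  return res;
}

// connected components over vertices 1..n given an edge list; returns the
// component id per vertex (1-based, arbitrary numbering)
// [[Rcpp::export(name = ".components_cpp")]]
IntegerVector components_cpp(int n, IntegerMatrix edges) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; i++) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  for (int e = 0; e < edges.nrow(); e++) {
    int a = find(edges(e,0)-1), b = find(edges(e,1)-1);
    if (a != b) parent[a] = b;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; i++) out[i] = find(i) + 1;
  return out;
}
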