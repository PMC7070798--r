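// Incremental 3D Delaunay tetrahedralization (Bowyer-Watson) with
// long-double geometric predicates and ghost tetrahedra over the convex
// hull (a symbolic vertex at infinity), so the finite part is the exact
// Delaunay tetrahedralization of the input.  Input points are jittered by a
// tiny seeded uniform offset before triangulation so that degenerate
// (cospherical or coplanar) configurations have measure zero; the jitter
// magnitude is far below the millimetre scale of LiDAR data.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;
typedef long double ld;

namespace {

struct Tet {
  int v[4];
  int nb[4];       // neighbor sharing the face opposite v[i]
  bool alive;
  std::uint32_t stamp;
};

struct Mesh {
  std::vector<std::array<ld,3>> P;  // real points
  std::array<ld,3> m;               // interior reference point
  std::vector<Tet> T;
  std::uint32_t stamp = 0;
  int n = 0;
  int INF = 0;                      // index of the symbolic infinite vertex

  ld orient(int a, int b, int c, int d) const {
    const std::array<ld,3> &A = P[a], &B = P[b], &C = P[c], &D = P[d];
    ld adx = A[0]-D[0], ady = A[1]-D[1], adz = A[2]-D[2];
    ld bdx = B[0]-D[0], bdy = B[1]-D[1], bdz = B[2]-D[2];
    ld cdx = C[0]-D[0], cdy = C[1]-D[1], cdz = C[2]-D[2];
    return adx*(bdy*cdz - bdz*cdy)
         - ady*(bdx*cdz - bdz*cdx)
         + adz*(bdx*cdy - bdy*cdx);
  }
  ld orient_m(int a, int b, int c) const {  // against the reference point
    const std::array<ld,3> &A = P[a], &B = P[b], &C = P[c];
    ld adx = A[0]-m[0], ady = A[1]-m[1], adz = A[2]-m[2];
    ld bdx = B[0]-m[0], bdy = B[1]-m[1], bdz = B[2]-m[2];
    ld cdx = C[0]-m[0], cdy = C[1]-m[1], cdz = C[2]-m[2];
    return adx*(bdy*cdz - bdz*cdy)
         - ady*(bdx*cdz - bdz*cdx)
         + adz*(bdx*cdy - bdy*cdx);
  }

  // > 0 iff e inside the circumsphere of positively oriented (a,b,c,d)
  ld insphere(int a, int b, int c, int d, int e) const {
    const std::array<ld,3> &A = P[a], &B = P[b], &C = P[c], &D = P[d],
                           &E = P[e];
    ld aex = A[0]-E[0], aey = A[1]-E[1], aez = A[2]-E[2];
    ld bex = B[0]-E[0], bey = B[1]-E[1], bez = B[2]-E[2];
    ld cex = C[0]-E[0], cey = C[1]-E[1], cez = C[2]-E[2];
    ld dex = D[0]-E[0], dey = D[1]-E[1], dez = D[2]-E[2];
    ld alift = aex*aex + aey*aey + aez*aez;
    ld blift = bex*bex + bey*bey + bez*bez;
    ld clift = cex*cex + cey*cey + cez*cez;
    ld dlift = dex*dex + dey*dey + dez*dez;
    ld ab = aex*bey - bex*aey, ac = aex*cey - cex*aey;
    ld ad = aex*dey - dex*aey, bc = bex*cey - cex*bey;
    ld bd = bex*dey - dex*bey, cd = cex*dey - dex*cey;
    ld abc = aez*bc - bez*ac + cez*ab;
    ld abd = aez*bd - bez*ad + dez*ab;
    ld acd = aez*cd - cez*ad + dez*ac;
    ld bcd = bez*cd - cez*bd + dez*bc;
    return dlift*abc - clift*abd + blift*acd - alift*bcd;
  }

  int inf_pos(const Tet& tt) const {
    for (int i = 0; i < 4; i++) if (tt.v[i] == INF) return i;
    return -1;
  }

  // Conflict ("p inside circumsphere") test.  For ghost tetrahedra the
  // circumsphere degenerates to the outer open half-space of the hull face.
  bool conflict(int t, int p) const {
    const Tet& tt = T[t];
    int j = inf_pos(tt);
    if (j < 0) {
      ld s = orient(tt.v[0], tt.v[1], tt.v[2], tt.v[3]);
      ld in = insphere(tt.v[0], tt.v[1], tt.v[2], tt.v[3], p);
      return (s >= 0) ? (in > 0) : (in < 0);
    }
    int f0 = tt.v[(j+1)&3], f1 = tt.v[(j+2)&3], f2 = tt.v[(j+3)&3];
    // creation enforces orient(f0,f1,f2, m) < 0, m interior
    return orient(f0, f1, f2, p) > 0;
  }

  bool contains_finite(int t, int p) const {
    const Tet& tt = T[t];
    for (int i = 0; i < 4; i++) {
      int f0 = tt.v[(i+1)&3], f1 = tt.v[(i+2)&3], f2 = tt.v[(i+3)&3];
      ld s = orient(f0, f1, f2, tt.v[i]);
      ld o = orient(f0, f1, f2, p);
      if ((s > 0 && o < 0) || (s < 0 && o > 0)) return false;
    }
    return true;
  }

  // returns a tetrahedron in conflict with p (or containing p)
  int locate(int start, int p) {
    int cur = start;
    for (int step = 0; step < 500000; ++step) {
      const Tet& tt = T[cur];
      int j = inf_pos(tt);
      if (j >= 0) {
        if (conflict(cur, p)) return cur;
        cur = tt.nb[j];   // re-enter the hull through the real face
        continue;
      }
      int next = -1;
      for (int ii = 0; ii < 4; ii++) {
        int i = (ii + step) & 3;
        int f0 = tt.v[(i+1)&3], f1 = tt.v[(i+2)&3], f2 = tt.v[(i+3)&3];
        ld s = orient(f0, f1, f2, tt.v[i]);
        ld o = orient(f0, f1, f2, p);
        if ((s > 0 && o < 0) || (s < 0 && o > 0)) { next = tt.nb[i]; break; }
      }
      if (next < 0) return cur;
      cur = next;
    }
    for (int t = (int)T.size() - 1; t >= 0; --t)
      if (T[t].alive && conflict(t, p)) return t;
    Rcpp::stop("delaunay3d: point location failed");
    return -1;
  }

  // create tetrahedron with v0 fixed in place; orient by swapping v2/v3
  // (finite) or the two non-v0 real face vertices (ghost)
  int make_tet(int a, int b, int c, int d) {
    Tet tt;
    tt.v[0] = a; tt.v[1] = b; tt.v[2] = c; tt.v[3] = d;
    tt.nb[0] = tt.nb[1] = tt.nb[2] = tt.nb[3] = -1;
    tt.alive = true;
    tt.stamp = 0;
    int j = -1;
    for (int i = 0; i < 4; i++) if (tt.v[i] == INF) j = i;
    if (j < 0) {
      if (orient(tt.v[0], tt.v[1], tt.v[2], tt.v[3]) < 0)
        std::swap(tt.v[2], tt.v[3]);
    } else {
      int f[3] = { tt.v[(j+1)&3], tt.v[(j+2)&3], tt.v[(j+3)&3] };
      if (orient_m(f[0], f[1], f[2]) > 0) {
        // swap two real vertices not in position 0
        int s1 = -1, s2 = -1;
        for (int i = 1; i < 4; i++)
          if (tt.v[i] != INF) { if (s1 < 0) s1 = i; else s2 = i; }
        std::swap(tt.v[s1], tt.v[s2]);
      }
    }
    T.push_back(tt);
    return (int)T.size() - 1;
  }

  void insert(int p, int& hint) {
    int loc = locate(hint, p);

    ++stamp;
    std::vector<int> cavity, queue_;
    queue_.push_back(loc);
    T[loc].stamp = stamp;
    while (!queue_.empty()) {
      int t = queue_.back(); queue_.pop_back();
      if (t != loc && !conflict(t, p)) continue;
      cavity.push_back(t);
      for (int i = 0; i < 4; i++) {
        int nb = T[t].nb[i];
        if (nb >= 0 && T[nb].stamp != stamp) {
          T[nb].stamp = stamp;
          queue_.push_back(nb);
        }
      }
    }

    std::uint32_t cav_stamp = ++stamp;
    for (int t : cavity) T[t].stamp = cav_stamp;

    struct BFace { int f[3]; int outside; int dead; };
    std::vector<BFace> bfaces;
    for (int t : cavity) {
      const Tet& tt = T[t];
      for (int i = 0; i < 4; i++) {
        int nb = tt.nb[i];
        if (nb >= 0 && T[nb].stamp == cav_stamp) continue;
        BFace bf;
        bf.f[0] = tt.v[(i+1)&3];
        bf.f[1] = tt.v[(i+2)&3];
        bf.f[2] = tt.v[(i+3)&3];
        bf.outside = nb;
        bf.dead = t;
        bfaces.push_back(bf);
      }
    }
    for (int t : cavity) T[t].alive = false;

    std::unordered_map<std::uint64_t, std::pair<int,int>> edge_map;
    edge_map.reserve(bfaces.size() * 3);
    int last = -1;
    for (const BFace& bf : bfaces) {
      int nt = make_tet(p, bf.f[0], bf.f[1], bf.f[2]);
      last = nt;
      Tet& ntt = T[nt];
      ntt.nb[0] = bf.outside;
      if (bf.outside >= 0) {
        Tet& ot = T[bf.outside];
        for (int j = 0; j < 4; j++)
          if (ot.nb[j] == bf.dead) { ot.nb[j] = nt; break; }
      }
      for (int k = 1; k < 4; k++) {
        int e0 = ntt.v[(k==1)?2:1];
        int e1 = ntt.v[(k==3)?2:3];
        std::uint64_t key = (e0 < e1)
          ? ((std::uint64_t)(std::uint32_t)e0 << 32) | (std::uint32_t)e1
          : ((std::uint64_t)(std::uint32_t)e1 << 32) | (std::uint32_t)e0;
        auto it = edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = std::make_pair(nt, k);
        } else {
          int ot = it->second.first, ok = it->second.second;
          ntt.nb[k] = ot;
          T[ot].nb[ok] = nt;
          edge_map.erase(it);
        }
      }
    }
    if (last >= 0) hint = last;
  }
};

inline std::uint64_t splitmix64(std::uint64_t& x) {
  x += 0x9e3779b97f4a7c15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
inline double runif01(std::uint64_t& s) {
  return (double)(splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
}

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix pts, double jitter, int seed) {
  const int n = pts.nrow();
  List empty = List::create(_["tetra"] = IntegerMatrix(0, 4),
                            _["volume"] = NumericVector(0),
                            _["circumradius"] = NumericVector(0),
                            _["degenerate"] = false);
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) return empty;

  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  double hi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++) {
      double v = pts(i, d);
      if (!R_finite(v)) stop("non-finite coordinate");
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double scale = 0.0;
  for (int d = 0; d < 3; d++) scale = std::max(scale, hi[d] - lo[d]);
  if (scale <= 0) scale = 1.0;

  Mesh M;
  M.n = n;
  M.INF = n;
  M.P.resize(n);
  std::uint64_t rs = (std::uint64_t)(std::uint32_t)seed * 0x100000001b3ULL
                   + 1442695040888963407ULL;
  const double jmag = jitter * scale;
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++)
      M.P[i][d] = (ld)pts(i, d) + (ld)((runif01(rs) - 0.5) * 2.0 * jmag);

  std::vector<int> order(n);
  for (int i = 0; i < n; i++) order[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(splitmix64(rs) % (std::uint64_t)(i + 1));
    std::swap(order[i], order[j]);
  }

  // move a strongly non-degenerate quadruple to the front
  const ld s3 = (ld)scale * scale * scale;
  {
    // distinct second point
    int k = 1;
    auto dist2 = [&](int a, int b) {
      ld dx = M.P[a][0]-M.P[b][0], dy = M.P[a][1]-M.P[b][1],
         dz = M.P[a][2]-M.P[b][2];
      return dx*dx + dy*dy + dz*dz;
    };
    while (k < n && dist2(order[0], order[k]) == 0) k++;
    if (k >= n) return empty;
    std::swap(order[1], order[k]);
    // non-collinear third
    k = 2;
    while (k < n) {
      int a = order[0], b = order[1], c = order[k];
      ld ux = M.P[b][0]-M.P[a][0], uy = M.P[b][1]-M.P[a][1],
         uz = M.P[b][2]-M.P[a][2];
      ld vx = M.P[c][0]-M.P[a][0], vy = M.P[c][1]-M.P[a][1],
         vz = M.P[c][2]-M.P[a][2];
      ld cx = uy*vz - uz*vy, cy = uz*vx - ux*vz, cz = ux*vy - uy*vx;
      if (cx*cx + cy*cy + cz*cz > 0) break;
      k++;
    }
    if (k >= n) return empty;
    std::swap(order[2], order[k]);
    // non-coplanar fourth
    k = 3;
    while (k < n) {
      ld o = M.orient(order[0], order[1], order[2], order[k]);
      if (std::fabs((double)(o / s3)) > 1e-14) break;
      k++;
    }
    if (k >= n) {
      warning("delaunay3d: input points are (nearly) coplanar; empty complex");
      return empty;
    }
    std::swap(order[3], order[k]);
  }

  for (int d = 0; d < 3; d++)
    M.m[d] = (M.P[order[0]][d] + M.P[order[1]][d] +
              M.P[order[2]][d] + M.P[order[3]][d]) / (ld)4.0;

  M.T.reserve((size_t)n * 8 + 16);
  int t0 = M.make_tet(order[0], order[1], order[2], order[3]);
  {
    // four ghost tetrahedra, linked to t0 and to each other
    std::unordered_map<std::uint64_t, std::pair<int,int>> emap;
    for (int i = 0; i < 4; i++) {
      const Tet t0c = M.T[t0];
      int f0 = t0c.v[(i+1)&3], f1 = t0c.v[(i+2)&3], f2 = t0c.v[(i+3)&3];
      int g = M.make_tet(M.INF, f0, f1, f2);
      M.T[g].nb[0] = t0;
      M.T[t0].nb[i] = g;
      Tet& gt = M.T[g];
      for (int k = 1; k < 4; k++) {
        int e0 = gt.v[(k==1)?2:1];
        int e1 = gt.v[(k==3)?2:3];
        std::uint64_t key = (e0 < e1)
          ? ((std::uint64_t)(std::uint32_t)e0 << 32) | (std::uint32_t)e1
          : ((std::uint64_t)(std::uint32_t)e1 << 32) | (std::uint32_t)e0;
        auto it = emap.find(key);
        if (it == emap.end()) emap[key] = std::make_pair(g, k);
        else {
          M.T[g].nb[k] = it->second.first;
          M.T[it->second.first].nb[it->second.second] = g;
        }
      }
    }
  }

  int hint = t0;
  for (int i = 4; i < n; i++) {
    M.insert(order[i], hint);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<std::array<int,4>> out;
  out.reserve(M.T.size());
  for (const Tet& tt : M.T) {
    if (!tt.alive) continue;
    if (tt.v[0] == M.INF || tt.v[1] == M.INF ||
        tt.v[2] == M.INF || tt.v[3] == M.INF) continue;
    out.push_back({ tt.v[0], tt.v[1], tt.v[2], tt.v[3] });
  }
  const int mtet = (int)out.size();
  IntegerMatrix tetra(mtet, 4);
  NumericVector vol(mtet), crad(mtet);
  for (int t = 0; t < mtet; t++) {
    const std::array<int,4>& q = out[t];
    double A[3][3];
    const std::array<ld,3>& p0 = M.P[q[0]];
    for (int r = 0; r < 3; r++)
      for (int d = 0; d < 3; d++)
        A[r][d] = (double)(M.P[q[r+1]][d] - p0[d]);
    double det = A[0][0]*(A[1][1]*A[2][2] - A[1][2]*A[2][1])
               - A[0][1]*(A[1][0]*A[2][2] - A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*A[2][1] - A[1][1]*A[2][0]);
    vol[t] = std::fabs(det) / 6.0;
    double b[3];
    for (int r = 0; r < 3; r++)
      b[r] = 0.5 * (A[r][0]*A[r][0] + A[r][1]*A[r][1] + A[r][2]*A[r][2]);
    if (det == 0) crad[t] = R_PosInf;
    else {
      double x[3];
      for (int c = 0; c < 3; c++) {
        double Ac[3][3];
        for (int r = 0; r < 3; r++)
          for (int d = 0; d < 3; d++)
            Ac[r][d] = (c == d) ? b[r] : A[r][d];
        double dc = Ac[0][0]*(Ac[1][1]*Ac[2][2] - Ac[1][2]*Ac[2][1])
                  - Ac[0][1]*(Ac[1][0]*Ac[2][2] - Ac[1][2]*Ac[2][0])
                  + Ac[0][2]*(Ac[1][0]*Ac[2][1] - Ac[1][1]*Ac[2][0]);
        x[c] = dc / det;
      }
      crad[t] = std::sqrt(x[0]*x[0] + x[1]*x[1] + x[2]*x[2]);
    }
    for (int c = 0; c < 4; c++) tetra(t, c) = q[c] + 1;
  }
  return List::create(_["tetra"] = tetra,
                      _["volume"] = vol,
                      _["circumradius"] = crad,
                      _["degenerate"] = false);
}

// Brute-force point-in-retained-complex test, used by the Monte-Carlo volume
// oracle in the test suite (independent of the volume-summation path).
// [[Rcpp::export(name = ".points_in_tets_cpp")]]
LogicalVector points_in_tets_cpp(NumericMatrix pts, IntegerMatrix tetra,
                                 NumericMatrix queries) {
  const int m = tetra.nrow(), q = queries.nrow();
  std::vector<std::array<double,3>> lo(m), hi(m);
  for (int t = 0; t < m; t++) {
    for (int d = 0; d < 3; d++) { lo[t][d] = R_PosInf; hi[t][d] = R_NegInf; }
    for (int c = 0; c < 4; c++) {
      int v = tetra(t, c) - 1;
      for (int d = 0; d < 3; d++) {
        double x = pts(v, d);
        if (x < lo[t][d]) lo[t][d] = x;
        if (x > hi[t][d]) hi[t][d] = x;
      }
    }
  }
  auto orient = [&](const double* a, const double* b, const double* c,
                    const double* d) {
    double adx=a[0]-d[0], ady=a[1]-d[1], adz=a[2]-d[2];
    double bdx=b[0]-d[0], bdy=b[1]-d[1], bdz=b[2]-d[2];
    double cdx=c[0]-d[0], cdy=c[1]-d[1], cdz=c[2]-d[2];
    return adx*(bdy*cdz-bdz*cdy) - ady*(bdx*cdz-bdz*cdx) + adz*(bdx*cdy-bdy*cdx);
  };
  LogicalVector res(q);
  for (int i = 0; i < q; i++) {
    double Pq[3] = { queries(i,0), queries(i,1), queries(i,2) };
    bool inside = false;
    for (int t = 0; t < m && !inside; t++) {
      if (Pq[0] < lo[t][0] || Pq[0] > hi[t][0] ||
          Pq[1] < lo[t][1] || Pq[1] > hi[t][1] ||
          Pq[2] < lo[t][2] || Pq[2] > hi[t][2]) continue;
      double V[4][3];
      for (int c = 0; c < 4; c++) {
        int v = tetra(t, c) - 1;
        for (int d = 0; d < 3; d++) V[c][d] = pts(v, d);
      }
      double s = orient(V[0], V[1], V[2], V[3]);
      if (s == 0) continue;
      double o0 = orient(Pq,   V[1], V[2], V[3]);
      double o1 = orient(V[0], Pq,   V[2], V[3]);
      double o2 = orient(V[0], V[1], Pq,   V[3]);
      double o3 = orient(V[0], V[1], V[2], Pq);
      if (s > 0) inside = (o0 >= 0 && o1 >= 0 && o2 >= 0 && o3 >= 0);
      else       inside = (o0 <= 0 && o1 <= 0 && o2 <= 0 && o3 <= 0);
    }
    res[i] = inside;
  }
  return res;
}
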