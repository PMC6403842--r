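// Knot-identification geometry: topology-preserving polygon simplification
// (KMT-style vertex deletion guarded by triangle tests), projection of a
// closed 3D polygon to a planar crossing diagram with Gauss code,
// Reidemeister R1/R2 diagram reduction, Alexander polynomial of a diagram by
// exact fraction-free (Bareiss) elimination over integer nodes followed by
// interpolation, and signed inter-curve crossing counts (Gauss linking
// number).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>

using namespace Rcpp;

namespace {

inline uint64_t mix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  double unif() { return (static_cast<double>(mix64(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  int pick(int n) { return static_cast<int>(mix64(s) % static_cast<uint64_t>(n)); }
};

struct V3 { double x, y, z; };
inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

inline V3 vscale(V3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }

// Does the (slightly endpoint-shrunk) segment p0-p1 pass through the interior
// of triangle abc?  Segment endpoints are retracted by a small fraction so
// that segments sharing a vertex with the triangle do not register a hit from
// the shared corner alone; true mid-triangle punctures still do.  Boundary
// (edge) contacts away from corners count as hits, which keeps the test
// conservative for the topology-preservation guarantee.
bool seg_hits_tri(V3 p0, V3 p1, V3 a, V3 b, V3 c) {
  V3 e1 = b - a, e2 = c - a;
  V3 n = cross(e1, e2);
  double nn = norm(n);
  if (nn < 1e-14) return false;  // degenerate (zero-area) triangle
  n = vscale(n, 1.0 / nn);
  V3 dir = p1 - p0;
  double L = norm(dir);
  if (L < 1e-12) return false;
  const double shrink = 1e-6;
  V3 q0 = p0 + vscale(dir, shrink), q1 = p1 + vscale(dir, -shrink);
  double scale = norm(e1) + norm(e2);
  double tolp = 1e-9 * scale;
  double d0 = dot(q0 - a, n), d1 = dot(q1 - a, n);
  if (d0 > tolp && d1 > tolp) return false;
  if (d0 < -tolp && d1 < -tolp) return false;

  // 2D frame in the triangle plane
  V3 u2 = vscale(e1, 1.0 / norm(e1));
  V3 v2 = cross(n, u2);
  auto to2d = [&](V3 p, double &x, double &y) {
    x = dot(p - a, u2); y = dot(p - a, v2);
  };
  double ax = 0, ay = 0, bx2, by2, cx2, cy2;
  to2d(b, bx2, by2); to2d(c, cx2, cy2);
  auto bary = [&](double px, double py, double &l1, double &l2, double &l3) {
    double den = (by2 - cy2) * (ax - cx2) + (cx2 - bx2) * (ay - cy2);
    l1 = ((by2 - cy2) * (px - cx2) + (cx2 - bx2) * (py - cy2)) / den;
    l2 = ((cy2 - ay) * (px - cx2) + (ax - cx2) * (py - cy2)) / den;
    l3 = 1.0 - l1 - l2;
  };

  if (std::fabs(d0) <= tolp && std::fabs(d1) <= tolp) {
    // coplanar: hit if an endpoint lies strictly inside, or the segment
    // properly crosses a triangle edge away from the corners
    double sx0, sy0, sx1, sy1;
    to2d(q0, sx0, sy0); to2d(q1, sx1, sy1);
    double l1, l2, l3;
    bary(sx0, sy0, l1, l2, l3);
    if (l1 > 1e-9 && l2 > 1e-9 && l3 > 1e-9) return true;
    bary(sx1, sy1, l1, l2, l3);
    if (l1 > 1e-9 && l2 > 1e-9 && l3 > 1e-9) return true;
    double ex[3] = {ax, bx2, cx2}, ey[3] = {ay, by2, cy2};
    for (int e = 0; e < 3; ++e) {
      double x0 = ex[e], y0 = ey[e], x1 = ex[(e + 1) % 3], y1 = ey[(e + 1) % 3];
      double rx = sx1 - sx0, ry = sy1 - sy0;
      double sxe = x1 - x0, sye = y1 - y0;
      double den = rx * sye - ry * sxe;
      if (std::fabs(den) < 1e-14) continue;
      double t = ((x0 - sx0) * sye - (y0 - sy0) * sxe) / den;
      double w = ((x0 - sx0) * ry - (y0 - sy0) * rx) / den;
      if (t > 1e-9 && t < 1 - 1e-9 && w > 1e-6 && w < 1 - 1e-6) return true;
    }
    return false;
  }

  // transversal: intersection point with the plane, then barycentric test
  double t = d0 / (d0 - d1);
  if (t < 0.0 || t > 1.0) return false;
  V3 q = q0 + vscale(q1 - q0, t);
  double qx, qy, l1, l2, l3;
  to2d(q, qx, qy);
  bary(qx, qy, l1, l2, l3);
  double mx = std::max(l1, std::max(l2, l3));
  if (mx > 1.0 - 1e-6) return false;  // corner touch (shared vertex)
  return l1 > -1e-9 && l2 > -1e-9 && l3 > -1e-9;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_simplify_curve(NumericMatrix verts, double seed, int min_keep) {
  int n0 = verts.nrow();
  std::vector<V3> P(n0);
  for (int i = 0; i < n0; ++i) P[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
  std::vector<int> alive(n0);
  for (int i = 0; i < n0; ++i) alive[i] = i;
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 88172645463325252ULL);
  if (min_keep < 3) min_keep = 3;

  bool changed = true;
  while (changed && static_cast<int>(alive.size()) > min_keep) {
    changed = false;
    int n = alive.size();
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.pick(i + 1)]);
    for (int oi = 0; oi < static_cast<int>(order.size()); ++oi) {
      int n_cur = alive.size();
      if (n_cur <= min_keep) break;
      int k = order[oi];
      if (k >= n_cur) continue;
      int kp = (k - 1 + n_cur) % n_cur, kn = (k + 1) % n_cur;
      V3 a = P[alive[kp]], b = P[alive[k]], c = P[alive[kn]];
      V3 nvec = cross(b - a, c - a);
      bool blocked = false;
      if (norm(nvec) > 1e-14) {
        for (int s = 0; s < n_cur && !blocked; ++s) {
          // skip only the two segments incident to the removed vertex; the
          // segments sharing a corner with the triangle are handled by the
          // endpoint-shrinking in seg_hits_tri
          if (s == k || s == kp) continue;
          int sn = (s + 1) % n_cur;
          if (seg_hits_tri(P[alive[s]], P[alive[sn]], a, b, c)) blocked = true;
        }
      }
      if (!blocked) {
        alive.erase(alive.begin() + k);
        changed = true;
        // indices in `order` referring to positions > k shift down by one
        for (int &o : order) if (o > k) --o;
      }
    }
  }

  NumericMatrix out(alive.size(), 3);
  for (size_t i = 0; i < alive.size(); ++i) {
    out(i, 0) = P[alive[i]].x; out(i, 1) = P[alive[i]].y; out(i, 2) = P[alive[i]].z;
  }
  return out;
}

namespace {

struct Crossing { int seg_over, seg_under, sign; };

// Project a closed polygon along `w` and enumerate transversal crossings.
// Returns false on a degenerate (non-generic) projection.
bool project_gauss(const std::vector<V3> &P, V3 w,
                   std::vector<std::array<int, 3>> &gauss,
                   std::vector<Crossing> &crossings) {
  int n = P.size();
  double wn = norm(w);
  w = {w.x / wn, w.y / wn, w.z / wn};
  V3 any = std::fabs(w.x) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
  V3 u = cross(w, any);
  double un = norm(u);
  u = {u.x / un, u.y / un, u.z / un};
  V3 v = cross(w, u);
  std::vector<double> px(n), py(n), pd(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    px[i] = dot(P[i], u); py[i] = dot(P[i], v); pd[i] = dot(P[i], w);
    scale = std::max(scale, std::fabs(px[i]) + std::fabs(py[i]));
  }
  const double eps = 1e-9 * (scale > 0 ? scale : 1.0);
  const double teps = 1e-7;

  struct Ev { double t; int id; };
  std::vector<std::vector<Ev>> events(n);
  crossings.clear();
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (i == j || i2 == j || i == j2) continue;
      double rx = px[i2] - px[i], ry = py[i2] - py[i];
      double sx = px[j2] - px[j], sy = py[j2] - py[j];
      double den = rx * sy - ry * sx;
      double qpx = px[j] - px[i], qpy = py[j] - py[i];
      if (std::fabs(den) < 1e-12 * (std::fabs(rx) + std::fabs(ry)) *
                               (std::fabs(sx) + std::fabs(sy)) + 1e-300) {
        // parallel in projection: degenerate only if overlapping
        double c2 = qpx * ry - qpy * rx;
        if (std::fabs(c2) < eps) {
          double rr = rx * rx + ry * ry;
          double t0 = (qpx * rx + qpy * ry) / rr;
          double t1 = t0 + (sx * rx + sy * ry) / rr;
          if (std::max(std::min(t0, t1), 0.0) <= std::min(std::max(t0, t1), 1.0))
            return false;
        }
        continue;
      }
      double t = (qpx * sy - qpy * sx) / den;
      double s = (qpx * ry - qpy * rx) / den;
      if (t <= -teps || t >= 1 + teps || s <= -teps || s >= 1 + teps) continue;
      if (t < teps || t > 1 - teps || s < teps || s > 1 - teps) return false;
      double di = pd[i] + t * (pd[(i + 1) % n] - pd[i]);
      double dj = pd[j] + s * (pd[j2] - pd[j]);
      if (std::fabs(di - dj) < eps) return false;
      int id = crossings.size();
      int sign = (rx * sy - ry * sx) > 0 ? 1 : -1;  // sign of cross(r, s)
      Crossing cr;
      if (di > dj) { cr.seg_over = i; cr.seg_under = j; }
      else { cr.seg_over = j; cr.seg_under = i; }
      // crossing sign from (over direction) x (under direction)
      cr.sign = (di > dj) ? sign : -sign;
      crossings.push_back(cr);
      events[i].push_back({t, id});
      events[j].push_back({s, id});
    }
  }
  gauss.clear();
  for (int i = 0; i < n; ++i) {
    std::sort(events[i].begin(), events[i].end(),
              [](const Ev &a, const Ev &b) { return a.t < b.t; });
    for (size_t k = 0; k + 1 < events[i].size(); ++k)
      if (events[i][k + 1].t - events[i][k].t < teps) return false;
    for (const Ev &e : events[i]) {
      int over = crossings[e.id].seg_over == i ? 1 : 0;
      gauss.push_back({e.id, over, crossings[e.id].sign});
    }
  }
  return true;
}

// Reidemeister R1 and R2 reduction on a signed Gauss sequence.
void reduce_gauss(std::vector<std::array<int, 3>> &g) {
  bool changed = true;
  while (changed && !g.empty()) {
    changed = false;
    int m = g.size();
    // R1: the two passes of one crossing are cyclically adjacent
    for (int p = 0; p < m; ++p) {
      int q = (p + 1) % m;
      if (g[p][0] == g[q][0]) {
        int id = g[p][0];
        std::vector<std::array<int, 3>> ng;
        for (auto &e : g) if (e[0] != id) ng.push_back(e);
        g.swap(ng);
        changed = true;
        break;
      }
    }
    if (changed) continue;
    // R2: strand passes over (or under) two crossings consecutively while the
    // partner strand meets the same two crossings consecutively on the other
    // level
    m = g.size();
    for (int p = 0; p < m && !changed; ++p) {
      int p2 = (p + 1) % m;
      if (g[p][1] != g[p2][1]) continue;
      int a = g[p][0], b = g[p2][0];
      if (a == b) continue;
      for (int q = 0; q < m && !changed; ++q) {
        int q2 = (q + 1) % m;
        if (q == p || q2 == p || q == p2) continue;
        if (g[q][1] != g[q2][1] || g[q][1] == g[p][1]) continue;
        int c = g[q][0], d = g[q2][0];
        if ((c == a && d == b) || (c == b && d == a)) {
          std::vector<std::array<int, 3>> ng;
          for (auto &e : g) if (e[0] != a && e[0] != b) ng.push_back(e);
          g.swap(ng);
          changed = true;
        }
      }
    }
  }
}

typedef __int128 bigint;

// Exact determinant of an integer matrix (Bareiss). Returns false on overflow.
bool bareiss_det(std::vector<std::vector<bigint>> M, bigint &det) {
  int n = M.size();
  if (n == 0) { det = 1; return true; }
  const bigint LIM = (bigint)1 << 120;
  bigint prev = 1;
  int sign = 1;
  for (int k = 0; k < n - 1; ++k) {
    if (M[k][k] == 0) {
      int piv = -1;
      for (int r = k + 1; r < n; ++r) if (M[r][k] != 0) { piv = r; break; }
      if (piv < 0) { det = 0; return true; }
      std::swap(M[k], M[piv]);
      sign = -sign;
    }
    for (int i = k + 1; i < n; ++i)
      for (int j = k + 1; j < n; ++j) {
        bigint num = M[i][j] * M[k][k] - M[i][k] * M[k][j];
        if (num > LIM || -num > LIM) return false;
        M[i][j] = num / prev;
      }
    prev = M[k][k];
  }
  det = sign * M[n - 1][n - 1];
  return true;
}

// Long-double LU determinant (fallback for large diagrams; magnitude only).
double lu_det(std::vector<std::vector<long double>> M) {
  int n = M.size();
  if (n == 0) return 1.0;
  long double det = 1.0;
  for (int k = 0; k < n; ++k) {
    int piv = k;
    for (int r = k + 1; r < n; ++r)
      if (std::fabs((double)M[r][k]) > std::fabs((double)M[piv][k])) piv = r;
    if (M[piv][k] == 0.0L) return 0.0;
    if (piv != k) { std::swap(M[piv], M[k]); det = -det; }
    det *= M[k][k];
    for (int r = k + 1; r < n; ++r) {
      long double f = M[r][k] / M[k][k];
      for (int c = k; c < n; ++c) M[r][c] -= f * M[k][c];
    }
  }
  return (double)det;
}

// Build the Alexander (Wirtinger/Fox) presentation matrix from a reduced
// signed Gauss sequence; entries are degree-<=1 integer polynomials
// (constant, linear) stored as pairs.
void alexander_matrix(const std::vector<std::array<int, 3>> &g, int c,
                      std::vector<std::vector<std::array<long, 2>>> &M) {
  int m2 = g.size();  // == 2c
  // arcs: an arc ends at each under-pass; label positions
  std::vector<int> arc_at(m2);
  int arc = 0;
  for (int p = 0; p < m2; ++p) {
    arc_at[p] = arc;
    if (g[p][1] == 0) ++arc;  // under-pass terminates the arc
  }
  // positions before the first under-pass belong to the last arc
  for (int p = 0; p < m2 && g[p][1] != 0; ++p) arc_at[p] = 0;
  // re-walk so that labels are 0..c-1 cyclically: shift labels mod c
  for (int p = 0; p < m2; ++p) arc_at[p] %= c;

  M.assign(c, std::vector<std::array<long, 2>>(c, {0, 0}));
  std::vector<int> over_arc(c, -1), in_arc(c, -1), out_arc(c, -1), csign(c, 0);
  for (int p = 0; p < m2; ++p) {
    int id = g[p][0];
    if (g[p][1] == 1) over_arc[id] = arc_at[p];
    else { in_arc[id] = arc_at[p]; out_arc[id] = (arc_at[p] + 1) % c; csign[id] = g[p][2]; }
  }
  for (int k = 0; k < c; ++k) {
    int o = over_arc[k], i = in_arc[k], j = out_arc[k];
    if (csign[k] > 0) {
      // row: o gets (1 - t), i gets t, j gets -1
      M[k][o][0] += 1; M[k][o][1] -= 1;
      M[k][i][1] += 1;
      M[k][j][0] -= 1;
    } else {
      // row: o gets (t - 1), i gets 1, j gets -t
      M[k][o][0] -= 1; M[k][o][1] += 1;
      M[k][i][0] += 1;
      M[k][j][1] -= 1;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_project_diagram(NumericMatrix verts, NumericVector direction, bool reduce) {
  int n = verts.nrow();
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
  V3 w = {direction[0], direction[1], direction[2]};
  std::vector<std::array<int, 3>> gauss;
  std::vector<Crossing> crossings;
  bool ok = project_gauss(P, w, gauss, crossings);
  if (!ok) return List::create(_["ok"] = false);
  IntegerMatrix cr(crossings.size(), 3);
  for (size_t k = 0; k < crossings.size(); ++k) {
    cr(k, 0) = crossings[k].seg_over + 1;
    cr(k, 1) = crossings[k].seg_under + 1;
    cr(k, 2) = crossings[k].sign;
  }
  if (reduce) reduce_gauss(gauss);
  IntegerMatrix gm(gauss.size(), 3);
  for (size_t k = 0; k < gauss.size(); ++k) {
    gm(k, 0) = gauss[k][0] + 1; gm(k, 1) = gauss[k][1]; gm(k, 2) = gauss[k][2];
  }
  return List::create(_["ok"] = true, _["raw_crossings"] = cr,
                      _["gauss"] = gm,
                      _["n_crossings"] = (int)(gauss.size() / 2));
}

// [[Rcpp::export]]
List cpp_alexander_from_gauss(IntegerMatrix gauss) {
  std::vector<std::array<int, 3>> g(gauss.nrow());
  for (int p = 0; p < gauss.nrow(); ++p)
    g[p] = {gauss(p, 0) - 1, gauss(p, 1), gauss(p, 2)};
  // renumber crossing ids densely
  std::vector<int> ids;
  for (auto &e : g) ids.push_back(e[0]);
  std::sort(ids.begin(), ids.end());
  ids.erase(std::unique(ids.begin(), ids.end()), ids.end());
  for (auto &e : g)
    e[0] = std::lower_bound(ids.begin(), ids.end(), e[0]) - ids.begin();
  int c = ids.size();
  if (c == 0)
    return List::create(_["coeffs"] = IntegerVector::create(1),
                        _["determinant"] = 1.0, _["exact"] = true);

  std::vector<std::vector<std::array<long, 2>>> M;
  alexander_matrix(g, c, M);
  int m = c - 1;  // delete last row and last column

  auto eval_at = [&](long t, bigint &det) -> bool {
    std::vector<std::vector<bigint>> A(m, std::vector<bigint>(m));
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j)
        A[i][j] = (bigint)M[i][j][0] + (bigint)M[i][j][1] * t;
    return bareiss_det(A, det);
  };

  if (m <= 20) {
    // determinant polynomial has degree <= m: interpolate on m+1 nodes
    int nn = m + 1;
    std::vector<long> nodes(nn);
    for (int k = 0; k < nn; ++k) nodes[k] = k - nn / 2;
    std::vector<long double> vals(nn);
    bool exact = true;
    for (int k = 0; k < nn && exact; ++k) {
      bigint d;
      if (!eval_at(nodes[k], d)) { exact = false; break; }
      vals[k] = (long double)d;
    }
    if (exact) {
      // Lagrange interpolation to monomial coefficients
      std::vector<long double> coef(nn, 0.0L);
      for (int k = 0; k < nn; ++k) {
        std::vector<long double> basis(1, 1.0L);
        long double denom = 1.0L;
        for (int j = 0; j < nn; ++j) {
          if (j == k) continue;
          denom *= (long double)(nodes[k] - nodes[j]);
          std::vector<long double> nb(basis.size() + 1, 0.0L);
          for (size_t d0 = 0; d0 < basis.size(); ++d0) {
            nb[d0] += basis[d0] * (long double)(-nodes[j]);
            nb[d0 + 1] += basis[d0];
          }
          basis.swap(nb);
        }
        for (size_t d0 = 0; d0 < basis.size(); ++d0)
          coef[d0] += vals[k] * basis[d0] / denom;
      }
      std::vector<long long> ic(nn);
      for (int d0 = 0; d0 < nn; ++d0) ic[d0] = llroundl(coef[d0]);
      // normalise: strip t^k, positive lowest-degree coefficient
      int lo = 0, hi = nn - 1;
      while (lo < nn && ic[lo] == 0) ++lo;
      while (hi >= 0 && ic[hi] == 0) --hi;
      if (lo > hi) { lo = 0; hi = 0; ic[0] = 0; }
      std::vector<long long> out(ic.begin() + lo, ic.begin() + hi + 1);
      if (out.front() < 0) for (auto &v : out) v = -v;
      long long det1 = 0;
      long long p = 1;
      for (size_t d0 = 0; d0 < out.size(); ++d0) { det1 += out[d0] * p; p = -p; }
      IntegerVector rc(out.size());
      for (size_t d0 = 0; d0 < out.size(); ++d0) rc[d0] = (int)out[d0];
      return List::create(_["coeffs"] = rc,
                          _["determinant"] = (double)std::llabs(det1),
                          _["exact"] = true);
    }
  }
  // large diagram: report |Delta(-1)| only (long double LU)
  std::vector<std::vector<long double>> A(m, std::vector<long double>(m));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      A[i][j] = (long double)M[i][j][0] - (long double)M[i][j][1];
  double det = std::fabs(lu_det(A));
  return List::create(_["coeffs"] = IntegerVector(0),
                      _["determinant"] = std::round(det), _["exact"] = false);
}

// Signed crossings between two disjoint closed curves in a projection;
// the Gauss linking number is half the signed sum.
// [[Rcpp::export]]
List cpp_link_crossings(NumericMatrix va, NumericMatrix vb, NumericVector direction) {
  int na = va.nrow(), nb = vb.nrow();
  V3 w = {direction[0], direction[1], direction[2]};
  double wn = norm(w);
  w = {w.x / wn, w.y / wn, w.z / wn};
  V3 any = std::fabs(w.x) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
  V3 u = cross(w, any);
  double un = norm(u);
  u = {u.x / un, u.y / un, u.z / un};
  V3 v = cross(w, u);
  std::vector<double> ax(na), ay(na), ad(na), bx(nb), by(nb), bd(nb);
  double scale = 0.0;
  for (int i = 0; i < na; ++i) {
    V3 p = {va(i, 0), va(i, 1), va(i, 2)};
    ax[i] = dot(p, u); ay[i] = dot(p, v); ad[i] = dot(p, w);
    scale = std::max(scale, std::fabs(ax[i]) + std::fabs(ay[i]));
  }
  for (int i = 0; i < nb; ++i) {
    V3 p = {vb(i, 0), vb(i, 1), vb(i, 2)};
    bx[i] = dot(p, u); by[i] = dot(p, v); bd[i] = dot(p, w);
    scale = std::max(scale, std::fabs(bx[i]) + std::fabs(by[i]));
  }
  const double eps = 1e-9 * (scale > 0 ? scale : 1.0);
  const double teps = 1e-7;
  long sum = 0;
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    double rx = ax[i2] - ax[i], ry = ay[i2] - ay[i];
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      double sx = bx[j2] - bx[j], sy = by[j2] - by[j];
      double den = rx * sy - ry * sx;
      double qpx = bx[j] - ax[i], qpy = by[j] - ay[i];
      if (std::fabs(den) < 1e-14 + 1e-12 * (std::fabs(rx) + std::fabs(ry)) *
                                        (std::fabs(sx) + std::fabs(sy)))
        continue;
      double t = (qpx * sy - qpy * sx) / den;
      double s = (qpx * ry - qpy * rx) / den;
      if (t <= -teps || t >= 1 + teps || s <= -teps || s >= 1 + teps) continue;
      if (t < teps || t > 1 - teps || s < teps || s > 1 - teps)
        return List::create(_["ok"] = false);
      double di = ad[i] + t * (ad[i2] - ad[i]);
      double dj = bd[j] + s * (bd[j2] - bd[j]);
      if (std::fabs(di - dj) < eps) return List::create(_["ok"] = false);
      int sgn = den > 0 ? 1 : -1;         // sign of cross(r, s)
      if (di < dj) sgn = -sgn;            // orient by the over strand
      sum += sgn;
    }
  }
  return List::create(_["ok"] = true, _["signed_sum"] = (double)sum);
}

// Count transversal passages of a closed polyline through the disc spanned by
// a small ring polygon (fan triangulation about the ring centroid). Used to
// verify that a cohesin ring remains threaded on the chromatin fibre.
// [[Rcpp::export]]
List cpp_pierce_count(NumericMatrix ring, NumericMatrix chain, bool chain_closed) {
  int nr = ring.nrow(), nc = chain.nrow();
  std::vector<V3> R(nr), C(nc);
  for (int i = 0; i < nr; ++i) R[i] = {ring(i, 0), ring(i, 1), ring(i, 2)};
  for (int i = 0; i < nc; ++i) C[i] = {chain(i, 0), chain(i, 1), chain(i, 2)};
  V3 cen = {0, 0, 0};
  for (auto &p : R) { cen.x += p.x / nr; cen.y += p.y / nr; cen.z += p.z / nr; }
  int count = 0;
  long signed_count = 0;
  int nseg = chain_closed ? nc : nc - 1;
  for (int s = 0; s < nseg; ++s) {
    V3 p0 = C[s], p1 = C[(s + 1) % nc];
    V3 d = p1 - p0;
    for (int k = 0; k < nr; ++k) {
      V3 a = cen, b = R[k], c = R[(k + 1) % nr];
      V3 e1 = b - a, e2 = c - a;
      V3 h = cross(d, e2);
      double det = dot(e1, h);
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      V3 sv = p0 - a;
      double uu = dot(sv, h) * inv;
      if (uu < 0 || uu > 1) continue;
      V3 q = cross(sv, e1);
      double vv = dot(d, q) * inv;
      if (vv < 0 || uu + vv > 1) continue;
      double t = dot(e2, q) * inv;
      if (t <= 0 || t >= 1) continue;
      ++count;
      V3 nvec = cross(e1, e2);
      signed_count += dot(d, nvec) > 0 ? 1 : -1;
    }
  }
  return List::create(_["count"] = count, _["signed_count"] = (double)signed_count);
}
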