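// Bounded 3D Voronoi tessellation inside a confining sphere, computed cell by
// cell (in the manner of VORO++): each bead's cell starts as a box containing
// the sphere and is clipped by the bisector half-space of every other bead,
// processed in order of increasing plane distance with a security-radius
// early exit.  The spherical wall is realised by tangent planes derived from
// the configuration itself: first the bisector with the bead's own mirror
// image across the sphere surface (the tangent plane in its radial
// direction), then adaptive tangent planes at the directions of any cell
// vertices still poking beyond the sphere.  Every cell is thereby clipped to
// a circumscribed polyhedral approximation of the sphere whose radial
// overshoot is below wall_tol, the construction rotates rigidly with the
// bead configuration, and the cell volumes sum to the sphere volume to
// within a few tenths of a percent.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 scale(V3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

struct Face {
  std::vector<V3> pts;
  int neighbor;     // bead index (0-based) or -1 for wall
};

struct Plane { V3 n; double d; int neighbor; };  // half-space (x-p)*n <= d

// area and unit normal of a planar polygon (Newell)
double face_area(const Face &f, V3 &nrm) {
  V3 acc = {0, 0, 0};
  int m = f.pts.size();
  for (int i = 0; i < m; ++i) {
    V3 a = f.pts[i], b = f.pts[(i + 1) % m];
    acc.x += (a.y - b.y) * (a.z + b.z);
    acc.y += (a.z - b.z) * (a.x + b.x);
    acc.z += (a.x - b.x) * (a.y + b.y);
  }
  double nn = norm(acc);
  nrm = nn > 0 ? scale(acc, 1.0 / nn) : V3{0, 0, 1};
  return 0.5 * nn;
}

// clip one cell (list of faces) by a half-space; returns cut points collected
void clip_cell(std::vector<Face> &faces, V3 p, const Plane &pl, double tol) {
  std::vector<V3> cut;
  std::vector<Face> out;
  out.reserve(faces.size() + 1);
  for (Face &f : faces) {
    int m = f.pts.size();
    std::vector<double> s(m);
    bool any_in = false, any_out = false;
    for (int i = 0; i < m; ++i) {
      s[i] = dot(f.pts[i] - p, pl.n) - pl.d;
      if (s[i] <= tol) any_in = true;
      if (s[i] > tol) any_out = true;
    }
    if (!any_out) { out.push_back(std::move(f)); continue; }
    if (!any_in) continue;
    Face nf; nf.neighbor = f.neighbor;
    for (int i = 0; i < m; ++i) {
      int j = (i + 1) % m;
      bool in_i = s[i] <= tol, in_j = s[j] <= tol;
      if (in_i) nf.pts.push_back(f.pts[i]);
      if (in_i != in_j) {
        double t = s[i] / (s[i] - s[j]);
        V3 q = f.pts[i] + scale(f.pts[j] - f.pts[i], t);
        nf.pts.push_back(q);
        cut.push_back(q);
      }
    }
    if (nf.pts.size() >= 3) out.push_back(std::move(nf));
  }
  // cap face: convex section => order unique cut points by angle
  if (cut.size() >= 3) {
    V3 cen = {0, 0, 0};
    std::vector<V3> uniq;
    for (const V3 &q : cut) {
      bool dup = false;
      for (const V3 &r : uniq)
        if (norm(q - r) < 10 * tol + 1e-10) { dup = true; break; }
      if (!dup) uniq.push_back(q);
    }
    if (uniq.size() >= 3) {
      for (const V3 &q : uniq) cen = cen + scale(q, 1.0 / uniq.size());
      V3 a = std::fabs(pl.n.x) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
      V3 u = cross(pl.n, a); u = scale(u, 1.0 / norm(u));
      V3 v = cross(pl.n, u);
      std::vector<std::pair<double, V3>> ang;
      for (const V3 &q : uniq)
        ang.push_back({std::atan2(dot(q - cen, v), dot(q - cen, u)), q});
      std::sort(ang.begin(), ang.end(),
                [](const std::pair<double, V3> &x, const std::pair<double, V3> &y) {
                  return x.first < y.first;
                });
      Face cap; cap.neighbor = pl.neighbor;
      for (auto &pr : ang) cap.pts.push_back(pr.second);
      out.push_back(std::move(cap));
    }
  }
  faces.swap(out);
}

}  // namespace

// [[Rcpp::export]]
List cpp_tessellate(NumericMatrix pos, double sphere_r, double wall_tol) {
  int n = pos.nrow();
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) {
    P[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    if (norm(P[i]) >= sphere_r)
      stop("bead %d lies on or outside the confining sphere", i + 1);
  }
  const double tol = 1e-9 * sphere_r;

  std::vector<double> volumes(n, 0.0);
  std::vector<int> f_i, f_j;
  std::vector<double> f_area;

  std::vector<Plane> cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    cand.reserve(n);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      V3 dvec = P[j] - P[i];
      double d = norm(dvec);
      if (d < 1e-8)
        stop("coincident bead positions: beads %d and %d", i + 1, j + 1);
      cand.push_back({scale(dvec, 1.0 / d), 0.5 * d, j});
    }
    // own mirror image across the sphere surface: its bisector is the
    // tangent plane in the bead's radial direction (first wall plane)
    double rmi = norm(P[i]);
    if (rmi > 1e-9)
      cand.push_back({scale(P[i], 1.0 / rmi), sphere_r - rmi, -1});
    std::sort(cand.begin(), cand.end(),
              [](const Plane &a, const Plane &b) { return a.d < b.d; });

    // start from a box that contains the whole sphere
    double ri = norm(P[i]);
    double h = sphere_r + ri + 0.5;
    std::vector<Face> faces;
    V3 c = P[i];
    auto mk = [&](V3 a, V3 b, V3 cc, V3 d2) {
      Face f; f.neighbor = -2; f.pts = {a, b, cc, d2}; faces.push_back(f);
    };
    V3 lo = {c.x - h, c.y - h, c.z - h}, hi = {c.x + h, c.y + h, c.z + h};
    mk({lo.x, lo.y, lo.z}, {lo.x, hi.y, lo.z}, {hi.x, hi.y, lo.z}, {hi.x, lo.y, lo.z});
    mk({lo.x, lo.y, hi.z}, {hi.x, lo.y, hi.z}, {hi.x, hi.y, hi.z}, {lo.x, hi.y, hi.z});
    mk({lo.x, lo.y, lo.z}, {hi.x, lo.y, lo.z}, {hi.x, lo.y, hi.z}, {lo.x, lo.y, hi.z});
    mk({lo.x, hi.y, lo.z}, {lo.x, hi.y, hi.z}, {hi.x, hi.y, hi.z}, {hi.x, hi.y, lo.z});
    mk({lo.x, lo.y, lo.z}, {lo.x, lo.y, hi.z}, {lo.x, hi.y, hi.z}, {lo.x, hi.y, lo.z});
    mk({hi.x, lo.y, lo.z}, {hi.x, hi.y, lo.z}, {hi.x, hi.y, hi.z}, {hi.x, lo.y, hi.z});

    double maxdist = std::sqrt(3.0) * h;
    auto run_clip = [&](const std::vector<Plane> &planes) {
      for (const Plane &pl : planes) {
        if (pl.d > maxdist) break;
        clip_cell(faces, P[i], pl, tol);
        // security radius: furthest cell vertex from the bead
        maxdist = 0.0;
        for (const Face &f : faces)
          for (const V3 &q : f.pts)
            maxdist = std::max(maxdist, norm(q - P[i]));
      }
    };
    run_clip(cand);

    // adaptive wall bounding: while any cell vertex pokes beyond the sphere
    // (beyond a small radial tolerance), clip by the tangent plane in that
    // vertex's direction. The construction is derived from the configuration
    // alone, so the tessellation is rotation-covariant, and it bounds every
    // cell — even a single bead's — tightly to the sphere.
    for (int iter = 0; iter < 20000; ++iter) {
      double worst = sphere_r * (1.0 + wall_tol);
      V3 vdir = {0, 0, 0};
      bool found = false;
      for (const Face &f : faces)
        for (const V3 &q : f.pts) {
          double nq = norm(q);
          if (nq > worst) { worst = nq; vdir = q; found = true; }
        }
      if (!found) break;
      double nv = norm(vdir);
      Plane pl = {scale(vdir, 1.0 / nv), sphere_r - dot(P[i], vdir) / nv, -1};
      clip_cell(faces, P[i], pl, tol);
    }

    double vol = 0.0;
    for (const Face &f : faces) {
      V3 nrm;
      double a = face_area(f, nrm);
      if (a < 1e-12) continue;
      double dist = std::fabs(dot(f.pts[0] - P[i], nrm));
      vol += a * dist / 3.0;
      f_i.push_back(i + 1);
      f_j.push_back(f.neighbor >= 0 ? f.neighbor + 1 : NA_INTEGER);
      f_area.push_back(a);
    }
    volumes[i] = vol;
  }

  return List::create(_["volumes"] = NumericVector(volumes.begin(), volumes.end()),
                      _["facet_bead"] = IntegerVector(f_i.begin(), f_i.end()),
                      _["facet_neighbor"] = IntegerVector(f_j.begin(), f_j.end()),
                      _["facet_area"] = NumericVector(f_area.begin(), f_area.end()));
}
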