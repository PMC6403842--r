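// Bead-spring ring-polymer force field and Langevin (BAOAB) integrator.
//
// Conventions (reduced units): bead diameter sigma = 1, kBT = 1, mass = 1.
// Backbone bonds are FENE (or harmonic) and always carry a WCA core between
// the two bonded beads, so chains keep their contour length even when the
// non-bonded excluded volume of a bead is switched off (phantom flag).
// Non-bonded pairs interact through a purely repulsive WCA term unless either
// bead is phantom.  Extra harmonic springs (cohesin walk bonds, migrating
// extruder bonds) are passed separately and never carry a WCA core.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro-free minimal PRNG: 64-bit splitmix stream + polar Box-Muller.
// Self-contained so that trajectories are reproducible bit-for-bit for a
// given seed on one platform, independent of the C++ standard library.
struct Rng {
  uint64_t s;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : s(seed) {}
  double unif() {  // in (0,1)
    return (static_cast<double>(splitmix64(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

struct ForcePar {
  int bond_style;        // 0 = FENE, 1 = harmonic
  double bond_k;         // kBT / sigma^2
  double bond_rmax;      // FENE maximum extension (sigma)
  double bond_r0;        // harmonic rest length (sigma)
  double ev_eps;         // WCA epsilon (kBT); <= 0 switches pair term off
  double ev_cut;         // WCA cutoff (sigma)
  double bend_kappa;     // bending stiffness (kBT)
  double wall_k;         // wall stiffness (kBT / sigma^2)
  double sphere_r;       // confining radius; <= 0 means unconfined
  double force_cap;      // per-bead |F| cap; <= 0 means uncapped
};

struct System {
  int n;
  std::vector<double> x, y, z;
  const int *bond_i, *bond_j; int n_bonds;
  const int *hb_i, *hb_j; const double *hb_k, *hb_r0; int n_hb;
  const int *ang_a, *ang_b, *ang_c; int n_ang;
  std::vector<char> phantom;
  std::unordered_set<uint64_t> bonded;   // backbone pairs, to exclude from WCA
};

inline uint64_t pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return static_cast<uint64_t>(i) * static_cast<uint64_t>(n) + j;
}

// WCA force magnitude divided by r (so F_vec = coef * dr); U shifted to 0 at
// cutoff. Near-coincident pairs (r < 1e-6 sigma) are treated as clashes: the
// force is capped at a fixed moderate magnitude so overlapping initial
// configurations push apart instead of exploding.
inline double wca_coef(double r2, double eps, double cut2, double &u, int &clashes) {
  if (r2 >= cut2) return 0.0;
  if (r2 < 1e-12) {
    ++clashes;
    double r = std::sqrt(r2);
    return (r > 1e-9) ? 100.0 / r : 0.0;  // |F| capped at 100 kBT/sigma
  }
  double inv2 = 1.0 / r2;
  double s6 = inv2 * inv2 * inv2;      // (sigma/r)^6 with sigma = 1
  double s12 = s6 * s6;
  u += 4.0 * eps * (s12 - s6) + eps;
  return eps * (48.0 * s12 - 24.0 * s6) * inv2;
}

struct CellList {
  double x0, y0, z0, cs;
  int nx, ny, nz;
  std::vector<int> head, nxt;
  void build(const System &sys, double cell_size) {
    cs = cell_size;
    double xmin = 1e300, ymin = 1e300, zmin = 1e300;
    double xmax = -1e300, ymax = -1e300, zmax = -1e300;
    for (int i = 0; i < sys.n; ++i) {
      xmin = std::min(xmin, sys.x[i]); xmax = std::max(xmax, sys.x[i]);
      ymin = std::min(ymin, sys.y[i]); ymax = std::max(ymax, sys.y[i]);
      zmin = std::min(zmin, sys.z[i]); zmax = std::max(zmax, sys.z[i]);
    }
    double span = (xmax - xmin) + (ymax - ymin) + (zmax - zmin);
    if (!std::isfinite(span) || span > 1e6)
      stop("integration blow-up: non-finite or diverging coordinates");
    x0 = xmin - 0.5 * cs; y0 = ymin - 0.5 * cs; z0 = zmin - 0.5 * cs;
    nx = std::max(1, (int)((xmax - x0) / cs) + 1);
    ny = std::max(1, (int)((ymax - y0) / cs) + 1);
    nz = std::max(1, (int)((zmax - z0) / cs) + 1);
    if ((double)nx * ny * nz > 2.5e8)
      stop("integration blow-up: diverging coordinates (cell list overflow)");
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(sys.n, -1);
    for (int i = 0; i < sys.n; ++i) {
      int c = cell_of(sys.x[i], sys.y[i], sys.z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int cell_of(double px, double py, double pz) const {
    int cx = std::min(nx - 1, std::max(0, (int)((px - x0) / cs)));
    int cy = std::min(ny - 1, std::max(0, (int)((py - y0) / cs)));
    int cz = std::min(nz - 1, std::max(0, (int)((pz - z0) / cs)));
    return (cz * ny + cy) * nx + cx;
  }
};

// Returns number of near-coincident (clashing) pairs seen.
int forces(const System &sys, const ForcePar &fp,
           std::vector<double> &fx, std::vector<double> &fy, std::vector<double> &fz,
           double &epot, CellList &cl) {
  const int n = sys.n;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  epot = 0.0;
  int clashes = 0;
  const double cut2 = fp.ev_cut * fp.ev_cut;

  // backbone bonds: FENE/harmonic + WCA core (always, regardless of phantom)
  for (int b = 0; b < sys.n_bonds; ++b) {
    int i = sys.bond_i[b], j = sys.bond_j[b];
    double dx = sys.x[i] - sys.x[j], dy = sys.y[i] - sys.y[j], dz = sys.z[i] - sys.z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double coef = 0.0;
    if (fp.bond_style == 0) {
      double rm = fp.bond_rmax;
      double rr = std::min(r, 0.99 * rm);       // clamp to keep FENE finite
      double q = 1.0 - (rr * rr) / (rm * rm);
      coef = -fp.bond_k / q;
      epot += -0.5 * fp.bond_k * rm * rm * std::log(q);
    } else {
      coef = (r > 1e-12) ? -fp.bond_k * (r - fp.bond_r0) / r : 0.0;
      epot += 0.5 * fp.bond_k * (r - fp.bond_r0) * (r - fp.bond_r0);
    }
    if (fp.ev_eps > 0.0) {
      coef += wca_coef(r2, fp.ev_eps, cut2, epot, clashes);
    }
    fx[i] += coef * dx; fy[i] += coef * dy; fz[i] += coef * dz;
    fx[j] -= coef * dx; fy[j] -= coef * dy; fz[j] -= coef * dz;
  }

  // extra harmonic springs (walk bonds, migrating extruder bonds)
  for (int b = 0; b < sys.n_hb; ++b) {
    int i = sys.hb_i[b], j = sys.hb_j[b];
    double dx = sys.x[i] - sys.x[j], dy = sys.y[i] - sys.y[j], dz = sys.z[i] - sys.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double coef = -sys.hb_k[b] * (r - sys.hb_r0[b]) / r;
    epot += 0.5 * sys.hb_k[b] * (r - sys.hb_r0[b]) * (r - sys.hb_r0[b]);
    fx[i] += coef * dx; fy[i] += coef * dy; fz[i] += coef * dz;
    fx[j] -= coef * dx; fy[j] -= coef * dy; fz[j] -= coef * dz;
  }

  // bending: U = kappa * (1 - cos phi), phi angle between successive bonds
  if (fp.bend_kappa > 0.0) {
    for (int t = 0; t < sys.n_ang; ++t) {
      int a = sys.ang_a[t], b = sys.ang_b[t], c = sys.ang_c[t];
      double b1x = sys.x[b] - sys.x[a], b1y = sys.y[b] - sys.y[a], b1z = sys.z[b] - sys.z[a];
      double b2x = sys.x[c] - sys.x[b], b2y = sys.y[c] - sys.y[b], b2z = sys.z[c] - sys.z[b];
      double r1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
      double r2n = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
      if (r1 < 1e-12 || r2n < 1e-12) continue;
      double inv1 = 1.0 / r1, inv2 = 1.0 / r2n;
      double e1x = b1x * inv1, e1y = b1y * inv1, e1z = b1z * inv1;
      double e2x = b2x * inv2, e2y = b2y * inv2, e2z = b2z * inv2;
      double ct = e1x * e2x + e1y * e2y + e1z * e2z;
      epot += fp.bend_kappa * (1.0 - ct);
      // dU/d(cos phi) = -kappa; gradients of cos phi:
      double g1x = (e2x - ct * e1x) * inv1, g1y = (e2y - ct * e1y) * inv1, g1z = (e2z - ct * e1z) * inv1;
      double g2x = (e1x - ct * e2x) * inv2, g2y = (e1y - ct * e2y) * inv2, g2z = (e1z - ct * e2z) * inv2;
      double k = fp.bend_kappa;
      fx[a] += -k * g1x; fy[a] += -k * g1y; fz[a] += -k * g1z;
      fx[b] += k * (g1x - g2x); fy[b] += k * (g1y - g2y); fz[b] += k * (g1z - g2z);
      fx[c] += k * g2x; fy[c] += k * g2y; fz[c] += k * g2z;
    }
  }

  // non-bonded WCA via linked cells, skipping phantom beads and backbone pairs
  if (fp.ev_eps > 0.0) {
    cl.build(sys, std::max(fp.ev_cut, 1.0));
    for (int cz = 0; cz < cl.nz; ++cz)
      for (int cy = 0; cy < cl.ny; ++cy)
        for (int cx = 0; cx < cl.nx; ++cx) {
          int c0 = (cz * cl.ny + cy) * cl.nx + cx;
          for (int i = cl.head[c0]; i >= 0; i = cl.nxt[i]) {
            if (sys.phantom[i]) continue;
            for (int dz = -1; dz <= 1; ++dz)
              for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                  int ncx = cx + dx, ncy = cy + dy, ncz = cz + dz;
                  if (ncx < 0 || ncy < 0 || ncz < 0 ||
                      ncx >= cl.nx || ncy >= cl.ny || ncz >= cl.nz) continue;
                  int c1 = (ncz * cl.ny + ncy) * cl.nx + ncx;
                  if (c1 < c0) continue;
                  for (int j = cl.head[c1]; j >= 0; j = cl.nxt[j]) {
                    if (c1 == c0 && j <= i) continue;
                    if (sys.phantom[j]) continue;
                    double ddx = sys.x[i] - sys.x[j];
                    double ddy = sys.y[i] - sys.y[j];
                    double ddz = sys.z[i] - sys.z[j];
                    double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
                    if (r2 >= cut2) continue;
                    if (sys.bonded.count(pair_key(i, j, sys.n))) continue;
                    double coef = wca_coef(r2, fp.ev_eps, cut2, epot, clashes);
                    fx[i] += coef * ddx; fy[i] += coef * ddy; fz[i] += coef * ddz;
                    fx[j] -= coef * ddx; fy[j] -= coef * ddy; fz[j] -= coef * ddz;
                  }
                }
          }
        }
  }

  // spherical wall: harmonic inward restoring force beyond sphere_r
  if (fp.sphere_r > 0.0) {
    for (int i = 0; i < n; ++i) {
      double r = std::sqrt(sys.x[i] * sys.x[i] + sys.y[i] * sys.y[i] + sys.z[i] * sys.z[i]);
      if (r > fp.sphere_r) {
        double exc = r - fp.sphere_r;
        double coef = -fp.wall_k * exc / r;
        epot += 0.5 * fp.wall_k * exc * exc;
        fx[i] += coef * sys.x[i]; fy[i] += coef * sys.y[i]; fz[i] += coef * sys.z[i];
      }
    }
  }

  if (fp.force_cap > 0.0) {
    double cap2 = fp.force_cap * fp.force_cap;
    for (int i = 0; i < n; ++i) {
      double f2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
      if (f2 > cap2) {
        double s = fp.force_cap / std::sqrt(f2);
        fx[i] *= s; fy[i] *= s; fz[i] *= s;
      }
    }
  }
  return clashes;
}

ForcePar unpack_ff(const List &ff) {
  ForcePar fp;
  std::string style = as<std::string>(ff["bond_style"]);
  fp.bond_style = (style == "harmonic") ? 1 : 0;
  fp.bond_k = as<double>(ff["bond_k"]);
  fp.bond_rmax = as<double>(ff["bond_rmax"]);
  fp.bond_r0 = as<double>(ff["bond_r0"]);
  fp.ev_eps = as<double>(ff["ev_epsilon"]);
  fp.ev_cut = as<double>(ff["ev_cutoff"]);
  fp.bend_kappa = as<double>(ff["bend_kappa"]);
  fp.wall_k = as<double>(ff["wall_stiffness"]);
  fp.force_cap = as<double>(ff["force_cap"]);
  return fp;
}

System unpack_system(const NumericMatrix &pos, const IntegerMatrix &bonds,
                     const IntegerMatrix &hbonds, const NumericVector &hb_k,
                     const NumericVector &hb_r0, const IntegerMatrix &angles,
                     const LogicalVector &phantom) {
  System sys;
  sys.n = pos.nrow();
  sys.x.resize(sys.n); sys.y.resize(sys.n); sys.z.resize(sys.n);
  for (int i = 0; i < sys.n; ++i) {
    sys.x[i] = pos(i, 0); sys.y[i] = pos(i, 1); sys.z[i] = pos(i, 2);
  }
  sys.n_bonds = bonds.nrow();
  sys.bond_i = sys.n_bonds ? &bonds(0, 0) : nullptr;
  sys.bond_j = sys.n_bonds ? &bonds(0, 1) : nullptr;
  sys.n_hb = hbonds.nrow();
  sys.hb_i = sys.n_hb ? &hbonds(0, 0) : nullptr;
  sys.hb_j = sys.n_hb ? &hbonds(0, 1) : nullptr;
  sys.hb_k = sys.n_hb ? &hb_k[0] : nullptr;
  sys.hb_r0 = sys.n_hb ? &hb_r0[0] : nullptr;
  sys.n_ang = angles.nrow();
  sys.ang_a = sys.n_ang ? &angles(0, 0) : nullptr;
  sys.ang_b = sys.n_ang ? &angles(0, 1) : nullptr;
  sys.ang_c = sys.n_ang ? &angles(0, 2) : nullptr;
  sys.phantom.resize(sys.n);
  for (int i = 0; i < sys.n; ++i) sys.phantom[i] = phantom[i] ? 1 : 0;
  sys.bonded.reserve(sys.n_bonds * 2);
  for (int b = 0; b < sys.n_bonds; ++b)
    sys.bonded.insert(pair_key(sys.bond_i[b], sys.bond_j[b], sys.n));
  return sys;
}

}  // namespace

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, IntegerMatrix bonds,
                        IntegerMatrix hbonds, NumericVector hb_k, NumericVector hb_r0,
                        IntegerMatrix angles, LogicalVector phantom,
                        double sphere_r, List ff) {
  System sys = unpack_system(pos, bonds, hbonds, hb_k, hb_r0, angles, phantom);
  ForcePar fp = unpack_ff(ff);
  fp.sphere_r = sphere_r;
  std::vector<double> fx(sys.n), fy(sys.n), fz(sys.n);
  double epot = 0.0;
  CellList cl;
  int clashes = forces(sys, fp, fx, fy, fz, epot, cl);
  NumericMatrix out(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return List::create(_["forces"] = out, _["potential"] = epot, _["clashes"] = clashes);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel, IntegerMatrix bonds,
                      IntegerMatrix hbonds, NumericVector hb_k, NumericVector hb_r0,
                      IntegerMatrix angles, LogicalVector phantom, double sphere_r,
                      List ff, double dt, double gamma, double temperature,
                      int n_steps, double seed, int log_every) {
  System sys = unpack_system(pos, bonds, hbonds, hb_k, hb_r0, angles, phantom);
  ForcePar fp = unpack_ff(ff);
  fp.sphere_r = sphere_r;
  const int n = sys.n;
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n);
  double epot = 0.0;
  CellList cl;
  Rng rng(static_cast<uint64_t>(seed));

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * temperature);
  const double hdt = 0.5 * dt;

  int total_clashes = forces(sys, fp, fx, fy, fz, epot, cl);
  double ke_acc = 0.0;
  long ke_samples = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {  // B half kick + A half drift
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
      sys.x[i] += hdt * vx[i]; sys.y[i] += hdt * vy[i]; sys.z[i] += hdt * vz[i];
    }
    for (int i = 0; i < n; ++i) {  // O: Ornstein-Uhlenbeck
      vx[i] = c1 * vx[i] + c2 * rng.gauss();
      vy[i] = c1 * vy[i] + c2 * rng.gauss();
      vz[i] = c1 * vz[i] + c2 * rng.gauss();
    }
    double chk = 0.0;
    for (int i = 0; i < n; ++i) {  // A half drift
      sys.x[i] += hdt * vx[i]; sys.y[i] += hdt * vy[i]; sys.z[i] += hdt * vz[i];
      chk += std::fabs(sys.x[i]) + std::fabs(sys.y[i]) + std::fabs(sys.z[i]);
    }
    if (!std::isfinite(chk) || std::fabs(chk) > 1e12 * (n + 1.0))
      stop("integration blow-up: non-finite or diverging coordinates at step %d",
           step);
    total_clashes += forces(sys, fp, fx, fy, fz, epot, cl);
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {  // B half kick
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
      ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    }
    ke *= 0.5;
    ke_acc += ke; ++ke_samples;
    if (step % 500 == 0 || step == n_steps) {
      bool ok = true;
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(sys.x[i] + sys.y[i] + sys.z[i])) { ok = false; break; }
      if (!ok)
        stop("integration blow-up: non-finite coordinates at step %d", step);
      if (log_every > 0 && step % log_every == 0)
        REprintf("step %d  epot %.3f  T_kin %.3f\n", step, epot,
                 2.0 * ke / (3.0 * n));
    }
  }

  NumericMatrix opos(n, 3), ovel(n, 3);
  for (int i = 0; i < n; ++i) {
    opos(i, 0) = sys.x[i]; opos(i, 1) = sys.y[i]; opos(i, 2) = sys.z[i];
    ovel(i, 0) = vx[i]; ovel(i, 1) = vy[i]; ovel(i, 2) = vz[i];
  }
  double mean_T = ke_samples ? (2.0 * ke_acc / ke_samples) / (3.0 * n) : NA_REAL;
  return List::create(_["pos"] = opos, _["vel"] = ovel,
                      _["potential"] = epot, _["mean_kinetic_temperature"] = mean_T,
                      _["clashes"] = total_clashes);
}
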