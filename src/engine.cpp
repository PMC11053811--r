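// Core numerics: cell-list pair search, force evaluation for the
// truncated/shifted Lennard-Jones + FENE force field, and a BAOAB
// Langevin integrator under cubic periodic boundaries.
// Reduced units throughout: sigma = 1, m = 1, energies in epsilon,
// time in tau = sqrt(m sigma^2 / epsilon).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

namespace {

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// splitmix64 seeding + xoshiro256++ stream; deterministic for a given seed.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare;
  double spare;
  double gauss() {  // Marsaglia polar
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

struct CellList {
  int nc;            // cells per dimension (>= 3 to be usable)
  double cw;         // cell width
  std::vector<std::vector<int>> cells;
  bool usable;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, int n, double L, double cutoff) {
    nc = (int)std::floor(L / cutoff);
    usable = nc >= 3;
    if (!usable) return;
    cw = L / nc;
    cells.assign((size_t)nc * nc * nc, {});
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[i] / cw); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
      int cy = (int)(y[i] / cw); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
      int cz = (int)(z[i] / cw); if (cz >= nc) cz = nc - 1; if (cz < 0) cz = 0;
      cells[(size_t)(cx * nc + cy) * nc + cz].push_back(i);
    }
  }
};

// Visit every unordered pair with min-image distance^2 <= cutoff^2.
template <typename F>
void for_pairs(const std::vector<double>& x, const std::vector<double>& y,
               const std::vector<double>& z, int n, double L, double cutoff,
               F&& fun) {
  double c2 = cutoff * cutoff;
  CellList cl;
  cl.build(x, y, z, n, L, cutoff);
  if (!cl.usable) {  // small box: brute force
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[i] - x[j], L);
        double dy = min_image(y[i] - y[j], L);
        double dz = min_image(z[i] - z[j], L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= c2) fun(i, j, dx, dy, dz, r2);
      }
    return;
  }
  int nc = cl.nc;
  // half neighbor stencil: same cell (j>i) + 13 forward neighbors
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  for (int cx = 0; cx < nc; ++cx)
    for (int cy = 0; cy < nc; ++cy)
      for (int cz = 0; cz < nc; ++cz) {
        const std::vector<int>& ci = cl.cells[(size_t)(cx * nc + cy) * nc + cz];
        if (ci.empty()) continue;
        for (size_t a = 0; a + 1 < ci.size(); ++a)
          for (size_t b = a + 1; b < ci.size(); ++b) {
            int i = ci[a], j = ci[b];
            double dx = min_image(x[i] - x[j], L);
            double dy = min_image(y[i] - y[j], L);
            double dz = min_image(z[i] - z[j], L);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 <= c2) fun(i, j, dx, dy, dz, r2);
          }
        for (int k = 0; k < 13; ++k) {
          int ox = (cx + off[k][0] + nc) % nc;
          int oy = (cy + off[k][1] + nc) % nc;
          int oz = (cz + off[k][2] + nc) % nc;
          const std::vector<int>& cj = cl.cells[(size_t)(ox * nc + oy) * nc + oz];
          if (cj.empty()) continue;
          for (int i : ci)
            for (int j : cj) {
              double dx = min_image(x[i] - x[j], L);
              double dy = min_image(y[i] - y[j], L);
              double dz = min_image(z[i] - z[j], L);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 <= c2) fun(i, j, dx, dy, dz, r2);
            }
        }
      }
}

inline uint64_t pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (uint64_t)i * (uint64_t)n + (uint64_t)j;
}

struct FFParams {
  const double* eps;    // ntype x ntype, column-major
  const double* rcut;   // ntype x ntype
  const double* ushift; // precomputed 4 eps ((1/rc)^12 - (1/rc)^6)
  int ntype;
  double maxcut;
  double fene_k, fene_R0;
  bool bonded_lj;
};

class Engine {
public:
  int n;
  std::vector<double> x, y, z;       // wrapped, in [0, L)
  std::vector<int> ix, iy, iz;       // image flags
  std::vector<double> vx, vy, vz;
  std::vector<int> type;             // 0-based type codes
  std::vector<int> b1, b2;           // bonds, 0-based
  std::unordered_set<uint64_t> bonded;
  double L;
  FFParams ff;
  std::vector<double> eps_s, rcut_s, ush_s;  // backing stores for ff pointers
  std::vector<double> fx, fy, fz;

  // Verlet neighbor list (cutoff + skin), rebuilt on displacement trigger
  double skin = 0.4;
  std::vector<int> nb_i, nb_j;
  std::vector<double> ref_x, ref_y, ref_z;  // unwrapped coords at last build
  bool nb_valid = false;

  double ux(int i) const { return x[i] + L * ix[i]; }
  double uy(int i) const { return y[i] + L * iy[i]; }
  double uz(int i) const { return z[i] + L * iz[i]; }

  void build_neighbor_list() {
    nb_i.clear(); nb_j.clear();
    for_pairs(x, y, z, n, L, ff.maxcut + skin,
              [this](int i, int j, double, double, double, double) {
                nb_i.push_back(i);
                nb_j.push_back(j);
              });
    ref_x.resize(n); ref_y.resize(n); ref_z.resize(n);
    for (int i = 0; i < n; ++i) {
      ref_x[i] = ux(i); ref_y[i] = uy(i); ref_z[i] = uz(i);
    }
    nb_valid = true;
  }

  bool needs_rebuild() const {
    if (!nb_valid) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = ux(i) - ref_x[i], dy = uy(i) - ref_y[i],
             dz = uz(i) - ref_z[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void pair_force(int i, int j, double dx, double dy, double dz, double r2) {
    int ti = type[i], tj = type[j];
    double rc = ff.rcut[ti + ff.ntype * tj];
    if (r2 > rc * rc) return;
    if (!ff.bonded_lj && bonded.count(pair_key(i, j, n))) return;
    double e = ff.eps[ti + ff.ntype * tj];
    double s2 = 1.0 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
    double fr = 24.0 * e * (2.0 * s12 - s6) * s2;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }

  void compute_forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    if (needs_rebuild()) build_neighbor_list();
    double c2 = ff.maxcut * ff.maxcut;
    for (size_t k = 0; k < nb_i.size(); ++k) {
      int i = nb_i[k], j = nb_j[k];
      double dx = min_image(x[i] - x[j], L);
      double dy = min_image(y[i] - y[j], L);
      double dz = min_image(z[i] - z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= c2) pair_force(i, j, dx, dy, dz, r2);
    }
    double R02 = ff.fene_R0 * ff.fene_R0;
    for (size_t k = 0; k < b1.size(); ++k) {
      int i = b1[k], j = b2[k];
      double dx = min_image(x[i] - x[j], L);
      double dy = min_image(y[i] - y[j], L);
      double dz = min_image(z[i] - z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= R02)
        stop("FENE bond overstretched: bond %d-%d at r = %f (R0 = %f)",
             i + 1, j + 1, std::sqrt(r2), ff.fene_R0);
      double fr = -ff.fene_k / (1.0 - r2 / R02);
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }

  double potential_energy() {
    double u = 0.0;
    for_pairs(x, y, z, n, L, ff.maxcut,
              [this, &u](int i, int j, double, double, double, double r2) {
                int ti = type[i], tj = type[j];
                double rc = ff.rcut[ti + ff.ntype * tj];
                if (r2 > rc * rc) return;
                if (!ff.bonded_lj && bonded.count(pair_key(i, j, n))) return;
                double e = ff.eps[ti + ff.ntype * tj];
                double s2 = 1.0 / r2, s6 = s2 * s2 * s2;
                u += 4.0 * e * (s6 * s6 - s6) - e * ff.ushift[ti + ff.ntype * tj];
              });
    double R02 = ff.fene_R0 * ff.fene_R0;
    for (size_t k = 0; k < b1.size(); ++k) {
      int i = b1[k], j = b2[k];
      double dx = min_image(x[i] - x[j], L);
      double dy = min_image(y[i] - y[j], L);
      double dz = min_image(z[i] - z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= R02)
        stop("FENE bond overstretched: bond %d-%d", i + 1, j + 1);
      u += -0.5 * ff.fene_k * R02 * std::log(1.0 - r2 / R02);
    }
    return u;
  }

  void wrap(int i) {
    if (x[i] >= L) { x[i] -= L; ix[i] += 1; } else if (x[i] < 0) { x[i] += L; ix[i] -= 1; }
    if (y[i] >= L) { y[i] -= L; iy[i] += 1; } else if (y[i] < 0) { y[i] += L; iy[i] -= 1; }
    if (z[i] >= L) { z[i] -= L; iz[i] += 1; } else if (z[i] < 0) { z[i] += L; iz[i] -= 1; }
  }

  // Cap the half-step displacement at dmax/2 (LAMMPS nve/limit style);
  // used during push-off to defuse initial overlaps. dmax <= 0 disables.
  void drift(int i, double h, double dmax) {
    double dx = h * vx[i], dy = h * vy[i], dz = h * vz[i];
    if (dmax > 0) {
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > 0.5 * dmax) {
        double sc = 0.5 * dmax / d;
        dx *= sc; dy *= sc; dz *= sc;
      }
    }
    x[i] += dx; y[i] += dy; z[i] += dz;
    wrap(i);
  }

  // BAOAB splitting: with gamma = 0 it reduces to plain velocity Verlet (NVE).
  void run(int nsteps, double dt, double gamma, double kT, Rng& rng,
           double dmax) {
    double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
    double c2 = (gamma > 0) ? std::sqrt(kT * (1.0 - c1 * c1)) : 0.0;
    double h = 0.5 * dt;
    compute_forces();
    for (int s = 0; s < nsteps; ++s) {
      for (int i = 0; i < n; ++i) {
        vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
        drift(i, h, dmax);
      }
      if (gamma > 0) {
        for (int i = 0; i < n; ++i) {
          vx[i] = c1 * vx[i] + c2 * rng.gauss();
          vy[i] = c1 * vy[i] + c2 * rng.gauss();
          vz[i] = c1 * vz[i] + c2 * rng.gauss();
        }
      }
      for (int i = 0; i < n; ++i) drift(i, h, dmax);
      compute_forces();
      for (int i = 0; i < n; ++i) {
        vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
      }
    }
  }
};

Engine make_engine(const NumericMatrix& pos, const IntegerMatrix& img,
                   const NumericMatrix& vel, const IntegerVector& type,
                   const IntegerMatrix& bonds, const NumericMatrix& eps,
                   const NumericMatrix& rcut, double L, double fene_k,
                   double fene_R0, bool bonded_lj) {
  Engine e;
  e.n = pos.nrow();
  e.L = L;
  e.x.resize(e.n); e.y.resize(e.n); e.z.resize(e.n);
  e.ix.resize(e.n); e.iy.resize(e.n); e.iz.resize(e.n);
  e.vx.assign(e.n, 0.0); e.vy.assign(e.n, 0.0); e.vz.assign(e.n, 0.0);
  e.type.resize(e.n);
  e.fx.resize(e.n); e.fy.resize(e.n); e.fz.resize(e.n);
  for (int i = 0; i < e.n; ++i) {
    e.x[i] = pos(i, 0); e.y[i] = pos(i, 1); e.z[i] = pos(i, 2);
    e.ix[i] = img(i, 0); e.iy[i] = img(i, 1); e.iz[i] = img(i, 2);
    if (vel.nrow() == e.n) {
      e.vx[i] = vel(i, 0); e.vy[i] = vel(i, 1); e.vz[i] = vel(i, 2);
    }
    e.type[i] = type[i] - 1;
  }
  for (int k = 0; k < bonds.nrow(); ++k) {
    e.b1.push_back(bonds(k, 0) - 1);
    e.b2.push_back(bonds(k, 1) - 1);
  }
  if (!bonded_lj)
    for (size_t k = 0; k < e.b1.size(); ++k)
      e.bonded.insert(pair_key(e.b1[k], e.b2[k], e.n));
  int nt = eps.nrow();
  e.eps_s.assign(eps.begin(), eps.end());
  e.rcut_s.assign(rcut.begin(), rcut.end());
  e.ush_s.resize((size_t)nt * nt);
  double mc = 0.0;
  for (int k = 0; k < nt * nt; ++k) {
    double rc = e.rcut_s[k];
    if (rc > mc) mc = rc;
    double s2 = 1.0 / (rc * rc), s6 = s2 * s2 * s2;
    e.ush_s[k] = 4.0 * (s6 * s6 - s6);  // per unit eps
  }
  e.ff.eps = e.eps_s.data(); e.ff.rcut = e.rcut_s.data(); e.ff.ushift = e.ush_s.data();
  e.ff.ntype = nt; e.ff.maxcut = mc;
  e.ff.fene_k = fene_k; e.ff.fene_R0 = fene_R0; e.ff.bonded_lj = bonded_lj;
  return e;
}

}  // namespace

// [[Rcpp::export(name = ".advance_cpp")]]
List advance_cpp(NumericMatrix pos, IntegerMatrix img, NumericMatrix vel,
                 IntegerVector type, IntegerMatrix bonds, NumericMatrix eps,
                 NumericMatrix rcut, double L, double fene_k, double fene_R0,
                 bool bonded_lj, int nsteps, double dt, double gamma,
                 double kT, double seed, double dmax) {
  Engine e = make_engine(pos, img, vel, type, bonds, eps, rcut, L,
                         fene_k, fene_R0, bonded_lj);
  Rng rng((uint64_t)seed);
  e.run(nsteps, dt, gamma, kT, rng, dmax);
  NumericMatrix opos(e.n, 3), ovel(e.n, 3);
  IntegerMatrix oimg(e.n, 3);
  for (int i = 0; i < e.n; ++i) {
    opos(i, 0) = e.x[i]; opos(i, 1) = e.y[i]; opos(i, 2) = e.z[i];
    oimg(i, 0) = e.ix[i]; oimg(i, 1) = e.iy[i]; oimg(i, 2) = e.iz[i];
    ovel(i, 0) = e.vx[i]; ovel(i, 1) = e.vy[i]; ovel(i, 2) = e.vz[i];
  }
  return List::create(_["pos"] = opos, _["img"] = oimg, _["vel"] = ovel);
}

// [[Rcpp::export(name = ".forces_cpp")]]
NumericMatrix forces_cpp(NumericMatrix pos, IntegerVector type,
                         IntegerMatrix bonds, NumericMatrix eps,
                         NumericMatrix rcut, double L, double fene_k,
                         double fene_R0, bool bonded_lj) {
  IntegerMatrix img(pos.nrow(), 3);
  NumericMatrix vel(0, 3);
  Engine e = make_engine(pos, img, vel, type, bonds, eps, rcut, L,
                         fene_k, fene_R0, bonded_lj);
  e.compute_forces();
  NumericMatrix f(e.n, 3);
  for (int i = 0; i < e.n; ++i) {
    f(i, 0) = e.fx[i]; f(i, 1) = e.fy[i]; f(i, 2) = e.fz[i];
  }
  return f;
}

// [[Rcpp::export(name = ".potential_energy_cpp")]]
double potential_energy_cpp(NumericMatrix pos, IntegerVector type,
                            IntegerMatrix bonds, NumericMatrix eps,
                            NumericMatrix rcut, double L, double fene_k,
                            double fene_R0, bool bonded_lj) {
  IntegerMatrix img(pos.nrow(), 3);
  NumericMatrix vel(0, 3);
  Engine e = make_engine(pos, img, vel, type, bonds, eps, rcut, L,
                         fene_k, fene_R0, bonded_lj);
  return e.potential_energy();
}

// Pairs of rows of `pos` whose minimum-image distance is <= cutoff.
// Returns a 3-column matrix: i, j (1-based row indices), distance.
// [[Rcpp::export(name = ".pairs_within_cpp")]]
NumericMatrix pairs_within_cpp(NumericMatrix pos, double L, double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
  }
  std::vector<double> out;
  for_pairs(x, y, z, n, L, cutoff,
            [&out](int i, int j, double, double, double, double r2) {
              out.push_back(i + 1);
              out.push_back(j + 1);
              out.push_back(std::sqrt(r2));
            });
  int m = (int)out.size() / 3;
  NumericMatrix res(m, 3);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out[3 * k]; res(k, 1) = out[3 * k + 1]; res(k, 2) = out[3 * k + 2];
  }
  return res;
}
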