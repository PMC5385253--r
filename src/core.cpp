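// Simulation core: FENE/WCA forces, Langevin (GJF) integration, chain
// growth, obstacle placement and translocation event bookkeeping.
//
// All randomness uses mt19937_64 + Box-Muller seeded from (seed, index,
// stream) through a splitmix64 finaliser, so trajectories are bit-identical
// for a given seed on any platform and runs of an ensemble are independent
// streams addressable by run index.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// combine master seed, run index and stream tag into one 64-bit state
static inline uint64_t stream_seed(double seed, int index, int stream) {
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t h = splitmix64(s * 0x9E3779B97F4A7C15ULL + 0x632BE59BD9B4E019ULL);
  h = splitmix64(h ^ ((uint64_t)(uint32_t)index * 0xFF51AFD7ED558CCDULL));
  h = splitmix64(h ^ ((uint64_t)(uint32_t)stream * 0xC4CEB9FE1A85EC53ULL));
  return h;
}

struct RNG {
  // mt19937_64 has a standard-specified sequence: portable determinism
  std::mt19937_64 eng;
  bool have_cached;
  double cached;
  explicit RNG(uint64_t seed) : eng(seed), have_cached(false), cached(0.0) {}
  double unif() { // (0, 1]
    return ((eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double gauss() { // Marsaglia polar method (no trig), deterministic
    if (have_cached) { have_cached = false; return cached; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    cached = v * f;
    have_cached = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// Parameters

struct Pars {
  double sigma, eps, k_spring, R0, mass;
  double xi, kBT, dt;
  double F, L, R, d;
  double mem_extent; // 0 disables the analytic membrane closure
  bool field_everywhere;
};

static Pars read_pars(const List& p) {
  Pars q;
  q.sigma = as<double>(p["sigma"]);
  q.eps = as<double>(p["epsilon"]);
  q.k_spring = as<double>(p["k_spring"]);
  q.R0 = as<double>(p["R0"]);
  q.mass = as<double>(p["mass"]);
  q.xi = as<double>(p["friction"]);
  q.kBT = as<double>(p["kBT"]);
  q.dt = as<double>(p["dt"]);
  q.F = as<double>(p["F"]);
  q.L = as<double>(p["L"]);
  q.R = as<double>(p["R"]);
  q.d = as<double>(p["d"]);
  q.mem_extent = as<double>(p["mem_extent"]);
  q.field_everywhere = as<bool>(p["field_everywhere"]);
  return q;
}

static inline bool in_channel(double x, double y, double z,
                              const Pars& p) {
  return z >= 0.0 && z <= p.L && (x * x + y * y) <= p.R * p.R;
}

// ---------------------------------------------------------------------------
// Static environment (wall particles + obstacles) with a cell list.
// Each static particle carries its own pair sigma (Lorentz rule for
// obstacles of diameter d != sigma).

struct StaticEnv {
  std::vector<double> x, y, z, sig; // pair sigma per particle
  // cell list
  double rc;           // max cutoff = 2^(1/6) * max sigma
  double zlo, zhi;     // z slab beyond which no static contact is possible
  double ox, oy, oz;   // grid origin
  int nx, ny, nz_;
  std::vector<int> cell_start;
  std::vector<int> cell_ids;
  int n() const { return (int)x.size(); }

  double cell;         // cell edge = rc + skin (Verlet-list search range)
  double skin;

  void build(const NumericMatrix& wall, const NumericMatrix& obst,
             double sigma, double d) {
    int nw = wall.nrow(), no = obst.nrow();
    x.resize(nw + no); y.resize(nw + no); z.resize(nw + no);
    sig.resize(nw + no);
    for (int i = 0; i < nw; ++i) {
      x[i] = wall(i, 0); y[i] = wall(i, 1); z[i] = wall(i, 2);
      sig[i] = sigma;
    }
    double sig_o = 0.5 * (sigma + d);
    for (int i = 0; i < no; ++i) {
      x[nw + i] = obst(i, 0); y[nw + i] = obst(i, 1); z[nw + i] = obst(i, 2);
      sig[nw + i] = sig_o;
    }
    double smax = sigma;
    if (no > 0) smax = std::max(smax, sig_o);
    rc = std::pow(2.0, 1.0 / 6.0) * smax;
    skin = 0.4 * sigma;
    cell = rc + skin;
    if (n() == 0) { nx = ny = nz_ = 0; zlo = 0; zhi = 0; return; }
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n(); ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    zlo = zmin - rc; zhi = zmax + rc;
    ox = xmin - cell; oy = ymin - cell; oz = zmin - cell;
    nx = (int)std::floor((xmax - ox) / cell) + 2;
    ny = (int)std::floor((ymax - oy) / cell) + 2;
    nz_ = (int)std::floor((zmax - oz) / cell) + 2;
    int ncell = nx * ny * nz_;
    std::vector<int> count(ncell, 0);
    std::vector<int> cix(n());
    for (int i = 0; i < n(); ++i) {
      int cx = (int)std::floor((x[i] - ox) / cell);
      int cy = (int)std::floor((y[i] - oy) / cell);
      int cz = (int)std::floor((z[i] - oz) / cell);
      cix[i] = (cz * ny + cy) * nx + cx;
      count[cix[i]]++;
    }
    cell_start.assign(ncell + 1, 0);
    for (int c = 0; c < ncell; ++c) cell_start[c + 1] = cell_start[c] + count[c];
    cell_ids.resize(n());
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < n(); ++i) cell_ids[fill[cix[i]]++] = i;
  }

  // static particles within rc + skin of (bx,by,bz), via the cell grid
  void collect(double bx, double by, double bz, std::vector<int>& out) const {
    out.clear();
    if (n() == 0 || bz < zlo - skin || bz > zhi + skin) return;
    int cx = (int)std::floor((bx - ox) / cell);
    int cy = (int)std::floor((by - oy) / cell);
    int cz = (int)std::floor((bz - oz) / cell);
    double range2 = cell * cell;
    for (int dz = -1; dz <= 1; ++dz) {
      int zc = cz + dz; if (zc < 0 || zc >= nz_) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yc = cy + dy; if (yc < 0 || yc >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xc = cx + dx; if (xc < 0 || xc >= nx) continue;
          int c = (zc * ny + yc) * nx + xc;
          for (int q = cell_start[c]; q < cell_start[c + 1]; ++q) {
            int j = cell_ids[q];
            double rx = bx - x[j], ry = by - y[j], rz = bz - z[j];
            if (rx * rx + ry * ry + rz * rz <= range2) out.push_back(j);
          }
        }
      }
    }
  }
};

// Per-bead Verlet neighbour lists over the static particles, refreshed
// only when a bead has moved more than half the skin since its list was
// built.
struct NbrList {
  const StaticEnv* env;
  std::vector<std::vector<int>> nbrs;
  std::vector<double> rx, ry, rz; // positions at last rebuild
  std::vector<char> valid;

  void init(const StaticEnv* e, int N) {
    env = e;
    nbrs.assign(N, {});
    rx.assign(N, 0.0); ry.assign(N, 0.0); rz.assign(N, 0.0);
    valid.assign(N, 0);
  }

  const std::vector<int>& get(int i, double bx, double by, double bz) {
    double half = 0.5 * env->skin;
    if (!valid[i]) {
      env->collect(bx, by, bz, nbrs[i]);
      rx[i] = bx; ry[i] = by; rz[i] = bz; valid[i] = 1;
    } else {
      double dx = bx - rx[i], dy = by - ry[i], dz = bz - rz[i];
      if (dx * dx + dy * dy + dz * dz > half * half) {
        env->collect(bx, by, bz, nbrs[i]);
        rx[i] = bx; ry[i] = by; rz[i] = bz;
      }
    }
    return nbrs[i];
  }
};

// WCA force from listed static particles onto a bead
static double static_force_on(const StaticEnv& env,
                              const std::vector<int>& list,
                              double bx, double by, double bz, double eps,
                              double* fx, double* fy, double* fz,
                              bool* overlap) {
  double u = 0.0;
  for (size_t q = 0; q < list.size(); ++q) {
    int j = list[q];
    double rx = bx - env.x[j], ry = by - env.y[j], rz = bz - env.z[j];
    double r2 = rx * rx + ry * ry + rz * rz;
    double cut = 1.1224620483093730 * env.sig[j];
    if (r2 >= cut * cut) continue;
    if (r2 < 1e-24) { *overlap = true; continue; }
    double s2 = env.sig[j] * env.sig[j] / r2;
    double s6 = s2 * s2 * s2, s12 = s6 * s6;
    double fr = 24.0 * eps * (2.0 * s12 - s6) / r2;
    *fx += fr * rx; *fy += fr * ry; *fz += fr * rz;
    u += 4.0 * eps * (s12 - s6) + eps;
  }
  return u;
}

// ---------------------------------------------------------------------------
// Force evaluation on the chain. Returns status: 0 ok, 1 broken bond,
// 2 overlap singularity. bad_index reports the offending bead/bond.

static int chain_forces(const std::vector<double>& px,
                        const std::vector<double>& py,
                        const std::vector<double>& pz,
                        const StaticEnv& env, NbrList& nl, const Pars& p,
                        bool field_on,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& fz,
                        double* energy, int* bad_index) {
  int N = (int)px.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double u = 0.0;
  double cut = 1.1224620483093730 * p.sigma;
  double cut2 = cut * cut;
  // FENE bonds between consecutive beads
  for (int i = 0; i + 1 < N; ++i) {
    double rx = px[i + 1] - px[i], ry = py[i + 1] - py[i],
           rz = pz[i + 1] - pz[i];
    double r2 = rx * rx + ry * ry + rz * rz;
    double w = 1.0 - r2 / (p.R0 * p.R0);
    if (w <= 0.0) { *bad_index = i + 2; return 1; } // 1-based far bead
    double fr = -p.k_spring / w; // force on i+1 along r is -k r / w
    fx[i + 1] += fr * rx; fy[i + 1] += fr * ry; fz[i + 1] += fr * rz;
    fx[i] -= fr * rx; fy[i] -= fr * ry; fz[i] -= fr * rz;
    u += -0.5 * p.k_spring * p.R0 * p.R0 * std::log(w);
  }
  // WCA between all bead pairs (N is small; all-pairs is fastest here)
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double rx = px[i] - px[j], ry = py[i] - py[j], rz = pz[i] - pz[j];
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 >= cut2) continue;
      if (r2 < 1e-24) { *bad_index = i + 1; return 2; }
      double s2 = p.sigma * p.sigma / r2;
      double s6 = s2 * s2 * s2, s12 = s6 * s6;
      double fr = 24.0 * p.eps * (2.0 * s12 - s6) / r2;
      fx[i] += fr * rx; fy[i] += fr * ry; fz[i] += fr * rz;
      fx[j] -= fr * rx; fy[j] -= fr * ry; fz[j] -= fr * rz;
      u += 4.0 * p.eps * (s12 - s6) + p.eps;
    }
  }
  // static wall + obstacles (per-bead Verlet lists over a cell grid)
  bool overlap = false;
  for (int i = 0; i < N; ++i) {
    if (env.n() == 0) break;
    if (pz[i] < env.zlo || pz[i] > env.zhi) continue;
    const std::vector<int>& list = nl.get(i, px[i], py[i], pz[i]);
    u += static_force_on(env, list, px[i], py[i], pz[i], p.eps,
                         &fx[i], &fy[i], &fz[i], &overlap);
    if (overlap) { *bad_index = i + 1; return 2; }
  }
  // analytic closure of the membrane beyond the particle lattice: WCA
  // planes at z = 0 and z = L for beads outside the tiled annulus, so the
  // membrane is effectively infinite and a dragged tail cannot be pulled
  // around its rim
  if (p.mem_extent > 0.0) {
    double rim = p.mem_extent - p.sigma;
    double rim2 = rim * rim;
    double cut = 1.1224620483093730 * p.sigma;
    for (int i = 0; i < N; ++i) {
      if (px[i] * px[i] + py[i] * py[i] <= rim2) continue;
      for (int plane = 0; plane < 2; ++plane) {
        double dz = pz[i] - (plane == 0 ? 0.0 : p.L);
        double r = std::fabs(dz);
        if (r >= cut) continue;
        if (r < 1e-12) { *bad_index = i + 1; return 2; }
        double s2 = p.sigma * p.sigma / (r * r);
        double s6 = s2 * s2 * s2, s12 = s6 * s6;
        fz[i] += 24.0 * p.eps * (2.0 * s12 - s6) / (r * r) * dz;
        u += 4.0 * p.eps * (s12 - s6) + p.eps;
      }
    }
  }
  // driving field along +z on beads inside the channel
  if (field_on && p.F != 0.0) {
    for (int i = 0; i < N; ++i) {
      if (p.field_everywhere || in_channel(px[i], py[i], pz[i], p))
        fz[i] += p.F;
    }
  }
  if (energy) *energy = u;
  return 0;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix wall, NumericMatrix obst,
                List pars, bool field_on) {
  Pars p = read_pars(pars);
  StaticEnv env;
  env.build(wall, obst, p.sigma, p.d);
  int N = pos.nrow();
  std::vector<double> px(N), py(N), pz(N), fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
  }
  NbrList nl;
  nl.init(&env, N);
  double u = 0.0; int bad = -1;
  int st = chain_forces(px, py, pz, env, nl, p, field_on, fx, fy, fz, &u,
                        &bad);
  NumericMatrix f(N, 3);
  for (int i = 0; i < N; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  return List::create(_["forces"] = f, _["energy"] = u,
                      _["status"] = st, _["bad_index"] = bad);
}

// ---------------------------------------------------------------------------
// GJF Langevin integrator (Gronbech-Jensen & Farago 2013): correct
// configurational sampling and free diffusion at finite dt.

struct Integrator {
  Pars p;
  const StaticEnv* env;
  NbrList nl;
  bool field_on;
  int tether; // 0-based bead index held fixed, or -1
  double tx, ty, tz;
  std::vector<double> fx, fy, fz, bx_, by_, bz_, ofx, ofy, ofz;
  int status;
  int bad_index;

  void init(const Pars& pars, const StaticEnv* e, bool field, int teth,
            int N) {
    p = pars; env = e; field_on = field; tether = teth;
    nl.init(e, N);
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
    bx_.assign(N, 0.0); by_.assign(N, 0.0); bz_.assign(N, 0.0);
    ofx.assign(N, 0.0); ofy.assign(N, 0.0); ofz.assign(N, 0.0);
    status = 0; bad_index = -1;
  }

  bool forces(std::vector<double>& px, std::vector<double>& py,
              std::vector<double>& pz) {
    status = chain_forces(px, py, pz, *env, nl, p, field_on, fx, fy, fz,
                          nullptr, &bad_index);
    return status == 0;
  }

  // one GJF step of length dt; positions/velocities updated in place
  bool gjf(std::vector<double>& px, std::vector<double>& py,
           std::vector<double>& pz, std::vector<double>& vx,
           std::vector<double>& vy, std::vector<double>& vz, RNG& rng,
           double dt) {
    int N = (int)px.size();
    double m = p.mass;
    double c = p.xi * dt / (2.0 * m);
    double b = 1.0 / (1.0 + c);
    double a = (1.0 - c) / (1.0 + c);
    double sdnoise = std::sqrt(2.0 * p.xi * p.kBT * dt);
    double hdt2m = dt / (2.0 * m);
    for (int i = 0; i < N; ++i) {
      if (i == tether) continue;
      bx_[i] = sdnoise * rng.gauss();
      by_[i] = sdnoise * rng.gauss();
      bz_[i] = sdnoise * rng.gauss();
      px[i] += b * dt * vx[i] + b * dt * hdt2m * fx[i] + b * hdt2m * bx_[i];
      py[i] += b * dt * vy[i] + b * dt * hdt2m * fy[i] + b * hdt2m * by_[i];
      pz[i] += b * dt * vz[i] + b * dt * hdt2m * fz[i] + b * hdt2m * bz_[i];
    }
    ofx = fx; ofy = fy; ofz = fz;
    if (!forces(px, py, pz)) return false;
    for (int i = 0; i < N; ++i) {
      if (i == tether) { vx[i] = vy[i] = vz[i] = 0.0; continue; }
      vx[i] = a * vx[i] + hdt2m * (a * ofx[i] + fx[i]) + (b / m) * bx_[i];
      vy[i] = a * vy[i] + hdt2m * (a * ofy[i] + fy[i]) + (b / m) * by_[i];
      vz[i] = a * vz[i] + hdt2m * (a * ofz[i] + fz[i]) + (b / m) * bz_[i];
    }
    if (tether >= 0) { px[tether] = tx; py[tether] = ty; pz[tether] = tz; }
    return true;
  }

  // stability limit for the current configuration: near the FENE
  // divergence the bond stiffness grows as ~2k/w^2 with w = 1 - r^2/R0^2,
  // giving a local frequency ~ sqrt(4k/m)/w; keep dt a small fraction of
  // its period. Away from the divergence (all bonds < 0.75 R0) the base
  // step is already safe.
  double safe_dt(const std::vector<double>& px,
                 const std::vector<double>& py,
                 const std::vector<double>& pz,
                 const std::vector<double>& vx,
                 const std::vector<double>& vy,
                 const std::vector<double>& vz) const {
    int N = (int)px.size();
    double wmin = 1.0;
    double margin_min = p.R0;
    double dts = p.dt;
    double thr2 = 0.5625 * p.R0 * p.R0; // (0.75 R0)^2
    for (int i = 0; i + 1 < N; ++i) {
      double rx = px[i + 1] - px[i], ry = py[i + 1] - py[i],
             rz = pz[i + 1] - pz[i];
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 > thr2) {
        double w = 1.0 - r2 / (p.R0 * p.R0);
        if (w < wmin) wmin = w;
        // a stretching bond must not cross its remaining margin to R0
        // in one substep, however fast the beads separate
        double r = std::sqrt(r2);
        double margin = p.R0 - r;
        if (margin < margin_min) margin_min = margin;
        double rate = ((vx[i + 1] - vx[i]) * rx + (vy[i + 1] - vy[i]) * ry +
                       (vz[i + 1] - vz[i]) * rz) / r;
        if (rate > 1e-9) {
          double lim = 0.2 * margin / rate;
          if (lim < dts) dts = lim;
        }
      }
    }
    if (wmin < 1.0) {
      double omega = std::sqrt(4.0 * p.k_spring / p.mass) /
        std::max(wmin, 1e-9);
      dts = std::min(dts, 0.05 / omega);
    }
    // displacement cap: no bead may move more than 0.03 sigma per
    // substep, so fast beads cannot tunnel through a repulsive shell
    double v2max = 0.0;
    for (int i = 0; i < N; ++i) {
      double v2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      if (v2 > v2max) v2max = v2;
    }
    if (v2max > 0.36) { // only throttles beads faster than ~thermal
      dts = std::min(dts, 0.03 * p.sigma / std::sqrt(v2max));
    }
    // force-driven displacement cap: a bead in deep overlap can be
    // accelerated across a repulsive shell within one substep even from
    // rest, so bound (f/m) dt^2 / 2 by the same 0.03 sigma
    double f2max = 0.0;
    for (int i = 0; i < N; ++i) {
      double f2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
      if (f2 > f2max) f2max = f2;
    }
    if (f2max > 1e4) { // inconsequential below ~100 eps/sigma
      double fmax = std::sqrt(f2max);
      double lim = std::sqrt(0.06 * p.sigma * p.mass / fmax);
      if (lim < dts) dts = lim;
      // and force-driven stretch of the tautest bond must stay well
      // inside its margin to R0 even starting from rest
      if (wmin < 1.0) {
        double lim2 = std::sqrt(0.05 * margin_min * p.mass / fmax);
        if (lim2 < dts) dts = lim2;
      }
    }
    return dts;
  }

  // advance exactly one base step dt, subdividing adaptively whenever a
  // bond approaches the FENE divergence (tension spikes under strong
  // driving); trajectories remain deterministic for a given stream
  bool step(std::vector<double>& px, std::vector<double>& py,
            std::vector<double>& pz, std::vector<double>& vx,
            std::vector<double>& vy, std::vector<double>& vz, RNG& rng) {
    double remaining = p.dt;
    double floor_dt = p.dt * 9.094947017729282e-13; // dt / 2^40
    long iter = 0;
    while (remaining > 1e-300) {
      if (++iter > 200000) { status = 1; bad_index = -1; return false; }
      double dts = safe_dt(px, py, pz, vx, vy, vz);
      if (dts < floor_dt) dts = floor_dt;
      if (dts > remaining) dts = remaining;
      if (!gjf(px, py, pz, vx, vy, vz, rng, dts)) return false;
      remaining -= dts;
    }
    return true;
  }
};

static double rg2_of(const std::vector<double>& px,
                     const std::vector<double>& py,
                     const std::vector<double>& pz) {
  int N = (int)px.size();
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < N; ++i) { cx += px[i]; cy += py[i]; cz += pz[i]; }
  cx /= N; cy /= N; cz /= N;
  double s = 0;
  for (int i = 0; i < N; ++i) {
    double dx = px[i] - cx, dy = py[i] - cy, dz = pz[i] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return s / N;
}

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix pos, NumericMatrix vel, NumericMatrix wall,
                   NumericMatrix obst, List pars, int n_steps,
                   double seed, int index, int stream, int tether,
                   bool field_on, int record_every, bool keep_frames) {
  Pars p = read_pars(pars);
  StaticEnv env;
  env.build(wall, obst, p.sigma, p.d);
  int N = pos.nrow();
  std::vector<double> px(N), py(N), pz(N), vx(N), vy(N), vz(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  RNG rng(stream_seed(seed, index, stream));
  Integrator I;
  I.init(p, &env, field_on, tether, N);
  if (tether >= 0) { I.tx = px[tether]; I.ty = py[tether]; I.tz = pz[tether]; }
  std::vector<double> rg_trace, temp_trace;
  List frames;
  std::vector<double> frame_times;
  int done = 0;
  if (!I.forces(px, py, pz)) {
    return List::create(_["status"] = I.status, _["bad_index"] = I.bad_index,
                        _["steps_done"] = 0);
  }
  for (int s = 0; s < n_steps; ++s) {
    if (!I.step(px, py, pz, vx, vy, vz, rng)) break;
    ++done;
    if (record_every > 0 && (done % record_every) == 0) {
      rg_trace.push_back(rg2_of(px, py, pz));
      double ke = 0; int nf = 0;
      for (int i = 0; i < N; ++i) {
        if (i == tether) continue;
        ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
        ++nf;
      }
      temp_trace.push_back(nf > 0 ? p.mass * ke / (3.0 * nf) : 0.0);
      if (keep_frames) {
        NumericMatrix fr(N, 3);
        for (int i = 0; i < N; ++i) {
          fr(i, 0) = px[i]; fr(i, 1) = py[i]; fr(i, 2) = pz[i];
        }
        frames.push_back(fr);
        frame_times.push_back(done * p.dt);
      }
    }
  }
  NumericMatrix opos(N, 3), ovel(N, 3);
  for (int i = 0; i < N; ++i) {
    opos(i, 0) = px[i]; opos(i, 1) = py[i]; opos(i, 2) = pz[i];
    ovel(i, 0) = vx[i]; ovel(i, 1) = vy[i]; ovel(i, 2) = vz[i];
  }
  return List::create(_["positions"] = opos, _["velocities"] = ovel,
                      _["status"] = I.status, _["bad_index"] = I.bad_index,
                      _["steps_done"] = done,
                      _["rg2_trace"] = NumericVector(rg_trace.begin(), rg_trace.end()),
                      _["temp_trace"] = NumericVector(temp_trace.begin(), temp_trace.end()),
                      _["frames"] = frames,
                      _["frame_times"] = NumericVector(frame_times.begin(), frame_times.end()));
}

// ---------------------------------------------------------------------------
// Obstacle placement: centres uniform over the accessible cylinder
// {0 <= z <= L, radial <= R - d/2}; overlaps between obstacles permitted.

// [[Rcpp::export]]
NumericMatrix cpp_place_obstacles(int n, double L, double R, double d,
                                  double sigma, double seed, int index,
                                  int stream) {
  RNG rng(stream_seed(seed, index, stream));
  NumericMatrix out(n, 3);
  double rmax = R - 0.5 * d;
  if (rmax < 0) rmax = 0;
  // keep the entrance mouth viable: the protocol places bead 1 at the
  // origin, so obstacle centres inside its WCA contact zone would embed
  // the tethered bead in an obstacle and blow up at release
  double clear2 = std::pow(1.1224620483093730 * 0.5 * (sigma + d), 2);
  for (int i = 0; i < n; ++i) {
    double x, y, z;
    do {
      double r = rmax * std::sqrt(rng.unif());
      double th = 6.283185307179586 * rng.unif();
      x = r * std::cos(th);
      y = r * std::sin(th);
      z = L * rng.unif();
    } while (x * x + y * y + z * z < clear2);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Chain growth: bead 1 at the pore entrance (origin), beads 2..N grown on
// the cis side (z <= 0) as a self-avoiding walk of bond length sigma,
// rejecting placements that overlap earlier beads or static particles.

// [[Rcpp::export]]
NumericMatrix cpp_grow_chain(int N, NumericMatrix wall, NumericMatrix obst,
                             List pars, double seed, int index, int stream,
                             int max_restarts) {
  Pars p = read_pars(pars);
  StaticEnv env;
  env.build(wall, obst, p.sigma, p.d);
  RNG rng(stream_seed(seed, index, stream));
  double bond = p.sigma;
  double min_sep = 0.9 * p.sigma;
  NumericMatrix out(N, 3);
  std::vector<double> px(N), py(N), pz(N);
  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    px[0] = 0.0; py[0] = 0.0; pz[0] = 0.0;
    bool ok = true;
    for (int i = 1; i < N && ok; ++i) {
      bool placed = false;
      for (int t = 0; t < 300; ++t) {
        // uniform direction
        double g1 = rng.gauss(), g2 = rng.gauss(), g3 = rng.gauss();
        double nrm = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3);
        if (nrm < 1e-12) continue;
        double cx = px[i - 1] + bond * g1 / nrm;
        double cy = py[i - 1] + bond * g2 / nrm;
        double cz = pz[i - 1] + bond * g3 / nrm;
        if (cz > 0.0) continue;
        bool clash = false;
        // membrane closure plane beyond the particle lattice
        if (p.mem_extent > 0.0) {
          double rim = p.mem_extent - p.sigma;
          if (cx * cx + cy * cy > rim * rim && cz > -0.9 * p.sigma)
            clash = true;
        }
        for (int j = 0; j < i - 1 && !clash; ++j) {
          double dx = cx - px[j], dy = cy - py[j], dz = cz - pz[j];
          if (dx * dx + dy * dy + dz * dz < min_sep * min_sep) clash = true;
        }
        if (!clash) {
          // static clash: any placement closer than 0.9 * pair sigma
          for (int j = 0; j < env.n() && !clash; ++j) {
            double dx = cx - env.x[j], dy = cy - env.y[j], dz = cz - env.z[j];
            double lim = 0.9 * env.sig[j];
            if (dx * dx + dy * dy + dz * dz < lim * lim) clash = true;
          }
        }
        if (!clash) { px[i] = cx; py[i] = cy; pz[i] = cz; placed = true; break; }
      }
      if (!placed) ok = false;
    }
    if (ok) {
      for (int i = 0; i < N; ++i) {
        out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
      }
      out.attr("restarts") = attempt;
      return out;
    }
  }
  stop("chain growth failed after %d restarts", max_restarts + 1);
}

// ---------------------------------------------------------------------------
// Translocation run: integrate with the field on until success (all beads
// have crossed z > L), retraction (all beads z < 0) or step cap. Records
// first entry/exit times per bead, beads-in-channel counts and gyration
// tensors at each new exit count s.

static void gyr6(const std::vector<double>& px, const std::vector<double>& py,
                 const std::vector<double>& pz, const std::vector<int>& idx,
                 double* t) {
  int M = (int)idx.size();
  double cx = 0, cy = 0, cz = 0;
  for (int q = 0; q < M; ++q) { cx += px[idx[q]]; cy += py[idx[q]]; cz += pz[idx[q]]; }
  cx /= M; cy /= M; cz /= M;
  for (int a = 0; a < 6; ++a) t[a] = 0.0;
  for (int q = 0; q < M; ++q) {
    double dx = px[idx[q]] - cx, dy = py[idx[q]] - cy, dz = pz[idx[q]] - cz;
    t[0] += dx * dx; t[1] += dy * dy; t[2] += dz * dz;
    t[3] += dx * dy; t[4] += dx * dz; t[5] += dy * dz;
  }
  for (int a = 0; a < 6; ++a) t[a] /= M;
}

// [[Rcpp::export]]
List cpp_run_event(NumericMatrix pos, NumericMatrix vel, NumericMatrix wall,
                   NumericMatrix obst, List pars, double seed, int index,
                   int stream, double max_steps, double stall_time,
                   bool keep_snapshots) {
  Pars p = read_pars(pars);
  StaticEnv env;
  env.build(wall, obst, p.sigma, p.d);
  int N = pos.nrow();
  std::vector<double> px(N), py(N), pz(N), vx(N), vy(N), vz(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  RNG rng(stream_seed(seed, index, stream));
  Integrator I;
  I.init(p, &env, true, -1, N);

  std::vector<double> entry(N, NA_REAL), exit_t(N, NA_REAL);
  std::vector<bool> entered(N, false), exited(N, false);
  std::vector<int> n_in_at_exit(N, NA_INTEGER);
  std::vector<double> exit_order(N, NA_REAL);
  NumericMatrix gyr_whole(N, 6), gyr_out(N, 6);
  std::fill(gyr_whole.begin(), gyr_whole.end(), NA_REAL);
  std::fill(gyr_out.begin(), gyr_out.end(), NA_REAL);
  List snaps(keep_snapshots ? N : 0);

  int s_count = 0;
  int success = 0;
  std::string failure = "none";
  double tau = NA_REAL;
  double t = 0.0;
  double step_count = 0.0;

  // bead 1 sits at the entrance: inside the channel at t = 0
  for (int i = 0; i < N; ++i) {
    if (in_channel(px[i], py[i], pz[i], p)) { entered[i] = true; entry[i] = 0.0; }
  }

  if (!I.forces(px, py, pz)) {
    return List::create(_["status"] = I.status, _["bad_index"] = I.bad_index,
                        _["n_steps"] = 0.0);
  }
  std::vector<int> all_idx(N), out_idx;
  for (int i = 0; i < N; ++i) all_idx[i] = i;

  bool done = false;
  bool stalled = false;
  double last_progress = 0.0;
  while (!done && step_count < max_steps) {
    if (!I.step(px, py, pz, vx, vy, vz, rng)) break;
    step_count += 1.0;
    t = step_count * p.dt;
    bool new_exit = false;
    for (int i = 0; i < N; ++i) {
      if (!entered[i] && in_channel(px[i], py[i], pz[i], p)) {
        entered[i] = true; entry[i] = t; last_progress = t;
      }
      if (!exited[i] && pz[i] > p.L) {
        exited[i] = true; exit_t[i] = t; new_exit = true;
        last_progress = t;
      }
    }
    if (new_exit) {
      int n_in = 0;
      for (int i = 0; i < N; ++i)
        if (in_channel(px[i], py[i], pz[i], p)) ++n_in;
      out_idx.clear();
      for (int i = 0; i < N; ++i) if (exited[i]) out_idx.push_back(i);
      int new_s = (int)out_idx.size();
      double tw[6], to[6];
      gyr6(px, py, pz, all_idx, tw);
      if (new_s >= 1) gyr6(px, py, pz, out_idx, to);
      for (int s = s_count; s < new_s; ++s) {
        n_in_at_exit[s] = n_in;
        exit_order[s] = t;
        for (int a = 0; a < 6; ++a) {
          gyr_whole(s, a) = tw[a];
          gyr_out(s, a) = to[a];
        }
        if (keep_snapshots) {
          NumericMatrix sn(N, 3);
          for (int i = 0; i < N; ++i) {
            sn(i, 0) = px[i]; sn(i, 1) = py[i]; sn(i, 2) = pz[i];
          }
          snaps[s] = sn;
        }
      }
      s_count = new_s;
      if (s_count == N) { success = 1; tau = t; done = true; }
    }
    if (!done) {
      // retraction: the whole chain back on the cis side, a full bead
      // diameter clear of the entrance plane (the start state has bead 1
      // exactly at z = 0, so the bare z < 0 test would fire immediately)
      bool all_cis = true;
      for (int i = 0; i < N; ++i) {
        if (pz[i] >= -p.sigma) { all_cis = false; break; }
      }
      if (all_cis) { failure = "retracted"; done = true; }
      // jam detection: no bead has newly entered or exited for a long
      // time; the chain is wedged against obstacles (or dawdling at the
      // entrance) and the attempt is abandoned as a timeout failure
      if (!done && stall_time > 0 && t - last_progress > stall_time) {
        stalled = true; done = true;
      }
    }
  }
  if (I.status != 0) {
    return List::create(_["status"] = I.status, _["bad_index"] = I.bad_index,
                        _["n_steps"] = step_count);
  }
  if (!done || stalled) failure = "timeout";
  if (success) failure = "none";

  NumericMatrix opos(N, 3), ovel(N, 3);
  for (int i = 0; i < N; ++i) {
    opos(i, 0) = px[i]; opos(i, 1) = py[i]; opos(i, 2) = pz[i];
    ovel(i, 0) = vx[i]; ovel(i, 1) = vy[i]; ovel(i, 2) = vz[i];
  }
  return List::create(
    _["status"] = 0, _["bad_index"] = -1,
    _["success"] = (bool)success, _["failure_mode"] = failure,
    _["tau"] = tau, _["n_steps"] = step_count,
    _["entry_times"] = NumericVector(entry.begin(), entry.end()),
    _["exit_times"] = NumericVector(exit_t.begin(), exit_t.end()),
    _["exit_order_times"] = NumericVector(exit_order.begin(), exit_order.end()),
    _["n_in_at_exit"] = IntegerVector(n_in_at_exit.begin(), n_in_at_exit.end()),
    _["gyr_whole"] = gyr_whole, _["gyr_out"] = gyr_out,
    _["snapshots"] = snaps,
    _["positions"] = opos, _["velocities"] = ovel);
}
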