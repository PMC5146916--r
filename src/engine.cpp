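// Core simulation kernels: WCA/FENE/tether force field, Verlet neighbor list
// with cell binning, and a BAOAB Langevin integrator with per-bead
// temperature, mass and frozen flags. Periodic in x-y only; z is open.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <sstream>
using namespace Rcpp;

static const double TWO16 = 1.122462048309373;  // 2^(1/6)

struct System {
  int n;
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<int> kind;    // 0=P 1=S 2=B 3=C
  std::vector<int> group;   // 0 polymer, 1 membrane
  std::vector<char> frozen;
  std::vector<double> mass, temp;
  // pair tables by kind pair (4x4): sigma^2 and cutoff^2
  double sig2[4][4], cut2[4][4];
  double eps;
  // bonds
  std::vector<int> b1, b2;
  std::vector<double> bR02, bK;  // max extension^2, stiffness
  // tethers: k per bead (0 = none), anchors
  std::vector<double> tk, ax, ay, az;
  double Lx, Ly;
  bool mm_pairs;            // include membrane-membrane interactions
  int pulled;               // -1 = none
  double Fpull;             // along +z
};

static inline void min_image(const System& s, double& dx, double& dy) {
  dx -= s.Lx * std::nearbyint(dx / s.Lx);
  dy -= s.Ly * std::nearbyint(dy / s.Ly);
}

static inline bool pair_active(const System& s, int i, int j) {
  if (!s.mm_pairs && s.group[i] == 1 && s.group[j] == 1) return false;
  return true;
}

// ---------------------------------------------------------------- neighbor list
// Two Verlet lists with separate cell sizes and staleness tracking:
//  * a polymer list (every pair with at least one polymer bead), binned at
//    the largest pair cutoff, outer loop over polymer beads only;
//  * a membrane-membrane list (kinetic mode), binned at the much smaller
//    C-C cutoff -- membrane sites are dense and nearly static, so this
//    list is cheap to hold and rarely rebuilt.
struct NeighborList {
  std::vector<int> pi, pj;  // polymer-involved pairs
  std::vector<int> mi, mj;  // membrane-membrane pairs
  std::vector<double> x0, y0, z0;     // baseline of the polymer list
  std::vector<double> mx0, my0, mz0;  // baseline of the membrane list
  double skin = 0.3;
  double mem_skin = 0.5;
  // During dynamics, pairs of two frozen beads are skipped: they can exert
  // forces only on each other and never move. Single-point force
  // evaluations keep them so reported forces/energies are complete.
  bool skip_frozen_pairs = false;

  void build(const System& s) { build_poly(s); build_mem(s); }

  void build_poly(const System& s) {
    const int n = s.n;
    pi.clear(); pj.clear();
    x0.assign(s.x.begin(), s.x.end());
    y0.assign(s.y.begin(), s.y.end());
    z0.assign(s.z.begin(), s.z.end());
    double max_cut = 0.0;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        max_cut = std::max(max_cut, std::sqrt(s.cut2[a][b]));
    const double rl = max_cut + skin, rl2 = rl * rl;

    // outer beads: polymer only (membrane partners are always accepted, so
    // every polymer-membrane pair is generated exactly once)
    auto outer_ok = [&](int i) {
      return s.group[i] == 0 && !(skip_frozen_pairs && s.frozen[i]);
    };
    auto accept = [&](int i, int j) {
      if (j == i) return false;
      if (s.group[j] == 1) return true;
      if (skip_frozen_pairs && s.frozen[j]) return !s.frozen[i];
      return j > i;
    };
    auto try_pair = [&](int i, int j) {
      double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
      min_image(s, dx, dy);
      if (dx * dx + dy * dy + dz * dz < rl2) { pi.push_back(i); pj.push_back(j); }
    };

    const double fx = std::floor(s.Lx / rl), fy = std::floor(s.Ly / rl);
    const int ncx = (int)std::min(fx, 1e4), ncy = (int)std::min(fy, 1e4);
    // brute-force build for small systems and effectively open (huge or
    // tiny) boxes where cell binning is useless
    if (ncx < 3 || ncy < 3 || n < 64 || fx * fy > 16.0 * n) {
      for (int i = 0; i < n; ++i) {
        if (!outer_ok(i)) continue;
        for (int j = 0; j < n; ++j) if (accept(i, j)) try_pair(i, j);
      }
      return;
    }
    double zmin = s.z[0], zmax = s.z[0];
    for (int i = 1; i < n; ++i) { zmin = std::min(zmin, s.z[i]); zmax = std::max(zmax, s.z[i]); }
    const int ncz = std::max(1, (int)std::floor((zmax - zmin) / rl) + 1);
    const double cwx = s.Lx / ncx, cwy = s.Ly / ncy;
    std::vector<int> head(ncx * ncy * ncz, -1), nxt(n, -1);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      double xw = s.x[i] - s.Lx * std::floor(s.x[i] / s.Lx);
      double yw = s.y[i] - s.Ly * std::floor(s.y[i] / s.Ly);
      int a = std::min(ncx - 1, (int)(xw / cwx));
      int b = std::min(ncy - 1, (int)(yw / cwy));
      int c = std::min(ncz - 1, (int)((s.z[i] - zmin) / rl));
      ci[i] = a; cj[i] = b; ck[i] = c;
      int cell = (c * ncy + b) * ncx + a;
      nxt[i] = head[cell]; head[cell] = i;
    }
    for (int i = 0; i < n; ++i) {
      if (!outer_ok(i)) continue;
      for (int dc = -1; dc <= 1; ++dc) {
        int c = ck[i] + dc;
        if (c < 0 || c >= ncz) continue;
        for (int db = -1; db <= 1; ++db) {
          int b = (cj[i] + db + ncy) % ncy;
          for (int da = -1; da <= 1; ++da) {
            int a = (ci[i] + da + ncx) % ncx;
            for (int j = head[(c * ncy + b) * ncx + a]; j != -1; j = nxt[j])
              if (accept(i, j)) try_pair(i, j);
          }
        }
      }
    }
  }

  void build_mem(const System& s) {
    mi.clear(); mj.clear();
    mx0.assign(s.x.begin(), s.x.end());
    my0.assign(s.y.begin(), s.y.end());
    mz0.assign(s.z.begin(), s.z.end());
    if (!s.mm_pairs) return;
    std::vector<int> mem;
    for (int i = 0; i < s.n; ++i) if (s.group[i] == 1) mem.push_back(i);
    const int nm = (int)mem.size();
    if (nm < 2) return;
    const double rl = std::sqrt(s.cut2[3][3]) + mem_skin, rl2 = rl * rl;
    auto try_pair = [&](int i, int j) {
      double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
      min_image(s, dx, dy);
      if (dx * dx + dy * dy + dz * dz < rl2) { mi.push_back(i); mj.push_back(j); }
    };
    const double fx = std::floor(s.Lx / rl), fy = std::floor(s.Ly / rl);
    const int ncx = (int)std::min(fx, 1e4), ncy = (int)std::min(fy, 1e4);
    if (ncx < 3 || ncy < 3 || nm < 64 || fx * fy > 16.0 * nm) {
      for (int a = 0; a < nm; ++a)
        for (int b = a + 1; b < nm; ++b) try_pair(mem[a], mem[b]);
      return;
    }
    double zmin = s.z[mem[0]], zmax = s.z[mem[0]];
    for (int q : mem) { zmin = std::min(zmin, s.z[q]); zmax = std::max(zmax, s.z[q]); }
    const int ncz = std::max(1, (int)std::floor((zmax - zmin) / rl) + 1);
    const double cwx = s.Lx / ncx, cwy = s.Ly / ncy;
    std::vector<int> head(ncx * ncy * ncz, -1), nxt(s.n, -1);
    std::vector<int> ci(s.n), cj(s.n), ck(s.n);
    for (int q : mem) {
      double xw = s.x[q] - s.Lx * std::floor(s.x[q] / s.Lx);
      double yw = s.y[q] - s.Ly * std::floor(s.y[q] / s.Ly);
      int a = std::min(ncx - 1, (int)(xw / cwx));
      int b = std::min(ncy - 1, (int)(yw / cwy));
      int c = std::min(ncz - 1, (int)((s.z[q] - zmin) / rl));
      ci[q] = a; cj[q] = b; ck[q] = c;
      int cell = (c * ncy + b) * ncx + a;
      nxt[q] = head[cell]; head[cell] = q;
    }
    for (int q : mem) {
      for (int dc = -1; dc <= 1; ++dc) {
        int c = ck[q] + dc;
        if (c < 0 || c >= ncz) continue;
        for (int db = -1; db <= 1; ++db) {
          int b = (cj[q] + db + ncy) % ncy;
          for (int da = -1; da <= 1; ++da) {
            int a = (ci[q] + da + ncx) % ncx;
            for (int j = head[(c * ncy + b) * ncx + a]; j != -1; j = nxt[j])
              if (j > q) try_pair(q, j);
          }
        }
      }
    }
  }

  bool stale_poly(const System& s) const {
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < s.n; ++i) {
      if (s.frozen[i]) continue;
      double dx = s.x[i] - x0[i], dy = s.y[i] - y0[i], dz = s.z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  bool stale_mem(const System& s) const {
    const double lim2 = 0.25 * mem_skin * mem_skin;
    for (int i = 0; i < s.n; ++i) {
      if (s.group[i] != 1 || s.frozen[i]) continue;
      double dx = s.x[i] - mx0[i], dy = s.y[i] - my0[i], dz = s.z[i] - mz0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------- forces
// Returns potential energy; fills fx,fy,fz. Throws on broken bond.
static double compute_forces(const System& s, const NeighborList* nl,
                             std::vector<double>& fx, std::vector<double>& fy,
                             std::vector<double>& fz, long step_for_error = -1) {
  const int n = s.n;
  fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
  double U = 0.0;

  auto pair_term = [&](int i, int j) {
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    min_image(s, dx, dy);
    const double r2 = dx * dx + dy * dy + dz * dz;
    const int a = s.kind[i], b = s.kind[j];
    if (r2 >= s.cut2[a][b]) return;
    const double sr2 = s.sig2[a][b] / r2;
    const double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    U += 4.0 * s.eps * (sr12 - sr6) + s.eps;
    const double fmag = 24.0 * s.eps * (2.0 * sr12 - sr6) / r2;  // F/r, >= 0
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  };

  if (nl) {
    for (size_t p = 0; p < nl->pi.size(); ++p) pair_term(nl->pi[p], nl->pj[p]);
    for (size_t p = 0; p < nl->mi.size(); ++p) pair_term(nl->mi[p], nl->mj[p]);
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (pair_active(s, i, j)) pair_term(i, j);
  }

  for (size_t m = 0; m < s.b1.size(); ++m) {
    const int i = s.b1[m], j = s.b2[m];
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    min_image(s, dx, dy);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= s.bR02[m]) {
      std::ostringstream msg;
      msg << "FENE bond " << m + 1 << " (beads " << i + 1 << "-" << j + 1
          << ") exceeded its maximum extension";
      if (step_for_error >= 0) msg << " at step " << step_for_error;
      msg << "; reduce the time step or the applied force";
      stop(msg.str());
    }
    const double w = 1.0 - r2 / s.bR02[m];
    U += -0.5 * s.bK[m] * s.bR02[m] * std::log(w);
    const double fmag = -s.bK[m] / w;  // attractive
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }

  for (int i = 0; i < n; ++i) {
    if (s.tk[i] > 0.0) {
      const double dx = s.x[i] - s.ax[i], dy = s.y[i] - s.ay[i], dz = s.z[i] - s.az[i];
      U += 0.5 * s.tk[i] * (dx * dx + dy * dy + dz * dz);
      fx[i] -= s.tk[i] * dx; fy[i] -= s.tk[i] * dy; fz[i] -= s.tk[i] * dz;
    }
  }
  if (s.pulled >= 0) fz[s.pulled] += s.Fpull;

  for (int i = 0; i < n; ++i)
    if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]) || !std::isfinite(fz[i]))
      stop("non-finite force on bead %d", i + 1);
  return U;
}

static System unpack(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
                     IntegerVector group, LogicalVector frozen, NumericVector mass,
                     NumericVector temp, NumericMatrix sigma, double eps,
                     IntegerMatrix bonds, NumericVector bond_R0, NumericVector bond_K,
                     NumericVector tether_k, NumericMatrix anchor,
                     double Lx, double Ly, bool mm_pairs, int pulled, double Fpull) {
  System s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.vx.resize(s.n); s.vy.resize(s.n); s.vz.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
  }
  s.kind = as<std::vector<int>>(kind);
  s.group = as<std::vector<int>>(group);
  s.frozen.resize(s.n);
  for (int i = 0; i < s.n; ++i) s.frozen[i] = frozen[i] ? 1 : 0;
  s.mass = as<std::vector<double>>(mass);
  s.temp = as<std::vector<double>>(temp);
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      const double sg = sigma(a, b);
      s.sig2[a][b] = sg * sg;
      s.cut2[a][b] = TWO16 * TWO16 * sg * sg;
    }
  s.eps = eps;
  const int m = bonds.nrow();
  s.b1.resize(m); s.b2.resize(m); s.bR02.resize(m); s.bK.resize(m);
  for (int q = 0; q < m; ++q) {
    s.b1[q] = bonds(q, 0); s.b2[q] = bonds(q, 1);
    s.bR02[q] = bond_R0[q] * bond_R0[q];
    s.bK[q] = bond_K[q];
  }
  s.tk = as<std::vector<double>>(tether_k);
  s.ax.resize(s.n); s.ay.resize(s.n); s.az.resize(s.n);
  for (int i = 0; i < s.n; ++i) { s.ax[i] = anchor(i, 0); s.ay[i] = anchor(i, 1); s.az[i] = anchor(i, 2); }
  s.Lx = Lx; s.Ly = Ly;
  s.mm_pairs = mm_pairs;
  s.pulled = pulled;
  s.Fpull = Fpull;
  return s;
}

// Single force evaluation, neighbor-list or brute-force path.
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
                IntegerVector group, LogicalVector frozen, NumericVector mass,
                NumericVector temp, NumericMatrix sigma, double eps,
                IntegerMatrix bonds, NumericVector bond_R0, NumericVector bond_K,
                NumericVector tether_k, NumericMatrix anchor,
                double Lx, double Ly, bool mm_pairs, int pulled, double Fpull,
                std::string method, double skin) {
  System s = unpack(pos, vel, kind, group, frozen, mass, temp, sigma, eps,
                    bonds, bond_R0, bond_K, tether_k, anchor, Lx, Ly,
                    mm_pairs, pulled, Fpull);
  std::vector<double> fx, fy, fz;
  double U;
  if (method == "brute") {
    U = compute_forces(s, nullptr, fx, fy, fz);
  } else {
    NeighborList nl;
    nl.skin = skin;
    nl.build(s);
    U = compute_forces(s, &nl, fx, fy, fz);
  }
  NumericMatrix F(s.n, 3);
  for (int i = 0; i < s.n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["forces"] = F, _["energy"] = U);
}

// BAOAB Langevin run with optional sampling and translocation observers.
// Uses R's RNG (reproducible under set.seed). status: 0 = budget exhausted,
// 1 = translocated, 2 = failed slide.
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
             IntegerVector group, LogicalVector frozen, NumericVector mass,
             NumericVector temp, NumericMatrix sigma, double eps,
             IntegerMatrix bonds, NumericVector bond_R0, NumericVector bond_K,
             NumericVector tether_k, NumericMatrix anchor,
             double Lx, double Ly, bool mm_pairs, int pulled, double Fpull,
             double xi, double dt, double n_steps_d, double skin,
             int sample_stride,
             bool transloc_mode, int check_stride, double slab_half,
             double fail_r2, double fail_sustain_steps,
             IntegerVector rim_idx, double rim_sigma, int reff_stride,
             int traj_stride, int traj_max_frames) {
  System s = unpack(pos, vel, kind, group, frozen, mass, temp, sigma, eps,
                    bonds, bond_R0, bond_K, tether_k, anchor, Lx, Ly,
                    mm_pairs, pulled, Fpull);
  const long n_steps = (long)n_steps_d;
  const int n = s.n;

  // per-bead OU coefficients
  std::vector<double> c1(n), sv(n);
  for (int i = 0; i < n; ++i) {
    c1[i] = (xi > 0.0) ? std::exp(-xi * dt / s.mass[i]) : 1.0;
    sv[i] = std::sqrt(std::max(0.0, s.temp[i] * (1.0 - c1[i] * c1[i]) / s.mass[i]));
  }

  NeighborList nl;
  nl.skin = skin;
  nl.skip_frozen_pairs = true;
  nl.build(s);
  std::vector<double> fx, fy, fz;
  compute_forces(s, &nl, fx, fy, fz, 0);

  std::vector<int> mob;
  for (int i = 0; i < n; ++i) if (!s.frozen[i]) mob.push_back(i);

  // polymer bookkeeping
  std::vector<int> poly;
  for (int i = 0; i < n; ++i) if (s.group[i] == 0) poly.push_back(i);
  const int npoly = (int)poly.size();
  std::vector<int> mem;
  for (int i = 0; i < n; ++i) if (s.group[i] == 1) mem.push_back(i);

  // sampling buffers
  std::vector<double> samp;  // rows: t, com xyz, rg, ke_p, ke_m, tvar xyz
  const int SCOL = 10;
  std::vector<double> sumv2(n, 0.0);
  long n_samples = 0;

  std::vector<double> wait(npoly, 0.0);
  std::vector<double> reff_t, reff_v;
  std::vector<double> traj;
  int traj_frames = 0;

  int status = 0;
  double tau = NA_REAL;
  long steps_done = 0;
  double fail_acc = 0.0;

  auto record_sample = [&]() {
    double cx = 0, cy = 0, cz = 0, mtot = 0;
    for (int q : poly) { cx += s.mass[q] * s.x[q]; cy += s.mass[q] * s.y[q]; cz += s.mass[q] * s.z[q]; mtot += s.mass[q]; }
    cx /= mtot; cy /= mtot; cz /= mtot;
    double rg2 = 0;
    for (int q : poly) {
      const double dx = s.x[q] - cx, dy = s.y[q] - cy, dz = s.z[q] - cz;
      rg2 += s.mass[q] * (dx * dx + dy * dy + dz * dz);
    }
    rg2 /= mtot;
    double kep = 0, kem = 0;
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      const double k2 = 0.5 * s.mass[i] * (s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i]);
      if (s.group[i] == 0) kep += k2; else kem += k2;
      sumv2[i] += s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i];
    }
    double tvx = 0, tvy = 0, tvz = 0;
    int nteth = 0;
    for (int i : mem) {
      if (s.tk[i] <= 0.0 || s.frozen[i]) continue;
      const double dx = s.x[i] - s.ax[i], dy = s.y[i] - s.ay[i], dz = s.z[i] - s.az[i];
      tvx += dx * dx; tvy += dy * dy; tvz += dz * dz; ++nteth;
    }
    if (nteth > 0) { tvx /= nteth; tvy /= nteth; tvz /= nteth; }
    const double t = (double)steps_done * dt;
    samp.push_back(t); samp.push_back(cx); samp.push_back(cy); samp.push_back(cz);
    samp.push_back(std::sqrt(rg2)); samp.push_back(kep); samp.push_back(kem);
    samp.push_back(tvx); samp.push_back(tvy); samp.push_back(tvz);
    ++n_samples;
  };

  auto record_reff = [&]() {
    if (rim_idx.size() == 0) return;
    double rmin = R_PosInf;
    for (int q = 0; q < rim_idx.size(); ++q) {
      const int i = rim_idx[q];
      const double d = std::sqrt(s.x[i] * s.x[i] + s.y[i] * s.y[i]);
      rmin = std::min(rmin, d - rim_sigma);
    }
    reff_t.push_back((double)steps_done * dt);
    reff_v.push_back(rmin);
  };

  if (sample_stride > 0) record_sample();
  if (transloc_mode && reff_stride > 0) record_reff();

  for (long step = 1; step <= n_steps; ++step) {
    // B
    for (int i : mob) {
      const double h = 0.5 * dt / s.mass[i];
      s.vx[i] += h * fx[i]; s.vy[i] += h * fy[i]; s.vz[i] += h * fz[i];
    }
    // A
    for (int i : mob) {
      s.x[i] += 0.5 * dt * s.vx[i]; s.y[i] += 0.5 * dt * s.vy[i]; s.z[i] += 0.5 * dt * s.vz[i];
    }
    // O; beads at T = 0 keep the friction decay but draw no noise
    if (xi > 0.0) {
      for (int i : mob) {
        if (sv[i] > 0.0) {
          s.vx[i] = c1[i] * s.vx[i] + sv[i] * norm_rand();
          s.vy[i] = c1[i] * s.vy[i] + sv[i] * norm_rand();
          s.vz[i] = c1[i] * s.vz[i] + sv[i] * norm_rand();
        } else {
          s.vx[i] *= c1[i]; s.vy[i] *= c1[i]; s.vz[i] *= c1[i];
        }
      }
    }
    // A
    for (int i : mob) {
      s.x[i] += 0.5 * dt * s.vx[i]; s.y[i] += 0.5 * dt * s.vy[i]; s.z[i] += 0.5 * dt * s.vz[i];
    }
    if (nl.stale_poly(s)) nl.build_poly(s);
    if (s.mm_pairs && nl.stale_mem(s)) nl.build_mem(s);
    compute_forces(s, &nl, fx, fy, fz, step);
    // B
    for (int i : mob) {
      const double h = 0.5 * dt / s.mass[i];
      s.vx[i] += h * fx[i]; s.vy[i] += h * fy[i]; s.vz[i] += h * fz[i];
    }
    steps_done = step;

    if (transloc_mode) {
      for (int q = 0; q < npoly; ++q)
        if (std::fabs(s.z[poly[q]]) < slab_half) wait[q] += dt;
      if (reff_stride > 0 && step % reff_stride == 0) record_reff();
      if (step % check_stride == 0) {
        bool all_trans = true, any_trans = false;
        for (int q : poly) {
          if (s.z[q] > 0.0) any_trans = true; else all_trans = false;
        }
        if (all_trans) { status = 1; tau = (double)step * dt; break; }
        // failed slide: the chain has abandoned the pore -- the pulled bead
        // is far from the pore axis on the cis side and no bead has crossed
        if (fail_r2 < R_PosInf && s.pulled >= 0 && !any_trans) {
          const double lat2 = s.x[s.pulled] * s.x[s.pulled] + s.y[s.pulled] * s.y[s.pulled];
          if (s.z[s.pulled] < 0.0 && lat2 > fail_r2) {
            fail_acc += check_stride;
            if (fail_acc >= fail_sustain_steps) { status = 2; break; }
          } else fail_acc = 0.0;
        }
      }
    }
    if (sample_stride > 0 && step % sample_stride == 0) record_sample();
    if (traj_stride > 0 && step % traj_stride == 0 && traj_frames < traj_max_frames) {
      for (int i = 0; i < n; ++i) { traj.push_back(s.x[i]); traj.push_back(s.y[i]); traj.push_back(s.z[i]); }
      ++traj_frames;
    }
    if (step % 100000 == 0) checkUserInterrupt();
  }

  NumericMatrix outpos(n, 3), outvel(n, 3);
  for (int i = 0; i < n; ++i) {
    outpos(i, 0) = s.x[i]; outpos(i, 1) = s.y[i]; outpos(i, 2) = s.z[i];
    outvel(i, 0) = s.vx[i]; outvel(i, 1) = s.vy[i]; outvel(i, 2) = s.vz[i];
  }
  NumericMatrix smat(n_samples, SCOL);
  for (long r = 0; r < n_samples; ++r)
    for (int c = 0; c < SCOL; ++c) smat(r, c) = samp[r * SCOL + c];
  colnames(smat) = CharacterVector::create("time", "com_x", "com_y", "com_z", "rg",
                                           "ke_poly", "ke_mem", "tvar_x", "tvar_y", "tvar_z");
  List out = List::create(
    _["pos"] = outpos, _["vel"] = outvel,
    _["steps"] = (double)steps_done, _["status"] = status, _["tau"] = tau,
    _["samples"] = smat, _["sumv2"] = wrap(sumv2), _["n_samples"] = (double)n_samples,
    _["waiting"] = wrap(wait),
    _["reff_time"] = wrap(reff_t), _["reff"] = wrap(reff_v));
  if (traj_frames > 0) {
    NumericMatrix tm(traj_frames * n, 3);
    for (int r = 0; r < traj_frames * n; ++r)
      for (int c = 0; c < 3; ++c) tm(r, c) = traj[r * 3 + c];
    out["traj"] = tm;
    out["traj_frames"] = traj_frames;
  }
  return out;
}
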