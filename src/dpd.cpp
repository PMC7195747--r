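// DPD force kernels and integration loop.
//
// Pair noise is counter-based: theta_ij for a step is a pure function of
// (seed, global step, min(i,j), max(i,j)), so trajectories are independent
// of pair iteration order and restart-exact.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// uniform on [-sqrt(3), sqrt(3)]: zero mean, unit variance
static inline double pair_noise(uint64_t seed, uint64_t step, int i, int j) {
  int lo = i < j ? i : j, hi = i < j ? j : i;
  uint64_t k = splitmix64(seed ^ splitmix64(step ^ splitmix64(((uint64_t)lo << 32) | (uint64_t)(uint32_t)hi)));
  double u = (double)(k >> 11) * (1.0 / 9007199254740992.0); // [0,1)
  return (2.0 * u - 1.0) * 1.7320508075688772;
}

struct Box {
  double L[3];
  bool per[3];
  inline double mi(double d, int ax) const {
    if (per[ax]) d -= L[ax] * std::round(d / L[ax]);
    return d;
  }
  inline double wrap(double x, int ax) const {
    if (!per[ax]) return x;
    x -= L[ax] * std::floor(x / L[ax]);
    if (x >= L[ax]) x -= L[ax];
    return x;
  }
};

struct Sys {
  int n;
  Box box;
  std::vector<int> type;
  int ntype;
  std::vector<double> A;          // ntype x ntype repulsion
  std::vector<double> mass, charge;
  double gamma, sigma, dt;
  uint64_t seed;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  // optional fields
  bool elec;
  double elecC, elecCut, elecSmear;
  double grav[3];
};

struct ForceOut {
  std::vector<double> f;  // 3n
  double epotPair, epotBond;
  double vir[3];          // diagonal virial (conservative + bond)
  void reset(int n) {
    f.assign(3 * (size_t)n, 0.0);
    epotPair = epotBond = 0.0;
    vir[0] = vir[1] = vir[2] = 0.0;
  }
};

// conservative (+ optionally dissipative/random) force for one pair
static inline void pair_kernel(const Sys& S, const double* x, const double* v,
                               int i, int j, uint64_t step, bool thermostat,
                               double invSqrtDt, ForceOut& out) {
  double dx = S.box.mi(x[3 * i] - x[3 * j], 0);
  double dy = S.box.mi(x[3 * i + 1] - x[3 * j + 1], 1);
  double dz = S.box.mi(x[3 * i + 2] - x[3 * j + 2], 2);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= 1.0) return;
  double a = S.A[(size_t)S.type[i] * S.ntype + S.type[j]];
  double r = std::sqrt(r2);
  double w = 1.0 - r;
  out.epotPair += 0.5 * a * w * w;
  if (r < 1e-12) return;  // coincident: zero direction
  double ex = dx / r, ey = dy / r, ez = dz / r;
  double fmag = a * w;
  if (thermostat) {
    double dvx = v[3 * i] - v[3 * j];
    double dvy = v[3 * i + 1] - v[3 * j + 1];
    double dvz = v[3 * i + 2] - v[3 * j + 2];
    double ev = ex * dvx + ey * dvy + ez * dvz;
    fmag += -S.gamma * w * w * ev;
    fmag += S.sigma * w * pair_noise(S.seed, step, i, j) * invSqrtDt;
  }
  double fx = fmag * ex, fy = fmag * ey, fz = fmag * ez;
  out.f[3 * i] += fx; out.f[3 * i + 1] += fy; out.f[3 * i + 2] += fz;
  out.f[3 * j] -= fx; out.f[3 * j + 1] -= fy; out.f[3 * j + 2] -= fz;
  double cf = a * w;  // conservative part only enters the virial
  out.vir[0] += dx * cf * ex;
  out.vir[1] += dy * cf * ey;
  out.vir[2] += dz * cf * ez;
}

// all short-range pair forces via linked cells (all-pairs fallback for
// small or thin boxes)
static void pair_forces(const Sys& S, const double* x, const double* v,
                        uint64_t step, bool thermostat, ForceOut& out) {
  double invSqrtDt = 1.0 / std::sqrt(S.dt);
  int nc[3];
  bool cells = S.n > 64;
  for (int ax = 0; ax < 3; ++ax) {
    nc[ax] = (int)std::floor(S.box.L[ax]);
    if (nc[ax] < 3) cells = false;
  }
  if (!cells) {
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j)
        pair_kernel(S, x, v, i, j, step, thermostat, invSqrtDt, out);
    return;
  }
  int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  int ncell = ncx * ncy * ncz;
  std::vector<int> head(ncell, -1), nxt(S.n, -1);
  std::vector<int> ci(S.n), cj(S.n), ck(S.n);
  for (int p = 0; p < S.n; ++p) {
    int ix = (int)(S.box.wrap(x[3 * p], 0) / S.box.L[0] * ncx); if (ix >= ncx) ix = ncx - 1; if (ix < 0) ix = 0;
    int iy = (int)(S.box.wrap(x[3 * p + 1], 1) / S.box.L[1] * ncy); if (iy >= ncy) iy = ncy - 1; if (iy < 0) iy = 0;
    int iz = (int)(S.box.wrap(x[3 * p + 2], 2) / S.box.L[2] * ncz); if (iz >= ncz) iz = ncz - 1; if (iz < 0) iz = 0;
    ci[p] = ix; cj[p] = iy; ck[p] = iz;
    int c = (ix * ncy + iy) * ncz + iz;
    nxt[p] = head[c]; head[c] = p;
  }
  // half neighbor stencil: self + 13 neighbors
  static const int stencil[14][3] = {
    {0,0,0},{1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  for (int ix = 0; ix < ncx; ++ix)
    for (int iy = 0; iy < ncy; ++iy)
      for (int iz = 0; iz < ncz; ++iz) {
        int c = (ix * ncy + iy) * ncz + iz;
        for (int s = 0; s < 14; ++s) {
          int jx = ix + stencil[s][0], jy = iy + stencil[s][1], jz = iz + stencil[s][2];
          if (S.box.per[0]) { jx = (jx + ncx) % ncx; } else if (jx < 0 || jx >= ncx) continue;
          if (S.box.per[1]) { jy = (jy + ncy) % ncy; } else if (jy < 0 || jy >= ncy) continue;
          if (S.box.per[2]) { jz = (jz + ncz) % ncz; } else if (jz < 0 || jz >= ncz) continue;
          int c2 = (jx * ncy + jy) * ncz + jz;
          for (int p = head[c]; p >= 0; p = nxt[p]) {
            int qstart = (s == 0) ? nxt[p] : head[c2];
            for (int q = qstart; q >= 0; q = nxt[q])
              pair_kernel(S, x, v, p, q, step, thermostat, invSqrtDt, out);
          }
        }
      }
}

static void bond_forces(const Sys& S, const double* x, ForceOut& out) {
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    double dx = S.box.mi(x[3 * i] - x[3 * j], 0);
    double dy = S.box.mi(x[3 * i + 1] - x[3 * j + 1], 1);
    double dz = S.box.mi(x[3 * i + 2] - x[3 * j + 2], 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - S.br0[b];
    out.epotBond += 0.5 * S.bk[b] * d * d;
    if (r < 1e-12) continue;
    double fmag = -S.bk[b] * d;
    double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
    out.f[3 * i] += fx; out.f[3 * i + 1] += fy; out.f[3 * i + 2] += fz;
    out.f[3 * j] -= fx; out.f[3 * j + 1] -= fy; out.f[3 * j + 2] -= fz;
    out.vir[0] += dx * fx; out.vir[1] += dy * fy; out.vir[2] += dz * fz;
  }
}

// optional fields: smeared truncated Coulomb (all pairs; its cutoff
// exceeds r_c) and uniform gravity
static void field_forces(const Sys& S, const double* x, ForceOut& out) {
  if (S.elec) {
    double s2 = S.elecSmear * S.elecSmear;
    for (int i = 0; i < S.n; ++i) {
      if (S.charge[i] == 0.0) continue;
      for (int j = i + 1; j < S.n; ++j) {
        if (S.charge[j] == 0.0) continue;
        double dx = S.box.mi(x[3 * i] - x[3 * j], 0);
        double dy = S.box.mi(x[3 * i + 1] - x[3 * j + 1], 1);
        double dz = S.box.mi(x[3 * i + 2] - x[3 * j + 2], 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        double r = std::sqrt(r2);
        if (r >= S.elecCut) continue;
        double taper = 1.0 - r / S.elecCut;
        double fmag = S.elecC * S.charge[i] * S.charge[j] * taper * taper / (r2 + s2);
        if (r < 1e-12) continue;
        double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
        out.f[3 * i] += fx; out.f[3 * i + 1] += fy; out.f[3 * i + 2] += fz;
        out.f[3 * j] -= fx; out.f[3 * j + 1] -= fy; out.f[3 * j + 2] -= fz;
      }
    }
  }
  if (S.grav[0] != 0 || S.grav[1] != 0 || S.grav[2] != 0) {
    for (int i = 0; i < S.n; ++i) {
      out.f[3 * i] += S.mass[i] * S.grav[0];
      out.f[3 * i + 1] += S.mass[i] * S.grav[1];
      out.f[3 * i + 2] += S.mass[i] * S.grav[2];
    }
  }
}

static void total_forces(const Sys& S, const double* x, const double* v,
                         uint64_t step, bool thermostat, ForceOut& out) {
  out.reset(S.n);
  pair_forces(S, x, v, step, thermostat, out);
  bond_forces(S, x, out);
  field_forces(S, x, out);
}

static Sys make_sys(const NumericMatrix& pos, const NumericVector& box,
                    const LogicalVector& periodic, const IntegerVector& type0,
                    const NumericMatrix& aTable, const NumericVector& mass,
                    const NumericVector& charge, double gamma, double sigma,
                    double dt, double seed, const IntegerMatrix& bonds,
                    const NumericVector& bondK, const NumericVector& bondR0,
                    bool elec, double elecC, double elecCut, double elecSmear,
                    const NumericVector& gravity) {
  Sys S;
  S.n = pos.nrow();
  for (int ax = 0; ax < 3; ++ax) { S.box.L[ax] = box[ax]; S.box.per[ax] = periodic[ax]; }
  S.type.assign(type0.begin(), type0.end());
  S.ntype = aTable.nrow();
  S.A.assign(aTable.begin(), aTable.end());
  // NumericMatrix is column-major; table is symmetric so layout is immaterial
  S.mass.assign(mass.begin(), mass.end());
  S.charge.assign(charge.begin(), charge.end());
  S.gamma = gamma; S.sigma = sigma; S.dt = dt;
  S.seed = (uint64_t)seed;
  int nb = bonds.nrow();
  S.bi.resize(nb); S.bj.resize(nb);
  for (int b = 0; b < nb; ++b) { S.bi[b] = bonds(b, 0); S.bj[b] = bonds(b, 1); }
  S.bk.assign(bondK.begin(), bondK.end());
  S.br0.assign(bondR0.begin(), bondR0.end());
  S.elec = elec; S.elecC = elecC; S.elecCut = elecCut; S.elecSmear = elecSmear;
  S.grav[0] = gravity[0]; S.grav[1] = gravity[1]; S.grav[2] = gravity[2];
  return S;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericMatrix vel, NumericVector box,
                        LogicalVector periodic, IntegerVector type0,
                        NumericMatrix aTable, NumericVector mass,
                        NumericVector charge, double gamma, double sigma,
                        double dt, double seed, double step,
                        IntegerMatrix bonds, NumericVector bondK,
                        NumericVector bondR0, bool thermostat, bool elec,
                        double elecC, double elecCut, double elecSmear,
                        NumericVector gravity) {
  Sys S = make_sys(pos, box, periodic, type0, aTable, mass, charge, gamma,
                   sigma, dt, seed, bonds, bondK, bondR0, elec, elecC, elecCut,
                   elecSmear, gravity);
  std::vector<double> x(3 * (size_t)S.n), v(3 * (size_t)S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) { x[3 * i + d] = pos(i, d); v[3 * i + d] = vel(i, d); }
  ForceOut out; out.reset(S.n);
  total_forces(S, x.data(), v.data(), (uint64_t)step, thermostat, out);
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = out.f[3 * i + d];
  return List::create(_["forces"] = F, _["epot_pair"] = out.epotPair,
                      _["epot_bond"] = out.epotBond,
                      _["virial"] = NumericVector::create(out.vir[0], out.vir[1], out.vir[2]));
}

struct Constraints {
  std::vector<int> fixed;          // particle indices
  std::vector<double> fixedPos;    // 3 per fixed particle
  std::vector<int> cageIdx;
  std::vector<double> cage;        // 6 per caged particle
  std::vector<int> fvIdx;
  std::vector<double> fv;          // 3 per particle
  std::vector<int> kickIdx, kickFreq;
  std::vector<double> kick;        // 3 per particle
};

static void apply_constraints_step(const Sys& S, Constraints& C,
                                   std::vector<double>& x, std::vector<double>& v,
                                   uint64_t globalStep, bool doKicks = true) {
  for (size_t k = 0; k < C.fixed.size(); ++k) {
    int i = C.fixed[k];
    for (int d = 0; d < 3; ++d) { x[3 * i + d] = C.fixedPos[3 * k + d]; v[3 * i + d] = 0.0; }
  }
  for (size_t k = 0; k < C.cageIdx.size(); ++k) {
    int i = C.cageIdx[k];
    for (int d = 0; d < 3; ++d) {
      double lo = C.cage[6 * k + 2 * d], hi = C.cage[6 * k + 2 * d + 1];
      double& xi = x[3 * i + d];
      if (xi < lo) { xi = 2 * lo - xi; v[3 * i + d] = -v[3 * i + d]; }
      else if (xi > hi) { xi = 2 * hi - xi; v[3 * i + d] = -v[3 * i + d]; }
    }
  }
  for (size_t k = 0; k < C.fvIdx.size(); ++k) {
    int i = C.fvIdx[k];
    for (int d = 0; d < 3; ++d) v[3 * i + d] = C.fv[3 * k + d];
  }
  if (doKicks) {
    for (size_t k = 0; k < C.kickIdx.size(); ++k) {
      int i = C.kickIdx[k];
      if (C.kickFreq[k] > 0 && globalStep % (uint64_t)C.kickFreq[k] == 0)
        for (int d = 0; d < 3; ++d) v[3 * i + d] += C.kick[3 * k + d];
    }
  }
}

// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix pos0, NumericMatrix vel0, NumericVector box,
                      LogicalVector periodic, IntegerVector type0,
                      NumericMatrix aTable, NumericVector mass,
                      NumericVector charge, double gamma, double sigma,
                      double dt, double kT, int steps, int outputFreq,
                      int minSteps, int minOutput, int scaleSteps,
                      IntegerMatrix bonds, NumericVector bondK,
                      NumericVector bondR0,
                      IntegerVector fixedIdx, NumericMatrix fixedPos,
                      IntegerVector cageIdx, NumericMatrix cageBounds,
                      IntegerVector fvIdx, NumericMatrix fvVel,
                      IntegerVector kickIdx, NumericMatrix kickVel,
                      IntegerVector kickFreq,
                      bool elec, double elecC, double elecCut, double elecSmear,
                      NumericVector gravity, int integrator, double lambda,
                      double seed, double stepOffset, bool recordVelocities,
                      NumericMatrix evalVel0) {
  Sys S = make_sys(pos0, box, periodic, type0, aTable, mass, charge, gamma,
                   sigma, dt, seed, bonds, bondK, bondR0, elec, elecC, elecCut,
                   elecSmear, gravity);
  int n = S.n;
  std::vector<double> x(3 * (size_t)n), v(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3 * i + d] = pos0(i, d); v[3 * i + d] = vel0(i, d); }

  Constraints C;
  C.fixed.assign(fixedIdx.begin(), fixedIdx.end());
  C.fixedPos.resize(3 * C.fixed.size());
  for (size_t k = 0; k < C.fixed.size(); ++k)
    for (int d = 0; d < 3; ++d) C.fixedPos[3 * k + d] = fixedPos(k, d);
  C.cageIdx.assign(cageIdx.begin(), cageIdx.end());
  C.cage.resize(6 * C.cageIdx.size());
  for (size_t k = 0; k < C.cageIdx.size(); ++k)
    for (int d = 0; d < 6; ++d) C.cage[6 * k + d] = cageBounds(k, d);
  C.fvIdx.assign(fvIdx.begin(), fvIdx.end());
  C.fv.resize(3 * C.fvIdx.size());
  for (size_t k = 0; k < C.fvIdx.size(); ++k)
    for (int d = 0; d < 3; ++d) C.fv[3 * k + d] = fvVel(k, d);
  C.kickIdx.assign(kickIdx.begin(), kickIdx.end());
  C.kickFreq.assign(kickFreq.begin(), kickFreq.end());
  C.kick.resize(3 * C.kickIdx.size());
  for (size_t k = 0; k < C.kickIdx.size(); ++k)
    for (int d = 0; d < 3; ++d) C.kick[3 * k + d] = kickVel(k, d);

  ForceOut F1, F2;
  std::vector<double> minEnergy;
  List minFrames;

  // phase 1: steepest descent on conservative + bond forces, displacement
  // capped at 0.05 r_c, with backtracking so the energy never increases
  if (minSteps > 0) {
    std::vector<double> zero(3 * (size_t)n, 0.0);
    total_forces(S, x.data(), zero.data(), 0, false, F1);
    double e = F1.epotPair + F1.epotBond;
    minEnergy.push_back(e);
    double cap = 0.05;
    for (int s = 0; s < minSteps; ++s) {
      double fmax = 0.0;
      for (size_t k = 0; k < F1.f.size(); ++k) fmax = std::max(fmax, std::fabs(F1.f[k]));
      if (fmax < 1e-14) { minEnergy.push_back(e); continue; }
      double h = cap / fmax;
      std::vector<double> xtry(3 * (size_t)n);
      double step = h;
      bool accepted = false;
      for (int bt = 0; bt < 30; ++bt) {
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            xtry[3 * i + d] = S.box.wrap(x[3 * i + d] + step * F1.f[3 * i + d], d);
        total_forces(S, xtry.data(), zero.data(), 0, false, F2);
        double etry = F2.epotPair + F2.epotBond;
        if (etry <= e) {
          x.swap(xtry); F1.f.swap(F2.f);
          F1.epotPair = F2.epotPair; F1.epotBond = F2.epotBond;
          e = etry; accepted = true;
          break;
        }
        step *= 0.5;
      }
      minEnergy.push_back(e);
      if (minOutput > 0 && ((s + 1) % minOutput == 0)) {
        NumericMatrix fr(n, 3);
        for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) fr(i, d) = x[3 * i + d];
        minFrames.push_back(fr);
      }
      if (!accepted) break;
    }
  }

  // trajectory recording
  std::vector<double> serStep, serKT, serEkin, serEpot, serTension;
  List frames, framesVel;
  std::vector<double> frameSteps;
  int dof = 3 * n - 3;
  if (dof < 1) dof = 1;

  auto record = [&](uint64_t gstep, const ForceOut& FF) {
    double ekin = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) ekin += 0.5 * S.mass[i] * v[3 * i + d] * v[3 * i + d];
    double kTinst = 2.0 * ekin / dof;
    double V = S.box.L[0] * S.box.L[1] * S.box.L[2];
    // diagonal pressure tensor: kinetic + conservative virial
    double P[3];
    for (int d = 0; d < 3; ++d) {
      double kin = 0.0;
      for (int i = 0; i < n; ++i) kin += S.mass[i] * v[3 * i + d] * v[3 * i + d];
      P[d] = (kin + FF.vir[d]) / V;
    }
    double tension = (S.box.L[2] / 2.0) * (P[2] - 0.5 * (P[0] + P[1]));
    serStep.push_back((double)gstep);
    serKT.push_back(kTinst);
    serEkin.push_back(ekin);
    serEpot.push_back(FF.epotPair + FF.epotBond);
    serTension.push_back(tension);
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) fr(i, d) = x[3 * i + d];
    frames.push_back(fr);
    frameSteps.push_back((double)gstep);
    if (recordVelocities) {
      NumericMatrix fv(n, 3);
      for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) fv(i, d) = v[3 * i + d];
      framesVel.push_back(fv);
    }
  };

  uint64_t off = (uint64_t)stepOffset;
  bool thermo = S.sigma > 0.0 || S.gamma > 0.0;
  // Groot–Warren modified velocity Verlet: the force carried into step k
  // was evaluated (in step k-1) at the lambda-predicted velocity; the
  // evaluation velocity is part of the carried state so restarts
  // reproduce the force bitwise
  // velocity-type constraints act on the state entering the loop (kicks
  // excluded: they fire at step ends and must not double on restart)
  apply_constraints_step(S, C, x, v, off, false);
  std::vector<double> vEval(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) vEval[3 * i + d] = evalVel0(i, d);
  total_forces(S, x.data(), vEval.data(), off, thermo, F1);
  record(off, F1);

  std::vector<double> vh(3 * (size_t)n);
  for (int s = 1; s <= steps; ++s) {
    uint64_t gstep = off + (uint64_t)s;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double a = F1.f[3 * i + d] / S.mass[i];
        x[3 * i + d] = S.box.wrap(x[3 * i + d] + dt * v[3 * i + d] + 0.5 * dt * dt * a, d);
        vh[3 * i + d] = v[3 * i + d] + lambda * dt * a;
      }
    if (integrator == 1) {
      // self-consistent velocity iteration for the dissipative force
      std::vector<double> vNew(vh), vUsed(vh);
      for (int it = 0; it < 5; ++it) {
        vUsed = vNew;
        total_forces(S, x.data(), vUsed.data(), gstep, thermo, F2);
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            vNew[3 * i + d] = v[3 * i + d] +
              0.5 * dt * (F1.f[3 * i + d] + F2.f[3 * i + d]) / S.mass[i];
      }
      v = vNew;
      vh = vUsed;  // evaluation velocity of the carried force
    } else {
      total_forces(S, x.data(), vh.data(), gstep, thermo, F2);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          v[3 * i + d] += 0.5 * dt * (F1.f[3 * i + d] + F2.f[3 * i + d]) / S.mass[i];
    }
    F1.f.swap(F2.f);
    F1.epotPair = F2.epotPair; F1.epotBond = F2.epotBond;
    F1.vir[0] = F2.vir[0]; F1.vir[1] = F2.vir[1]; F1.vir[2] = F2.vir[2];
    vEval.swap(vh);
    apply_constraints_step(S, C, x, v, gstep);
    // fixation/cage constraints move positions after the force evaluation;
    // re-evaluate so the carried force matches the constrained state
    if (C.fixed.size() || C.cageIdx.size())
      total_forces(S, x.data(), vEval.data(), gstep, thermo, F1);
    if (s <= scaleSteps) {
      double ekin = 0.0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) ekin += 0.5 * S.mass[i] * v[3 * i + d] * v[3 * i + d];
      double kTinst = 2.0 * ekin / dof;
      if (kTinst > 0) {
        double fac = std::sqrt(kT / kTinst);
        for (size_t k = 0; k < v.size(); ++k) v[k] *= fac;
      }
    }
    for (size_t k = 0; k < x.size(); ++k)
      if (!std::isfinite(x[k]) || !std::isfinite(v[k]))
        stop("simulation diverged at step %d (non-finite coordinate)", (int)gstep);
    if (s % outputFreq == 0 || s == steps) record(gstep, F1);
  }

  NumericMatrix finalPos(n, 3), finalVel(n, 3), finalEvalVel(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      finalPos(i, d) = x[3 * i + d];
      finalVel(i, d) = v[3 * i + d];
      finalEvalVel(i, d) = vEval[3 * i + d];
    }
  return List::create(
    _["frames"] = frames, _["frames_vel"] = framesVel,
    _["frame_steps"] = NumericVector(frameSteps.begin(), frameSteps.end()),
    _["series"] = DataFrame::create(
      _["step"] = NumericVector(serStep.begin(), serStep.end()),
      _["kT"] = NumericVector(serKT.begin(), serKT.end()),
      _["kineticEnergy"] = NumericVector(serEkin.begin(), serEkin.end()),
      _["potentialEnergy"] = NumericVector(serEpot.begin(), serEpot.end()),
      _["surfaceTension"] = NumericVector(serTension.begin(), serTension.end())),
    _["minimization_energy"] = NumericVector(minEnergy.begin(), minEnergy.end()),
    _["minimization_frames"] = minFrames,
    _["final_pos"] = finalPos, _["final_vel"] = finalVel,
    _["final_eval_vel"] = finalEvalVel,
    _["final_step"] = (double)(off + (uint64_t)steps));
}

// minimum-image pair distance histogram between two index selections
// (0-based). same = TRUE: selections identical, unordered pairs counted
// once; same = FALSE: all ordered A x B pairs (i != j) counted.
// [[Rcpp::export]]
NumericVector cpp_pair_histogram(NumericMatrix pos, NumericVector box,
                                 LogicalVector periodic, IntegerVector selA,
                                 IntegerVector selB, double rMax, int nBins,
                                 bool same) {
  Box B;
  for (int ax = 0; ax < 3; ++ax) { B.L[ax] = box[ax]; B.per[ax] = periodic[ax]; }
  NumericVector h(nBins);
  double w = rMax / nBins;
  for (int ka = 0; ka < selA.size(); ++ka) {
    int i = selA[ka];
    int kb0 = same ? ka + 1 : 0;
    for (int kb = kb0; kb < selB.size(); ++kb) {
      int j = selB[kb];
      if (j == i) continue;
      double dx = B.mi(pos(i, 0) - pos(j, 0), 0);
      double dy = B.mi(pos(i, 1) - pos(j, 1), 1);
      double dz = B.mi(pos(i, 2) - pos(j, 2), 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= rMax) continue;
      int b = (int)(r / w);
      if (b >= nBins) b = nBins - 1;
      h[b] += 1.0;
    }
  }
  return h;
}

// neighbor count census: for each subject particle, number of particles of
// each type within the shell radius, plus nearest-neighbor index
// [[Rcpp::export]]
List cpp_neighbor_census(NumericMatrix pos, NumericVector box,
                         LogicalVector periodic, IntegerVector type0,
                         int nTypes, double shell) {
  Box B;
  for (int ax = 0; ax < 3; ++ax) { B.L[ax] = box[ax]; B.per[ax] = periodic[ax]; }
  int n = pos.nrow();
  IntegerMatrix counts(n, nTypes);
  IntegerVector nearest(n, NA_INTEGER);
  NumericVector nearestDist(n, R_PosInf);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = B.mi(pos(i, 0) - pos(j, 0), 0);
      double dy = B.mi(pos(i, 1) - pos(j, 1), 1);
      double dz = B.mi(pos(i, 2) - pos(j, 2), 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r <= shell) {
        counts(i, type0[j])++;
        counts(j, type0[i])++;
      }
      if (r < nearestDist[i]) { nearestDist[i] = r; nearest[i] = j; }
      if (r < nearestDist[j]) { nearestDist[j] = r; nearest[j] = i; }
    }
  return List::create(_["counts"] = counts, _["nearest"] = nearest,
                      _["nearest_dist"] = nearestDist);
}
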