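// Coarse-grained engine: KH pair potential + Debye-Hueckel electrostatics +
// harmonic bonds, Verlet neighbor list with minimum image, and a BAOAB-type
// Langevin integrator for mixed flexible-bead / rigid-body systems.
// Units: A, fs, amu, kcal/mol (converted internally via KCAL2INT), Kelvin.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KCAL2INT = 4.184e-4;   // kcal/mol -> amu A^2/fs^2
static const double KB = 0.0019872;        // kcal/(mol K)

// ---------------------------------------------------------------------------
// Counter-based RNG: a splitmix64-style permutation hashed over
// (seed, replica, step, slot).  Stateless, so replica streams are independent
// and a run is reproducible from its seed alone regardless of call slicing.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double u01(uint64_t seed, uint64_t rep, uint64_t step,
                         uint64_t slot) {
  uint64_t h = mix64(seed ^ mix64(rep ^ mix64(step ^ mix64(slot))));
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
static inline double rnorm_ctr(uint64_t seed, uint64_t rep, uint64_t step,
                               uint64_t slot) {
  double u1 = u01(seed, rep, step, 2 * slot);
  double u2 = u01(seed, rep, step, 2 * slot + 1);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ---------------------------------------------------------------------------
struct System {
  int n;
  std::vector<int> type;        // 0..19 residue index, -1 = capping bead
  std::vector<double> sigma, charge, mass;
  std::vector<int> gid;         // rigid group id (0-based), -1 flexible
  std::vector<int> fixedb;      // 1 = immobile
  std::vector<double> eps;      // 20x20 row-major
  double cap_eps;
  double dielectric, debye, elec_cut, ljfac, coulomb;
  double bond_fac;              // 1 (engine convention) or 0.5
  std::vector<int> bi, bj;
  std::vector<double> br0, bk;
  double box;                   // 0 => non-periodic
  std::unordered_set<long long> bonded;
  bool any_charge;
  double sigma_max;

  double rcut_global() const {
    double rc = ljfac * sigma_max;
    if (any_charge && elec_cut > rc) rc = elec_cut;
    return rc;
  }
  bool excluded(int i, int j) const {
    if (gid[i] >= 0 && gid[i] == gid[j]) return true;
    if (fixedb[i] && fixedb[j]) return true;
    long long key = (long long)std::min(i, j) * n + std::max(i, j);
    return bonded.count(key) > 0;
  }
};

static System unpack_system(const List& sys) {
  System S;
  S.type = as<std::vector<int>>(sys["type"]);
  S.n = (int)S.type.size();
  S.sigma = as<std::vector<double>>(sys["sigma"]);
  S.charge = as<std::vector<double>>(sys["charge"]);
  S.mass = as<std::vector<double>>(sys["mass"]);
  S.gid = as<std::vector<int>>(sys["gid"]);
  S.fixedb = as<std::vector<int>>(sys["fixed"]);
  S.eps = as<std::vector<double>>(sys["eps"]);
  S.cap_eps = as<double>(sys["cap_eps"]);
  NumericVector g = sys["globals"]; // dielectric, debye, elec_cut, ljfac, coulomb, bond_fac
  S.dielectric = g[0]; S.debye = g[1]; S.elec_cut = g[2];
  S.ljfac = g[3]; S.coulomb = g[4]; S.bond_fac = g[5];
  S.bi = as<std::vector<int>>(sys["bond_i"]);
  S.bj = as<std::vector<int>>(sys["bond_j"]);
  S.br0 = as<std::vector<double>>(sys["bond_r0"]);
  S.bk = as<std::vector<double>>(sys["bond_k"]);
  S.box = as<double>(sys["box"]);
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    S.bonded.insert((long long)std::min(i, j) * S.n + std::max(i, j));
  }
  S.any_charge = false;
  S.sigma_max = 0.0;
  for (int i = 0; i < S.n; ++i) {
    if (S.charge[i] != 0.0) S.any_charge = true;
    if (S.sigma[i] > S.sigma_max) S.sigma_max = S.sigma[i];
  }
  return S;
}

static inline void min_image(const System& S, double& dx, double& dy,
                             double& dz) {
  if (S.box > 0) {
    dx -= S.box * std::nearbyint(dx / S.box);
    dy -= S.box * std::nearbyint(dy / S.box);
    dz -= S.box * std::nearbyint(dz / S.box);
  }
}

// signed-eps KH pair energy/force (kcal/mol, kcal/(mol A)); fr = -du/dr
static inline void kh_pair(double r, double eps, double sig, double ljfac,
                           double& u, double& fr) {
  u = 0.0; fr = 0.0;
  if (eps == 0.0 || r >= ljfac * sig) return;
  double sr2 = sig * sig / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double lj = 4.0 * (sr12 - sr6);
  double dfr = (48.0 * sr12 - 24.0 * sr6) / r;  // -d(lj)/dr
  double rmin2 = std::pow(2.0, 1.0 / 3.0) * sig * sig; // (2^(1/6) sig)^2
  if (eps < 0) {
    u = -eps * lj; fr = -eps * dfr;
  } else if (r * r < rmin2) {
    u = eps * lj + 2.0 * eps; fr = eps * dfr;
  } else {
    u = -eps * lj; fr = -eps * dfr;
  }
}

struct PairEval {
  double vdw = 0, elec = 0;
};

// energy + force accumulation for one nonbonded pair; returns false if far
static inline bool eval_pair(const System& S, int i, int j, double dx,
                             double dy, double dz, double r2, PairEval& acc,
                             std::vector<double>* F) {
  double r = std::sqrt(r2);
  double sig = 0.5 * (S.sigma[i] + S.sigma[j]);
  double eps;
  if (S.type[i] < 0 || S.type[j] < 0) eps = S.cap_eps;  // capping bead: repulsive
  else eps = S.eps[S.type[i] * 20 + S.type[j]];
  double u, fr, frtot = 0;
  kh_pair(r, eps, sig, S.ljfac, u, fr);
  acc.vdw += u; frtot += fr;
  if (S.charge[i] != 0 && S.charge[j] != 0 && r < S.elec_cut) {
    double pref = S.coulomb * S.charge[i] * S.charge[j] / S.dielectric;
    double ue = pref * std::exp(-r / S.debye) / r;
    double fe = pref * std::exp(-r / S.debye) * (1.0 / r2 + 1.0 / (r * S.debye));
    acc.elec += ue; frtot += fe;
  }
  if (F && frtot != 0.0) {
    double s = frtot / r;
    (*F)[3 * i] += s * dx;  (*F)[3 * i + 1] += s * dy;  (*F)[3 * i + 2] += s * dz;
    (*F)[3 * j] -= s * dx;  (*F)[3 * j + 1] -= s * dy;  (*F)[3 * j + 2] -= s * dz;
  }
  return true;
}

// Verlet candidate-pair list
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> ref_pos;  // positions at last build
  double skin = 4.0;
  int n_close = 0;              // pairs seen below 0.1 A since last reset

  void build(const System& S, const std::vector<double>& x) {
    pi.clear(); pj.clear();
    double rc = S.rcut_global() + skin;
    double rc2 = rc * rc;
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j) {
        if (S.excluded(i, j)) continue;
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        min_image(S, dx, dy, dz);
        if (dx * dx + dy * dy + dz * dz < rc2) { pi.push_back(i); pj.push_back(j); }
      }
    ref_pos = x;
  }
  bool stale(const System& S, const std::vector<double>& x) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < S.n; ++i) {
      double dx = x[3 * i] - ref_pos[3 * i];
      double dy = x[3 * i + 1] - ref_pos[3 * i + 1];
      double dz = x[3 * i + 2] - ref_pos[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

struct Energies {
  double bond = 0, vdw = 0, elec = 0;
  double total() const { return bond + vdw + elec; }
};

static Energies forces(const System& S, const std::vector<double>& x,
                       NeighborList& nl, std::vector<double>& F) {
  std::fill(F.begin(), F.end(), 0.0);
  Energies E;
  PairEval acc;
  double rc = S.rcut_global();
  double rc2 = rc * rc;
  for (size_t p = 0; p < nl.pi.size(); ++p) {
    int i = nl.pi[p], j = nl.pj[p];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    min_image(S, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    if (r2 < 0.01) nl.n_close++;
    eval_pair(S, i, j, dx, dy, dz, r2, acc, &F);
  }
  E.vdw = acc.vdw; E.elec = acc.elec;
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    min_image(S, dx, dy, dz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - S.br0[b];
    E.bond += S.bond_fac * S.bk[b] * dr * dr;
    double fr = -2.0 * S.bond_fac * S.bk[b] * dr;  // -du/dr
    double s = (r > 1e-12) ? fr / r : 0.0;
    F[3 * i] += s * dx;  F[3 * i + 1] += s * dy;  F[3 * i + 2] += s * dz;
    F[3 * j] -= s * dx;  F[3 * j + 1] -= s * dy;  F[3 * j + 2] -= s * dz;
  }
  return E;
}

// ---------------------------------------------------------------------------
// quaternion helpers (w, x, y, z)
static inline void quat_rotate(const double q[4], const double v[3],
                               double out[3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double tx = 2 * (y * v[2] - z * v[1]);
  double ty = 2 * (z * v[0] - x * v[2]);
  double tz = 2 * (x * v[1] - y * v[0]);
  out[0] = v[0] + w * tx + (y * tz - z * ty);
  out[1] = v[1] + w * ty + (z * tx - x * tz);
  out[2] = v[2] + w * tz + (x * ty - y * tx);
}
static inline void quat_rotate_inv(const double q[4], const double v[3],
                                   double out[3]) {
  double qc[4] = {q[0], -q[1], -q[2], -q[3]};
  quat_rotate(qc, v, out);
}
// advance orientation by body-frame angular velocity w over time h (exact for
// constant w): q <- q (x) [cos(|w|h/2), sin(|w|h/2) w_hat]
static inline void quat_advance(double q[4], const double w[3], double h) {
  double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (wn < 1e-300) return;
  double half = 0.5 * wn * h;
  double c = std::cos(half), s = std::sin(half) / wn;
  double dq[4] = {c, s * w[0], s * w[1], s * w[2]};
  double a = q[0], b = q[1], cq = q[2], d = q[3];
  q[0] = a * dq[0] - b * dq[1] - cq * dq[2] - d * dq[3];
  q[1] = a * dq[1] + b * dq[0] + cq * dq[3] - d * dq[2];
  q[2] = a * dq[2] - b * dq[3] + cq * dq[0] + d * dq[1];
  q[3] = a * dq[3] + b * dq[2] - cq * dq[1] + d * dq[0];
  double nrm = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= nrm;
}

struct RigidBody {
  std::vector<int> members;
  std::vector<double> Xb;      // body-frame coords, m x 3 row-major
  double Iprin[3];             // effective principal moments (amu A^2)
  double M;                    // effective mass (amu)
  bool fixed;
  double com[3], V[3], q[4], w[3];  // state
  void place(std::vector<double>& x) const {
    for (size_t k = 0; k < members.size(); ++k) {
      double out[3];
      quat_rotate(q, &Xb[3 * k], out);
      int i = members[k];
      x[3 * i] = com[0] + out[0];
      x[3 * i + 1] = com[1] + out[1];
      x[3 * i + 2] = com[2] + out[2];
    }
  }
};

static std::vector<RigidBody> unpack_bodies(const List& state) {
  List gl = state["groups"];
  std::vector<RigidBody> B(gl.size());
  for (int g = 0; g < gl.size(); ++g) {
    List gi = gl[g];
    RigidBody& b = B[g];
    std::vector<int> mem = as<std::vector<int>>(gi["members"]); // 1-based
    b.members.resize(mem.size());
    for (size_t k = 0; k < mem.size(); ++k) b.members[k] = mem[k] - 1;
    NumericMatrix Xb = gi["Xb"];
    b.Xb.resize(3 * Xb.nrow());
    for (int k = 0; k < Xb.nrow(); ++k)
      for (int a = 0; a < 3; ++a) b.Xb[3 * k + a] = Xb(k, a);
    NumericVector I = gi["Iprin"], com = gi["com"], V = gi["V"], q = gi["q"],
                  w = gi["omega"];
    for (int a = 0; a < 3; ++a) {
      b.Iprin[a] = I[a]; b.com[a] = com[a]; b.V[a] = V[a]; b.w[a] = w[a];
    }
    for (int a = 0; a < 4; ++a) b.q[a] = q[a];
    b.M = as<double>(gi["M"]);
    b.fixed = as<bool>(gi["fixed"]);
  }
  return B;
}

static List pack_bodies(const std::vector<RigidBody>& B, const List& groups0) {
  List out(B.size());
  for (size_t g = 0; g < B.size(); ++g) {
    List gi = clone(as<List>(groups0[g]));
    gi["com"] = NumericVector::create(B[g].com[0], B[g].com[1], B[g].com[2]);
    gi["V"] = NumericVector::create(B[g].V[0], B[g].V[1], B[g].V[2]);
    gi["q"] = NumericVector::create(B[g].q[0], B[g].q[1], B[g].q[2], B[g].q[3]);
    gi["omega"] = NumericVector::create(B[g].w[0], B[g].w[1], B[g].w[2]);
    out[g] = gi;
  }
  return out;
}

// aggregate force and body-frame torque on a rigid body (internal units after
// the caller converts; here plain kcal/mol/A)
static inline void body_force_torque(const RigidBody& b,
                                     const std::vector<double>& x,
                                     const std::vector<double>& F,
                                     double Ft[3], double Tb[3]) {
  double Tw[3] = {0, 0, 0};
  Ft[0] = Ft[1] = Ft[2] = 0;
  for (size_t k = 0; k < b.members.size(); ++k) {
    int i = b.members[k];
    double rx = x[3 * i] - b.com[0];
    double ry = x[3 * i + 1] - b.com[1];
    double rz = x[3 * i + 2] - b.com[2];
    double fx = F[3 * i], fy = F[3 * i + 1], fz = F[3 * i + 2];
    Ft[0] += fx; Ft[1] += fy; Ft[2] += fz;
    Tw[0] += ry * fz - rz * fy;
    Tw[1] += rz * fx - rx * fz;
    Tw[2] += rx * fy - ry * fx;
  }
  quat_rotate_inv(b.q, Tw, Tb);
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, List sys) {
  System S = unpack_system(sys);
  std::vector<double> x(3 * S.n), F(3 * S.n, 0.0);
  for (int i = 0; i < S.n; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = pos(i, a);
  NeighborList nl; nl.skin = 0.0;
  nl.build(S, x);
  Energies E = forces(S, x, nl, F);
  NumericMatrix Fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int a = 0; a < 3; ++a) Fm(i, a) = F[3 * i + a];
  return List::create(_["forces"] = Fm, _["bond"] = E.bond, _["vdw"] = E.vdw,
                      _["elec"] = E.elec, _["total"] = E.total(),
                      _["n_close"] = nl.n_close);
}

// [[Rcpp::export]]
List cpp_cross_energy(NumericMatrix pos, List sys, IntegerVector group_a,
                      IntegerVector group_b) {
  System S = unpack_system(sys);
  std::vector<int> ina(S.n, 0), inb(S.n, 0);
  for (int k = 0; k < group_a.size(); ++k) ina[group_a[k] - 1] = 1;
  for (int k = 0; k < group_b.size(); ++k) inb[group_b[k] - 1] = 1;
  PairEval acc;
  for (int i = 0; i < S.n; ++i) {
    if (!ina[i]) continue;
    for (int j = 0; j < S.n; ++j) {
      if (!inb[j] || i == j) continue;
      if (ina[j] && inb[i] && j < i) continue;  // both in both: count once
      if (S.excluded(i, j)) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      min_image(S, dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      eval_pair(S, i, j, dx, dy, dz, r2, acc, nullptr);
    }
  }
  return List::create(_["vdw"] = acc.vdw, _["elec"] = acc.elec,
                      _["total"] = acc.vdw + acc.elec);
}

// [[Rcpp::export]]
List cpp_run(List sys, List state, List integ, int nsteps, int out_every) {
  System S = unpack_system(sys);
  std::vector<double> x(3 * S.n), v(3 * S.n), F(3 * S.n);
  NumericMatrix pos = state["pos"], vel = state["vel"];
  for (int i = 0; i < S.n; ++i)
    for (int a = 0; a < 3; ++a) {
      x[3 * i + a] = pos(i, a);
      v[3 * i + a] = vel(i, a);
    }
  std::vector<RigidBody> B = unpack_bodies(state);
  std::vector<int> mobile_flex;  // flexible, not fixed
  for (int i = 0; i < S.n; ++i)
    if (S.gid[i] < 0 && !S.fixedb[i]) mobile_flex.push_back(i);

  double dt = as<double>(integ["dt"]);
  double damping = as<double>(integ["damping"]);   // fs; <= 0 => NVE
  double Temp = as<double>(integ["temperature"]);
  uint64_t seed = (uint64_t)as<double>(integ["seed"]);
  uint64_t rep = (uint64_t)as<double>(integ["replica"]);
  double skin = as<double>(integ["skin"]);
  int rebuild_every = as<int>(integ["rebuild_every"]);
  uint64_t step0 = (uint64_t)as<double>(state["step"]);

  bool thermo = damping > 0;
  double c1 = thermo ? std::exp(-dt / damping) : 1.0;
  double noise_fac = thermo ? std::sqrt((1.0 - c1 * c1) * KB * Temp * KCAL2INT)
                            : 0.0;

  int ndof = 3 * (int)mobile_flex.size();
  for (auto& b : B) if (!b.fixed) ndof += 6;

  NeighborList nl; nl.skin = skin;
  nl.build(S, x);
  Energies E = forces(S, x, nl, F);

  int nf = (out_every > 0 && nsteps > 0) ? nsteps / out_every : 0;
  NumericVector frames(std::max(1, nf * S.n * 3));
  NumericMatrix elog(nf + 1, 7);  // step, Tkin, bond, vdw, elec, total, ke
  int frec = 0, nrebuild = 0;

  auto kinetic = [&]() {
    double ke = 0;
    for (int idx : mobile_flex) {
      double m = S.mass[idx];
      ke += 0.5 * m * (v[3 * idx] * v[3 * idx] + v[3 * idx + 1] * v[3 * idx + 1] +
                       v[3 * idx + 2] * v[3 * idx + 2]);
    }
    for (auto& b : B) {
      if (b.fixed) continue;
      ke += 0.5 * b.M * (b.V[0] * b.V[0] + b.V[1] * b.V[1] + b.V[2] * b.V[2]);
      for (int a = 0; a < 3; ++a) ke += 0.5 * b.Iprin[a] * b.w[a] * b.w[a];
    }
    return ke;  // internal units (amu A^2/fs^2)
  };
  auto log_row = [&](int row, uint64_t step) {
    double ke = kinetic();
    double tk = (ndof > 0) ? 2.0 * ke / (ndof * KB * KCAL2INT) : 0.0;
    elog(row, 0) = (double)step; elog(row, 1) = tk;
    elog(row, 2) = E.bond; elog(row, 3) = E.vdw; elog(row, 4) = E.elec;
    elog(row, 5) = E.total(); elog(row, 6) = ke / KCAL2INT;
  };
  log_row(0, step0);

  double f2i = KCAL2INT;  // force kcal/(mol A) -> amu A/fs^2 per 1/m
  for (int s = 1; s <= nsteps; ++s) {
    uint64_t gstep = step0 + (uint64_t)s;
    // B: half kick from current forces
    for (int idx : mobile_flex) {
      double inv = f2i / S.mass[idx];
      for (int a = 0; a < 3; ++a) v[3 * idx + a] += 0.5 * dt * F[3 * idx + a] * inv;
    }
    for (auto& b : B) {
      if (b.fixed) continue;
      double Ft[3], Tb[3];
      body_force_torque(b, x, F, Ft, Tb);
      for (int a = 0; a < 3; ++a) b.V[a] += 0.5 * dt * Ft[a] * f2i / b.M;
      // gyroscopic term + torque, body frame
      double Iw[3] = {b.Iprin[0] * b.w[0], b.Iprin[1] * b.w[1], b.Iprin[2] * b.w[2]};
      double gyro[3] = {b.w[1] * Iw[2] - b.w[2] * Iw[1],
                        b.w[2] * Iw[0] - b.w[0] * Iw[2],
                        b.w[0] * Iw[1] - b.w[1] * Iw[0]};
      for (int a = 0; a < 3; ++a)
        b.w[a] += 0.5 * dt * (Tb[a] * f2i - gyro[a]) / b.Iprin[a];
    }
    // A: half drift
    for (int idx : mobile_flex)
      for (int a = 0; a < 3; ++a) x[3 * idx + a] += 0.5 * dt * v[3 * idx + a];
    for (auto& b : B) {
      if (b.fixed) continue;
      for (int a = 0; a < 3; ++a) b.com[a] += 0.5 * dt * b.V[a];
      quat_advance(b.q, b.w, 0.5 * dt);
    }
    // O: Ornstein-Uhlenbeck (skipped in NVE mode)
    if (thermo) {
      for (int idx : mobile_flex) {
        double amp = noise_fac / std::sqrt(S.mass[idx]);
        for (int a = 0; a < 3; ++a)
          v[3 * idx + a] = c1 * v[3 * idx + a] +
            amp * rnorm_ctr(seed, rep, gstep, (uint64_t)(3 * idx + a));
      }
      uint64_t base = (uint64_t)3 * S.n;
      for (size_t g = 0; g < B.size(); ++g) {
        RigidBody& b = B[g];
        if (b.fixed) continue;
        double ampV = noise_fac / std::sqrt(b.M);
        for (int a = 0; a < 3; ++a)
          b.V[a] = c1 * b.V[a] + ampV * rnorm_ctr(seed, rep, gstep, base + 6 * g + a);
        for (int a = 0; a < 3; ++a)
          b.w[a] = c1 * b.w[a] + noise_fac / std::sqrt(b.Iprin[a]) *
            rnorm_ctr(seed, rep, gstep, base + 6 * g + 3 + a);
      }
    }
    // A: half drift
    for (int idx : mobile_flex)
      for (int a = 0; a < 3; ++a) x[3 * idx + a] += 0.5 * dt * v[3 * idx + a];
    for (auto& b : B) {
      if (b.fixed) continue;
      for (int a = 0; a < 3; ++a) b.com[a] += 0.5 * dt * b.V[a];
      quat_advance(b.q, b.w, 0.5 * dt);
      b.place(x);
    }
    // neighbor list upkeep, then new forces, then final B kick
    if (s % rebuild_every == 0 || nl.stale(S, x)) { nl.build(S, x); nrebuild++; }
    E = forces(S, x, nl, F);
    for (int idx : mobile_flex) {
      double inv = f2i / S.mass[idx];
      for (int a = 0; a < 3; ++a) v[3 * idx + a] += 0.5 * dt * F[3 * idx + a] * inv;
    }
    for (auto& b : B) {
      if (b.fixed) continue;
      double Ft[3], Tb[3];
      body_force_torque(b, x, F, Ft, Tb);
      for (int a = 0; a < 3; ++a) b.V[a] += 0.5 * dt * Ft[a] * f2i / b.M;
      double Iw[3] = {b.Iprin[0] * b.w[0], b.Iprin[1] * b.w[1], b.Iprin[2] * b.w[2]};
      double gyro[3] = {b.w[1] * Iw[2] - b.w[2] * Iw[1],
                        b.w[2] * Iw[0] - b.w[0] * Iw[2],
                        b.w[0] * Iw[1] - b.w[1] * Iw[0]};
      for (int a = 0; a < 3; ++a)
        b.w[a] += 0.5 * dt * (Tb[a] * f2i - gyro[a]) / b.Iprin[a];
    }
    if (out_every > 0 && s % out_every == 0) {
      for (int i = 0; i < S.n; ++i)
        for (int a = 0; a < 3; ++a)
          frames[(size_t)frec * S.n * 3 + (size_t)a * S.n + i] = x[3 * i + a];
      frec++;
      log_row(frec, gstep);
      for (int i = 0; i < 3 * S.n; ++i)
        if (!std::isfinite(x[i]))
          stop("non-finite coordinate at step %d (bead %d): simulation aborted",
               (int)gstep, i / 3 + 1);
    }
  }

  NumericMatrix posO(S.n, 3), velO(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int a = 0; a < 3; ++a) {
      posO(i, a) = x[3 * i + a];
      velO(i, a) = v[3 * i + a];
    }
  if (nf > 0) frames.attr("dim") = IntegerVector::create(S.n, 3, nf);
  return List::create(
      _["pos"] = posO, _["vel"] = velO,
      _["groups"] = pack_bodies(B, state["groups"]),
      _["step"] = (double)(step0 + (uint64_t)nsteps),
      _["frames"] = nf > 0 ? frames : NumericVector(0),
      _["nframes"] = nf, _["energy"] = elog, _["nrebuild"] = nrebuild,
      _["n_close"] = nl.n_close);
}
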